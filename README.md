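# codonstab

Coding regions influence how long human mRNAs live: synonymous codons are
decoded at different speeds, and slowly decoded ("non-optimal") codons
destabilize transcripts. Measuring this on endogenous mRNAs is confounded
because coding regions co-evolve with UTRs, length and expression level.
A clean way around the confound is a parallel reporter design — thousands
of human ORFs expressed from a common vector with invariant UTRs — so that
only the coding region varies.

`codonstab` implements the computational side of that design for R users
working from count tables and footprint tables (alignment and counting
are upstream):

* **Half-life estimation** from 4SU approach-to-equilibrium labeling
  time courses. Labeled abundance follows bounded growth,
  `y(t) = y_eq (1 - e^{kt})` with `k <= 0`, fitted per transcript by
  weighted nonlinear least squares (weights `1/y`, start
  `y_eq = max(y), k = -0.5`, box constraints `y_eq >= 0, k <= 0`);
  `HL = ln 2 / |k|`. Counts are spike-in normalized (labeled
  *D. melanogaster* spike) and coverage-filtered (>= 1 read at every time
  point, >= 5 at some time point) first.
* **Reporter classification**: a transcript counts as an ORFeome reporter
  in a cell line iff it is in that line's pool, its normalized
  steady-state signal is strictly more than 3x the matched line's, and
  strictly more than 4 reads.
* **Codon stability coefficients**: CSC(codon) = Spearman correlation
  between the codon's usage frequency and half-life across transcripts
  (stop codons excluded from output); AASC = mean CSC over synonymous
  codons; +1/+2 frameshift controls that must degrade any
  translation-dependent signal.
* **Pause scores** from 28–30 nt ribosome footprints: the A/P/E sites are
  read positions 17–19/14–16/11–13; score = observed in-frame site
  frequency / abundance-weighted expected frequency — a relative
  dwell-time proxy per codon.
* **ORF covariates**: length, minimum windowed folding energy (100-nt
  windows every 3 nt; pluggable energy function with a base-pairing
  surrogate default), miRNA 7mer-m8 seed sites, AU-rich elements.
* **A synthetic-data generator** with known ground truth (decay
  constants, codon weights, dwell multipliers) that drives the package's
  end-to-end recovery tests.

See `vignettes/codonstab-methods.Rmd` for the models, defaults and design
choices.

## Worked example

Run the full synthetic study — simulate a transcriptome whose decay rates
depend on codon content, fit half-lives, classify a planted two-pool
design, estimate CSCs in-frame and frameshifted, and score A-site pauses
from simulated footprints:

```r
library(codonstab)

cfg <- pipeline_config(
  sim = sim_config(n_transcripts = 300, seed = 42),
  n_footprints = 5e4)
report <- run_all(cfg, quiet = TRUE)
print(report)
#> codonstab synthetic study report
#>   n_transcripts                    300
#>   n_fit                            300
#>   halflife_median_rel_err_pct      4.895
#>   classification_errors            0
#>   csc_recovery_spearman            0.6779
#>   csc_shift1_spearman              0.1814
#>   csc_shift2_spearman              0.08937
#>   frameshift_gap                   0.4965
#>   pause_recovery_spearman          0.9859
#>   elapsed_s                        5.427
```

Reading the numbers: with Poisson count noise, fitted half-lives land
within ~5% of truth at the median (`halflife_median_rel_err_pct`); the
planted reporter/endogenous/excluded design is reproduced without error;
estimated CSCs rank-correlate 0.68 with the generating codon weights
in-frame but only 0.18/0.09 after +1/+2 frameshifts (`frameshift_gap`,
the translation-dependence signature); and A-site pause scores
rank-correlate 0.99 with the generating dwell multipliers. Recovery
strengthens with more transcripts — at n = 500 and noise-free counts, CSC
recovery is ≈ 0.84.

Fitting a single time course directly:

```r
tps <- c(1, 2, 4, 8, 12, 24)                     # hours
y <- 120 * (1 - exp(-log(2) / 6 * tps))          # HL = 6 h
fit <- fit_bounded_growth(tps, y)
c(fit$y_eq, fit$k, fit$half_life)
#> 120.0000  -0.1155   6.0000
```

A thin command-line front end over the same functions ships in
`inst/cli/codonstab.R`:

```sh
Rscript inst/cli/codonstab.R simulate --n 500 --seed 1 --out-prefix sim
Rscript inst/cli/codonstab.R fit-halflives --counts sim_timecourse.tsv \
    --samples sim_samples.tsv --out halflives.tsv
Rscript inst/cli/codonstab.R csc --fasta sim_cds.fa \
    --halflives halflives.tsv --out csc.tsv
```

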