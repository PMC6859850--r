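---
title: "Methods: isolating coding-region effects on mRNA stability"
author: "codonstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolating coding-region effects on mRNA stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonstab)
```

# Scope

`codonstab` implements the computational core of a reporter-based analysis
of how coding regions shape human mRNA stability: half-life estimation
from 4-thiouridine (4SU) approach-to-equilibrium time courses, ORFeome
reporter classification, codon and amino-acid stability coefficients
(CSC/AASC) with frameshift controls, ribosome-profiling A/P/E-site pause
scores, and ORF-level sequence covariates. Upstream read processing
(trimming, alignment, counting) is out of scope: the package consumes
count tables, footprint tables in transcript coordinates, and CDS FASTA.

Because the original sequencing libraries are not redistributable at desk
scale, the package ships a first-class synthetic-data generator with known
ground truth; every analysis stage is validated by recovery of the
generating parameters.

# The kinetic model

Under approach-to-equilibrium metabolic labeling, the labeled abundance of
a transcript follows bounded growth,

$$y(t) = y_{eq}\,\bigl(1 - e^{k t}\bigr), \qquad k \le 0,$$

where $y_{eq}$ is the steady-state level and $k$ the transcript-specific
decay constant (the sign convention keeps $k$ non-positive; the half-life
is $\mathrm{HL} = \ln 2 / |k|$). `fit_bounded_growth()` fits this curve by
weighted nonlinear least squares with weights $1/y(t)$ (the variance of a
count is proportional to its mean), start values $y_{eq} = \max(y)$,
$k = -0.5$, and box constraints $y_{eq} \in [0,\infty)$,
$k \in (-\infty, 0]$, using the port algorithm of `stats::nls()` with a
ceiling of 200 iterations. A fit is reported non-converged — half-life
`NA` — when the solver fails or the fitted $k$ sits at the zero bound
($k \ge -10^{-9}$, no measurable decay).

Counts are made comparable across time points by dividing each sample by
the total of its labeled *D. melanogaster* spike-in rows
(`spike_normalize()`); the unlabeled yeast spike is carried as QC rows
only. Before fitting, transcripts must show at least one raw read at
every time point and at least five at some time point
(`filter_timecourse()`). This raw-count filter also guarantees the
positive counts that the $1/y$ weights require; the fitter additionally
rejects series containing non-positive values rather than imputing.
Replicate half-lives are combined by arithmetic mean
(`combine_replicates()`). Half-lives are reported uncapped; values above
100 h are flagged `long_lived` rather than truncated.

Numerical behavior worth knowing:

* On noise-free data the fit recovers generating half-lives anywhere in
  [0.25, 100] h to better than $10^{-6}$ relative error with the default
  (1, 2, 4, 8, 12, 24) h design.
* The estimator is scale-equivariant: rescaling all counts rescales
  $y_{eq}$ and leaves $k$ unchanged, so the spike normalization's overall
  scale is immaterial to half-lives.
* With Poisson counts at a steady-state expectation of ~200 and the
  six-point design, the median relative half-life error is ~11%. This is
  not slack in the solver: the Cramér–Rao bound for this design evaluates
  to ~10% median error, so the weighted-NLS estimator operates close to
  the information limit; materially better accuracy requires deeper
  counts or more time points, not a different optimizer.

# Reporter classification

For a cell line $X$ carrying an ORFeome pool, `classify_orfeome()` labels
a transcript `orfeome` iff it is in $X$'s pool **and** its library-size-
normalized steady-state count strictly exceeds three times that in the
matched line **and** strictly exceeds 4. Transcripts not in the pool are
`endogenous`; pooled transcripts failing either threshold are `excluded`.
Both thresholds are strict inequalities, so `9` vs `3` (exactly
threefold) and `4` (exactly four) fail. Library-size normalization
(`library_size_normalize()`) scales each sample by mean-total/its-total,
keeping values on a read-count scale so the `> 4` threshold retains its
meaning. Transcripts present in counts but absent from the pool registry
are treated as not-in-pool. For endogenous half-life tables we exclude
any transcript present in either line's pool, recorded in output
metadata, since reads cannot be attributed at the transcript level.

# Codon stability coefficients

`codon_frequencies()` computes codon usage as fractions of the counted
codons, not raw counts — raw counts would confound CSC with ORF length.
Stop codons are counted in the denominator but excluded from CSC output.
The CSC of a codon (`compute_csc()`) is the Spearman correlation, across
transcripts, between the codon's frequency and the half-life; ties get
average ranks and `NA` half-lives are dropped pairwise. AASCs
(`compute_aasc()`) are arithmetic means over synonymous codons, an exact
identity covered by tests. Correlated correlation magnitudes are compared
with the standard independent-samples Fisher r-to-z formula
(`fisher_r_to_z()`).

Frameshift controls re-count codons after shifting the frame: `+1`
removes positions 1, $n-2$, $n-1$ of an $n$-nt CDS, and `+2` removes
positions 1, 2, $n-1$. A translation-dependent signal must degrade under
these shifts; on codon-driven synthetic data the in-frame CSC recovery
exceeds the shifted recoveries by well over 0.3 Spearman units.

# Pause scores from ribosome footprints

Footprints are 28–30 nt reads in transcript coordinates (0-based 5'
offsets; from transcriptome SAM, `five_prime_pos = POS - 1`). Within a
read, the A, P and E sites occupy positions 17–19, 14–16 and 11–13
(1-based). `assign_site_codon()` accepts a read for a site iff the site
start is in-frame and the site lies within the sequence; since the three
offsets are congruent mod 3, an accepted read's A/P/E codons are the
consecutive codon indices $i, i-1, i-2$, and evaluating the frame at any
one site is equivalent to any other — the choice is consequence-free and
tested.

The pause score of a codon is its observed site frequency over accepted
reads divided by the null expected frequency: the codon's frequency in
each gene's ORF weighted by the gene's share of in-frame accepted reads
(`expected_frequencies()`; one consistent set of A-site weights serves
all three site tables because a single null is defined). Stop codons are
included in the expectation's denominator — the null is a property of the
ORF sequence — and scores are reported for them as well. Amino-acid
scores are arithmetic means of member-codon scores. `tertile_groups()`
splits ranked codons into slow/neutral/fast groups of 21/20/20 with
lexicographic tie-breaking, so the grouping is deterministic and
order-invariant.

A geometric caveat specific to transcript-coordinate data: a read whose
A site sits in the first six codons would need a 5' end upstream of the
ORF, and one whose A site is the stop codon extends past it, so with
CDS-only records those codons are unobservable ("boundary shadow") while
still contributing to the expected null — the start codon's score is
then systematically deflated (~0.88 under uniform dwell). Real footprints
extend into the UTRs; the generator therefore supports short in-frame
untranslated flanks (`utr5_nt`, `utr3_nt`), and the pause-score recovery
studies use 18-nt flanks so that boundary codons are observable. The
expected null is always computed on the ORF proper, per its definition.

# ORF-level covariates

`feature_table()` assembles per-transcript covariates: ORF length;
minimum folding energy over 100-nt windows starting every 3 nt
(`sliding_windows()`, `min_window_energy()`); per-seed miRNA 7mer-m8
site flags (`scan_mirna_sites()` — the seed list is supplied by the user,
never hard-coded); and an AU-rich element flag (`detect_are()`, default
rule: at least one AUUUA pentamer, both motif and threshold
configurable). The energy function is an injection point: the default
`pairing_energy()` is a deterministic surrogate — the negated maximum
number of nested complementary pairs (A:U, G:C, G:U wobble; minimum
hairpin loop 3 nt) by dynamic programming in C++ — and any thermodynamic
folder can be plugged in as `function(window) <MFE>`. Tests target the
windowing and minimum logic, not folding thermodynamics. The miRNA site
definition (7mer-m8) and the ARE rule are deliberately simple documented
defaults; the underlying study did not specify its exact definitions, so
neither is presented as anything but a configurable choice.

# Shared statistics

`ks_test()`, `wilcoxon_test()` and `variance_ratio()` wrap the standard
two-sided tests into a common `TestResult` shape. Exact small-sample
p-values are used where the underlying routines support them (exact
Wilcoxon below n = 50 without ties; exact KS while $n_1 n_2 < 10^4$
without ties), with asymptotic approximations and tie corrections
otherwise. A paired Wilcoxon on identical vectors returns statistic 0 and
p = 1 (all differences zero carry no evidence). Variance ratios compare
spread of half-life distributions as var(y)/var(x) of median-centered
log2 half-lives with a two-sided F test; the log2 scale choice and the
method string are recorded in the result. Under null simulations all
three tests reject at ~5% at $\alpha = 0.05$; the exact KS test is
slightly conservative (~3%) by discreteness, which is a property of the
test, not the wrapper.

# The synthetic-data generator

`simulate_transcriptome()` emits CDS records (ATG start, single terminal
stop, no internal in-frame stop) whose codon usage varies across
transcripts through a per-transcript Dirichlet perturbation (total
concentration 30) of uniform sense-codon usage — without usage variation
there is no CSC signal to recover. Decay constants follow a linear model
on the log scale:

$$\log k_i = \alpha + \beta \sum_c f_i(c)\, w_c + \varepsilon_i,$$

with latent stability weights $w_c \sim N(0,1)$ (centered) and Gaussian
residuals. The underlying study states no generative model for the
codon–decay coupling; linear-in-frequencies is the minimal model that
makes CSC recovery well-posed. Defaults, chosen once: $\alpha$ places the
median half-life at 8 h (the study's endogenous median is 8.2 h);
$\beta = -2$ (stabilizing codons lower $k$); `eps_sd = "auto"` sets the
residual SD equal to the codon-term SD so codon composition explains ~50%
of var($\log k$) — under which the rank correlation between the codon
score and $\log k$ is ≈ −0.7. $\beta$ is a free simulation parameter, not
an empirical claim: the study provides no human effect-size estimate.

`simulate_timecourse()` draws counts around
$y_{eq,i}(1 - e^{-k_i t})$ at the labeled time points (default 1, 2, 4,
8, 12, 24 h), with constant-expectation fly spike rows at 10% of depth
(mirroring the 10% w/w spike mass of the labeling protocol) and yeast QC
rows at 2%; noise is Poisson or none, where "none" returns the
real-valued expectations so solver precision can be measured.
Steady-state abundances are lognormal (sdlog 1), normalizable to a target
median via `median_y_eq`.

`simulate_footprints()` samples A-site codon positions with probability
proportional to transcript abundance times the codon's dwell multiplier
(log-uniform in [0.5, 2] by default; stop codons get a terminal-pause
multiplier of 2), draws read lengths uniformly from 28–30 nt, and places
the 5' end so the sampled codon occupies read positions 17–19. Reads that
cannot be placed within the record are skipped and counted
(`n_skipped`).

`simulate_steady_state()` plants a two-line classification design:
pooled transcripts leak at 5% into the paired line (passing the threefold
rule), a planted 20% of pooled transcripts leak at 60% (failing it), and
endogenous transcripts are expressed equally in both; expected labels are
computed from the noise-free expectations on the classifier's normalized
scale, so classification can be checked for exact agreement.

What the generator deliberately does **not** emulate: raw reads and
alignment artifacts, biotinylation/enrichment efficiency, 5'/3' UTR
regulatory content beyond short neutral flanks, isoform structure, tRNA
pool dynamics, or any dependence of decay on length or structure. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated statistical model, not biological completeness.

# Study sizes used by the recovery suite

The shipped recovery studies use: 200 noise-free transcripts spanning
half-lives of 0.25–100 h (solver precision); 2000 Poisson transcripts at
median steady-state expectation 200 spanning 0.5–24 h (noise
sensitivity); 500 transcripts for CSC recovery and 10^5 footprint reads
over 500 transcripts for pause-score recovery; 300 transcripts with
$\beta = 0$ and residual SD 0.3 for null calibration (200 half-life
permutations); and 1000-replicate null simulations (n = 20 per sample)
for test sizes. These sizes give stable recovery statistics while keeping
a full run to a couple of minutes on one core.

# Known limitations

* The half-life estimator inherits the information limits of the
  six-point design discussed above; per-transcript errors at shallow
  depth are ~10% even when everything is specified correctly.
* CSC recovery at n = 500 with half the variance of $\log k$ unexplained
  tops out around Spearman 0.8–0.9 against the generating weights; this
  is estimation noise in 61 correlated statistics, not bias.
* The Fisher r-to-z comparison assumes independent samples; CSC sets
  computed from overlapping transcript sets violate independence, and no
  dependence correction is attempted.
* The surrogate folding energy ranks local structure by pairing capacity
  only; it is not a thermodynamic MFE and should not be compared across
  alphabets or against RNAfold values.
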