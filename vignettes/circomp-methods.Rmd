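---
title: "Weighted cosine rhythm detection and cross-species circadian comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted cosine rhythm detection and cross-species circadian comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

circomp detects circadian rhythmic genes in bulk RNA-seq time courses and
compares circadian characteristics between two gene universes, typically
two species profiled under matched designs. This vignette explains the
model, the estimation procedure, the statistical choices, and what the
synthetic data generator does and does not emulate.

```{r setup}
library(circomp)
```

## The oscillation model

Each gene's normalized expression $y$ (log2 counts-per-million) at sampling
time $t$ (hours) is modelled as a single cosine plus a baseline and a slow
linear drift:

$$
y(t) = A \cos\!\left(\frac{2\pi}{P}\,t \;-\; \frac{2\pi}{24}\,\phi_{24}\right)
      + C + s\,(t - \bar t),
$$

with amplitude $A \ge 0$ (log2 units, half the peak-to-trough swing), free-
running period $P \in (12, 36)$ h, phase $\phi_{24} \in [0, 24)$ h (the
peak time rescaled to a 24 h cycle, so genes with different periods remain
comparable), baseline $C$ (the average expression level, anchored at the
weighted mean sampling time $\bar t$), and drift slope $s$ (log2 per hour).
Parameters are estimated per gene by minimizing the weighted sum of squared
errors with per-observation weights from preprocessing.

The package's rhythmicity index is the **circadian oscillation
correlation**: the Pearson correlation between the trend-removed
observations and the fitted cosine. We deliberately exclude the trend from
the predicted values — a monotone drift fit by the trend term should not
be able to masquerade as rhythmicity — and we use plain (unweighted)
Pearson correlation, the conventional reading of a "correlation
coefficient" with no qualifier. A gene whose best fit has zero amplitude
has a constant prediction, an undefined correlation, and is treated as
arrhythmic. The conventional classification cutoff is a correlation of at
least 0.7, a threshold that has proven robust in circadian transcriptome
studies; `classify_rhythmic()` takes it as an argument and
`cutoff_sweep()` profiles counts across a cutoff range.

## Estimation: detrend, FFT, variable projection, polish

The fitting procedure in `fit_cos()` follows the classical
detrend-then-initialize-then-refine recipe, with one structural change:

1. A weighted linear regression on time gives the trend used for
   *initialization only* (`detrend()`).
2. The detrended residuals, averaged per timepoint so the series is
   uniformly spaced, are Fourier transformed; the maximal-power frequency
   bin whose period lies strictly inside (12, 36) h is kept as the main
   signal, refined by quadratic interpolation of the power across the peak
   bin and its neighbours (`fft_initial_period()`). If no in-bounds bin
   exists, a 24 h proposal is returned flagged.
3. The full model — cosine *and* trend — is then fit jointly by variable
   projection: at any fixed period the model is linear in
   $(A\cos\psi, A\sin\psi, C, s)$, so those four parameters have an exact
   weighted least-squares solution, and the period is the only nonlinear
   coordinate. The profiled objective is evaluated on a 0.5 h grid over
   (12, 36) seeded with the FFT proposal, the best candidate is refined by
   golden-section search, and a safeguarded Gauss-Newton polish takes the
   optimum to machine precision.
4. Standard errors come from the weighted Jacobian at the optimum with
   residual degrees of freedom $n - 4$; negative-amplitude local solutions
   are re-expressed with positive amplitude and a half-period phase shift;
   a fitted period within $10^{-6}$ of a bound is flagged `at_bound`.

Two design choices deserve comment. First, the trend is estimated
*jointly* rather than removed once and forgotten: over a 44 h window a
pure cosine is not orthogonal to a straight line (for the default design
the induced slope is about $-0.01 \cdot A$ per hour), so sequential
detrending followed by a cosine-only fit biases every parameter and cannot
recover exact curves. Joint estimation is what iterating
"detrend, fit, re-detrend" converges to, and it recovers noiseless curves
to below $10^{-6}$ in all parameters. Second, variable projection replaces
the more common box-constrained 4-parameter optimizer with phase restarts:
because phase, amplitude, baseline and slope are solved exactly at every
candidate period, there is no period-phase ridge to fall off, no restart
ladder, and the fit provably dominates any grid search over
(period, phase) nodes.

Numerical details: the profiled SSE is computed from explicit residuals
(the normal-equations shortcut $\sum w y^2 - 2c^\top b + c^\top A c$
cancels catastrophically near perfect fits and would stall refinement
around $10^{-6}$); the golden-section tolerance is $10^{-9}$ h; the
Gauss-Newton polish accepts only steps that keep the period in bounds and
do not increase the SSE, halving the step up to twice before giving up.
Genes whose fit fails (non-finite values, singular solves at every
candidate) are reported `converged = FALSE` and treated as arrhythmic,
never aborting a batch run.

## The oscillation p-value and its calibration

Robustness of oscillation is summarized by $-\log_{10}(p)$ from an F-type
statistic comparing the cosine model against the trend-only model on the
same weighted observations:

$$
F = \frac{(\mathrm{SSE}_0 - \mathrm{SSE}_1)/3}{\mathrm{SSE}_1/(n-4)}.
$$

The nominal $F(3, n-4)$ reference would be correct if the period were
fixed in advance. It is not: the fit searches a whole frequency band, so
under the null the numerator is the *best* improvement over roughly three
independent frequencies, and the nominal p-values are markedly
anti-conservative (simulated Kolmogorov-Smirnov distance from uniform
$\approx 0.36$ on the default design). No degrees-of-freedom convention
repairs this, and the selection effect has no closed-form null.

`fit_all()` therefore calibrates by Monte Carlo: 2000 white-noise genes
are fitted with the identical procedure on the identical design, and a
scaled-F family $F_{\mathrm{null}} \sim \lambda F(\nu_1, \nu_2)$ is fitted
to the resulting statistics by maximum likelihood
(`null_calibration()`, cached per design, internally seeded so the same
design always yields the same calibration). The smooth parametric family
keeps $-\log_{10}(p)$ continuous and finite for strongly rhythmic genes —
important for the radial plots — while matching the empirical null
closely (fresh-sample KS distance $\approx 0.03$). The calibration uses
equal weights; with per-observation weights the statistic is scale-free
and remains approximately pivotal. `rhythm_pvalue()` exposes both the
nominal and the calibrated tail. p-values are floored at $10^{-300}$
before $-\log_{10}$ so plot coordinates stay finite (radius cap 300).

## Preprocessing contracts

The pipeline consumes a raw count matrix and a sample sheet
(sample id, ZT hour, replicate). Preprocessing re-implements the
*contracts* of the standard count-normalization stack rather than any
specific package's code, with explicit defaults:

* **Expression filter** (`filter_expressed()`): keep genes whose CPM
  exceeds the CPM-equivalent of `min_count = 10` at the median library
  size in at least $\lceil n_{\mathrm{samples}}/n_{\mathrm{timepoints}}
  \rceil$ samples (one replicate group's worth) and whose total count
  exceeds 15.
* **Scaling factors** (`scaling_factors()`): trimmed mean of log2 ratios
  of relative abundance against a reference sample (the sample whose
  upper-quartile CPM is closest to the mean), trimming 30% from each
  log-ratio tail and 5% from each average-intensity tail — the
  conventional values — rescaled to geometric mean 1.
* **log2(CPM)** (`log2_cpm()`): pseudo-count `prior_count = 0.5` in CPM
  units (scaled by each sample's effective library size), which avoids
  log(0) with minimal bias, makes the transform exactly invariant to
  rescaling all counts by a common factor, and maps a zero count to
  approximately $\log_2(\texttt{prior\_count})$ in every sample.
* **Weights** (`estimate_weights()`): residuals are taken around
  per-timepoint means — replicates within a ZT hour are the only
  exchangeable unit in a time course. `mean_variance` converts a lowess
  trend of residual scale versus average expression into inverse-variance
  precision weights; `per_sample_quality` additionally multiplies by a
  per-sample factor inversely proportional to that sample's mean squared
  residual (mean 1), the default because variable samples should be
  down-weighted; `equal` and `external` (for importing weights computed
  elsewhere, e.g. for exact parity studies) complete the modes. Weights
  are strictly positive (floor $10^{-6}$, with a warning) and normalized
  to mean 1 — their overall scale cancels in weighted least squares.

Whether a study's weights were per sample or per observation is generally
not recoverable from a methods section; both granularities are supported,
and the fit only requires positive weights with the right qualitative
structure.

## Comparing two rhythmic universes

`compare_param()` contrasts phase24, period, amplitude or baseline between
two classified sets with two-sided Kolmogorov-Smirnov or Mann-Whitney
tests and reports medians and IQRs. Phase24 is a circular quantity;
published comparisons typically treat it linearly on $[0, 24)$, so that is
the default, but `circular = TRUE` runs a Kuiper-style variant that is
invariant to rotation of the phase origin — the statistically clean choice
when distributions straddle midnight. `phase_density_peaks()` estimates
the phase density on the circle by replicating phases at $\pm 24$ h before
kernel estimation (evaluated on a 0.01 h grid, rescaled to integrate to 1
over one cycle); the default bandwidth is a Silverman-style rule clipped
to [0.5, 2] h, which resolves peaks about 1.5 h apart without overfitting.
`cutoff_sweep()` compares rhythmic-fraction profiles across cutoffs with a
two-sample KS test; the profiles are paired by cutoff, which the KS test
ignores — this mirrors common practice and is documented as such.

## Homolog contrasts

For a reference clock gene and its homologs, `contrast_parameters()`
compares fitted parameters with a Welch-style statistic on the estimates
and their standard errors (Satterthwaite degrees of freedom from the fits'
residual df) and adjusts each reference gene's family of comparisons by
Holm-Sidak: sorted raw p-values receive
$p^{\mathrm{adj}}_{(i)} = 1 - (1 - p_{(i)})^{m-i+1}$, enforced monotone.
Significance stars follow the 0.05/0.01/0.001 convention. Phase
differences are wrapped to $(-12, 12]$ — 23 h versus 1 h is a 2 h shift,
not 22 h — which also makes contrasts invariant to rotating both genes'
phases. When per-replicate parameter estimates exist, the replicate-level
route `contrast_parameters_anova()` (one-way ANOVA, pooled-variance
per-homolog comparisons, Holm-Sidak) is available; the estimate-based
route is the default because parameter fits are usually obtained once per
gene, not per replicate. `radial_coordinates()` exports the phase24 angle
($2\pi\phi_{24}/24$), the capped robustness radius, and the phase standard
error as symbol size; `profile_table()` exports tidy observed-plus-
predicted time courses for profile plots.

## Correlation-ranked enrichment

`run_enrichment()` ranks genes by oscillation correlation in descending
order (ties broken by gene id, so rankings are deterministic) and computes
the weighted Kolmogorov-Smirnov enrichment score: hits advance the running
sum by $|r|^p / N_R$ (weight exponent $p = 1$), misses retreat by
$1/(N-n)$, and ES is the extreme deviation. Set sizes are bounded to
[3, 800] after intersection with the ranked universe. The null is by
gene-label permutation — the only available scheme for a preranked,
single-statistic analysis — with NES defined as ES over the mean |null ES|
of matching sign, an add-one two-tailed empirical p (floor
$1/(n_{\mathrm{perm}}+1)$), and FDR by the pooled positive/negative null
convention. The permutation seed is mandatory; identical seeds reproduce
NES/p/FDR bit for bit. `quadrant_compare()` intersects two result tables,
labels each common set by its NES sign pair — the off-diagonal quadrants
are where circadian enrichment disagrees between sources — and sorts
off-diagonal sets by ascending combined p, defined conservatively as
$\max(p_A, p_B)$. `nes_correlation()` reports the Pearson correlation of
common-set NES values with the regression F-test p-value.

## The synthetic data generator

`simulate_dataset()` emulates the sampling design of free-running plant
circadian studies: 12 timepoints at 4 h intervals for two continuous days
starting at ZT24 under constant light, with 2 (Arabidopsis-like) or 3
(soybean-like) biological replicates per timepoint. Per gene the mean
log2(CPM) follows the oscillation model above; a designed fraction of
genes (default 0.45, the regime reported for both species) is rhythmic
with amplitude U(0.5, 3) log2 units, period U(20, 28) h, phase U(0, 24) h,
baseline U(2, 10) log2(CPM) and a small drift U(-0.02, 0.02) log2/h so
trend handling is always exercised; arrhythmic genes have amplitude 0.
Counts are negative-binomial by default (a raw count matrix is the
pipeline's entry object) with per-gene dispersion U(0.01, 0.09), the
biological-coefficient-of-variation range of well-controlled bulk RNA-seq
replicates; a lognormal log2-scale noise model (sd parameter) is offered
for noise-level-controlled simulations. Library sizes are log-uniform
within a factor of two of a nominal 2e7 reads — typical bulk RNA-seq
depth — so library scaling is non-trivial but stable.
`make_homolog_truth()` and `simulate_species_pair()` plant homolog pairs
with designed phase shifts (wrapped on the circle), period shifts
(validated against the (12, 36) bounds) and amplitude ratios, so the
homolog-contrast machinery can be validated against known directions.

What the generator does *not* emulate: gene-gene correlation, waveform
asymmetry (sawtooth-like clock genes), batch structure, GC/length biases,
or annotation semantics of real gene-set databases. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the estimation and comparison machinery under the stated noise models, not
biological conclusions about any particular dataset.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 25 noiseless recovery
curves, 100 oracle-dominance instances against a dense
(0.01 h period, 0.05 h phase) grid search, 1000 white-noise genes for null
calibration checks, 500 noisy genes for recovery-error medians, 100
repeats for detection-power and homolog-concordance rates, and a
2000-gene two-species end-to-end run — sizes at which every reported rate
has a usefully narrow binomial interval while the whole suite stays quick
on a single CPU. All randomness flows from explicit seeds; the Monte Carlo
null calibration is internally seeded and cached per design, so repeated
runs of the same pipeline are bit-identical.

## Known limitations

* A single sinusoid: harmonics and non-sinusoidal waveforms are outside
  the model class, and genes with strong second harmonics will fit with
  reduced correlation.
* The null calibration assumes exchangeable Gaussian-like noise on the
  log2 scale; severe outliers are the weights' job, not the null's.
* The two-day window identifies periods in (12, 36) h only; fits at the
  bounds are flagged rather than excluded.
* The KS test on cutoff-sweep fraction profiles ignores their pairing by
  cutoff; it is provided for comparability with common practice.
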