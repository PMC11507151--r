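---
title: "Methods: ordinal quantifiers, spectral estimation and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordinal quantifiers, spectral estimation and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroplane)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and what the
synthetic-data validation does and does not establish about real
recordings.

## Ordinal symbolization

A voltage series is scanned with overlapping delay-embedded vectors
$(x_t, x_{t+\tau}, \dots, x_{t+(D-1)\tau})$. Each vector is replaced by its
ordinal pattern — the permutation that sorts it ascending — and a series of
$M$ samples contributes $n = M - (D-1)\tau$ patterns to a histogram over
the $D!$ possibilities (`bp_pdf()`). Patterns depend only on relative
order, so the distribution is invariant under positive affine rescaling of
the signal: electrode gain and offset drop out by construction.

Two conventions are fixed here because they silently differ between
implementations:

- **Tie-breaking** is stable: of two equal samples the earlier one receives
  the lower rank. Digitized voltages do tie occasionally, and stable
  ranking is what reference ordinal-pattern implementations do.
- **Pattern indexing** is the lexicographic rank of the sorting
  permutation (`pattern_index()`), making pattern ids comparable across
  software.

The defaults are $D = 6$, $\tau = 1$ sample, and non-overlapping 15 s
windows; at 200 Hz a window holds $M = 3000$ samples ($n = 2995$ vectors).
The histogram-quality rule $M \gg D!$ is enforced softly: below
$5 \cdot D!$ vectors `bp_pdf()` warns but proceeds (the threshold is the
`min_factor` knob of `embedding_config()`), since a hard cutoff would
forbid the standard $D = 6$ / 15 s configuration ($2995 < 5 \cdot 720$)
that the field uses deliberately, and the $D = 5$ analysis
($5! = 120 \ll 2995$) exists precisely to confirm conclusions are not an
undersampling artifact.

Windows containing a constant run of at least half a second are flagged as
padding and excluded from quantifier accumulation by default
(`window_iter()`, `channel_quantifiers(drop_padding = )`). Records in
fixed-length archives are commonly zero-padded at the tail; a constant
stretch would otherwise concentrate mass on the single monotone pattern
and bias both quantifiers downward. The flag is overridable because the
right handling of padded stretches is a genuinely open choice; excluding
them is the conservative one.

## Entropy, disequilibrium, complexity

All logarithms are base 2 and $0 \log 0 \equiv 0$; probabilities below
$10^{-15}$ are treated as exact zeros. From a pattern distribution $P$
over $N = D!$ states:

$$S[P] = -\sum_j p_j \log_2 p_j, \qquad H[P] = S[P] / \log_2 N \in [0, 1].$$

The Jensen–Shannon divergence from the uniform distribution $P_e$ is
evaluated with normalized entropies,
$J[P, P_e] = H[(P+P_e)/2] - H[P]/2 - H[P_e]/2$, and the disequilibrium is
$Q_J = Q_0 J$ with $Q_0 = 1 / J[P_\delta, P_e]$ computed numerically from
the same $J$ routine ($P_\delta$ any point mass) rather than transcribed
from a closed form. Because $H = S/\log_2 N$, the $\log_2 N$ factors cancel
in the product, so the complexity

$$C = Q_0 \, J[P, P_e] \, H[P]$$

is identical under the normalized- and unnormalized-entropy conventions;
the numerical $Q_0$ also removes any risk of a mistranscribed constant.
$C$ vanishes at both extremes — point mass ($H = 0$) and uniformity
($J = 0$) — and is positive for structured dynamics. The fully chaotic
logistic map at $D = 6$ sits at $H \approx 0.63$, $C \approx 0.48$ (the
test suite asserts the high-complexity band $C > 0.3$, not an exact
value, since the exact number depends on series length).

## Welch spectral estimation

`welch_psd()` averages Hamming-windowed, mean-detrended periodograms of
2 s blocks advanced by 1 s. The pipeline applies it to the first 60 s of
each record, which yields exactly 59 blocks at these settings and a 0.5 Hz
resolution; using the full 68 s of a padded record would both change the
block count and average in the zero tail. Spectra are one-sided,
restricted to [0.5, 100) Hz — the DC bin is dropped because it is
meaningless after zero-padding and mean-detrending — and normalized to
unit total power, so estimates are independent of amplitude and comparable
across electrodes.

Band powers use conventional clinical edges, delta [0.5, 4), theta
[4, 8), alpha [8, 13), beta [13, 30), gamma [30, 100) Hz
(`band_scheme()`), which are a configuration choice, not a measurement.
Spectral peaks are located by the argmax of the (group-median) PSD within
a 3–30 Hz search band (`psd_peak_frequency()`): on a 1/f-like background
the global argmax is always the lowest bin, so an unrestricted search
cannot see an oscillatory peak; 3–30 Hz covers the theta/alpha/beta range
where wake iEEG peaks occur.

## Cohort rules and age matching

Groups are (region, hemisphere) cells; eligibility requires at least five
*distinct patients* of each sex (channels never count). Age summaries use
the sample standard deviation over distinct patients.

Age-matched subsampling selects $k = 5$ patients per sex minimizing
$|\bar a_F - \bar a_M| + \lambda (s_F + s_M)$ with $\lambda = 0.1$. The
two stated goals — equalize mean ages, shrink spreads — do not define a
unique objective; a weighted sum with mean-difference priority is the
simplest formalization and $\lambda$ is exposed. The search is exhaustive
over all subset pairs when $\binom{n_F}{k}\binom{n_M}{k} \le 4 \times 10^6$
(all cohorts up to roughly 14 patients per sex at $k = 5$; a fully
exhaustive search at 25 per sex would need $2.8 \times 10^9$ pairs),
otherwise a seeded 10,000-draw random search under the same objective.
Ties are broken by lexicographic patient-id order so reruns are identical.

## Group comparison

Window-level quantifier values are pooled across channels and patients of
each sex and compared with a Mann–Whitney U test: exact null distribution
when the smaller sample has at most 8 observations and no ties, otherwise
the normal approximation with tie and continuity corrections. The binary
indicator is $h = \mathbf 1\{p < \alpha\}$ with $\alpha = 0.05$ and a
*strict* inequality. Pooling windows treats them as exchangeable and
ignores within-patient correlation (pseudo-replication); the simulation
results below quantify what this costs under the generator's assumptions,
but inference on real data should be read with that caveat.

The Benjamini–Hochberg step-up correction is applied per family, a family
being all eligible (region × hemisphere) tests for one
(analysis, quantifier, $D$) configuration; decisions are
`adjusted < q` with $q = 0.05$. Boxplot summaries follow Tukey
conventions — type-7 quartiles, whiskers at the most extreme points within
$1.5 \cdot \mathrm{IQR}$, notch $\mathrm{median} \pm 1.57\,
\mathrm{IQR}/\sqrt n$ as an approximate 95% CI of the median.

## The synthetic generator

`gen_cohort()` emulates the *structure* of a wake iEEG archive: per-sex
patient counts (default 5 + 5, the eligibility minimum), two channels per
patient, 68 s records at 200 Hz ending in 8 s of exact zeros (13,600
samples), ages from normal laws truncated to [18, 65] years (female
mean 30, male mean 35, sd 10 — the range archive age tables report),
and per-channel signals that are colored noise of exponent $\beta$ plus a
narrow-band Gaussian spectral bump at a configurable frequency carrying a
configurable fraction of total variance (default 0.3, a prominent but not
dominant rhythm; width 0.5 Hz). Group differences are injected as per-sex
values of $\beta$ and peak frequency. Every (patient, channel) pair uses
a private RNG stream derived from the master seed, so generation is
reproducible and independent of insertion order.

One numerical choice deserves emphasis: signals are synthesized in the
frequency domain with a *complex-Gaussian* spectrum — Rayleigh-distributed
amplitudes and uniform phases — not with deterministic amplitudes and
random phases only. Pure phase randomization fixes each realization's
energy at every frequency, which couples disjoint analysis windows of a
channel through a shared energy budget; window-level statistics then
correlate negatively within a channel and the pooled rank test becomes
radically conservative (measured null rejection ≈ 0 instead of 0.05).
Gaussian synthesis produces a genuinely stationary process with the same
expected spectrum, and the measured type-I error of the full pipeline is
then nominal (≈ 0.05–0.06 at $\alpha = 0.05$ over 1000 null cohorts).

What the generator does *not* emulate: physiological nonstationarity,
artifacts (line noise, spikes, movement), non-Gaussian or nonlinear
dynamics, inter-channel correlation within a patient, and any realistic
effect size — injected contrasts are free parameters, not estimates of
real sex differences. Passing the simulation suite therefore shows the
pipeline is calibrated and sensitive under Gaussian stationary conditions,
not that real cohorts satisfy those conditions.

## Problem sizes used in validation

The test suite validates the ordinal core against a naive sorting oracle
(100 random series, $M \le 200$, $D \le 4$, exact equality), white-noise
uniformity at $M = 10^5$, the logistic-map forbidden pattern at
$M = 10^5$ and its plane position at $M = 10^6$, type-I error over 1000
null cohorts (5 + 5 patients × 2 channels × 4 windows, $D = 6$), and
power plus peak recovery over 100 contrast cohorts. The acceptance script
re-runs the same computations at 400 null and 100 contrast cohorts.

## Known limitations

- Window pooling ignores the patient hierarchy; a mixed-effects or
  cluster-robust alternative is out of scope here.
- The exact Mann–Whitney branch is limited to tie-free small samples; with
  ties the corrected normal approximation is used regardless of size.
- The EDF reader covers plain 16-bit EDF (continuous records), not EDF+
  annotations.
- Band edges, the PSD segment span (first 60 s), and the age-matching
  objective are documented conventions; alternatives are exposed as
  configuration, and conclusions sensitive to them should be checked
  against those knobs.
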