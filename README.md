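# entroplane

Ordinal-pattern entropy and statistical complexity analysis of intracranial
EEG (iEEG) cohorts, with sex/region/hemisphere group comparison and Welch
spectral summaries.

## The problem and who this is for

Intracranial EEG channels record local field potentials whose dynamics are
nonlinear and noisy; classical amplitude statistics miss their ordinal
(causal) structure. A standard way to characterize such signals is to
symbolize each analysis window by its Bandt–Pompe ordinal patterns — the
permutations that sort consecutive delay-embedded samples — and summarize
the resulting pattern distribution P by two dimensionless quantifiers:

- normalized permutation Shannon entropy
  `H[P] = S[P] / log2(N)`, with `S[P] = −Σ_j p_j log2 p_j` and `N = D!`
  patterns for embedding dimension `D`;
- Martin–Plastino–Rosso (MPR) statistical complexity
  `C = Q_J[P, P_e] · H[P]`, where `Q_J = Q_0 · J[P, P_e]` is the normalized
  Jensen–Shannon disequilibrium between P and the uniform distribution
  `P_e`, and `Q_0` scales the divergence so `Q_J ∈ [0, 1]`.

`(H, C)` locates every window on the complexity–entropy causality plane:
white noise sits at `(≈1, ≈0)`, fully ordered signals at `(0, 0)`, and
chaotic dynamics in the high-complexity band in between. The frequency
domain is covered by an amplitude-independent Welch power spectral density
(2 s Hamming blocks, 1 s step, total-power normalization).

The package is aimed at neurophysiology groups comparing such quantifiers
across patient cohorts: channels are grouped by brain region, hemisphere
and sex, groups need at least five patients of each sex to be analyzed,
window-level quantifier values are pooled per sex and compared with
Mann–Whitney U tests, and the per-family Benjamini–Hochberg FDR correction
controls for the many regions tested. An age-matched subsampling mode
selects five patients per sex minimizing age differences between the sexes.

Because clinical iEEG cannot be redistributed, the package ships a
synthetic-cohort generator (`gen_cohort()`): 1/f-like colored-noise
channels with narrow-band oscillatory peaks, per-sex generative parameters,
zero-padded record tails, and a metadata table — enough structure to
exercise and validate every stage of the pipeline without any download.
Real recordings are read from EDF files plus a channel metadata CSV.

## Worked example

Simulate a cohort with an injected sex contrast — females with a steep
spectral exponent (beta = 2) and a 7 Hz peak, males with white background
(beta = 0) and a 10 Hz peak — and run the full pipeline:

```r
library(entroplane)
eff <- group_effect(beta_female = 2, beta_male = 0,
                    peak_freq_female = 7, peak_freq_male = 10)
coh <- gen_cohort(cohort_spec(effect = eff, seed = 1))
res <- run_pipeline(run_config(), cohort = coh)

res$comparison_table[, c("quantifier", "D", "median_female", "median_male",
                         "p_value", "h")]
#>   quantifier D median_female median_male  p_value h
#> 1          H 6         0.384      0.9760 1.44e-14 1
#> 2          C 6         0.305      0.0592 1.44e-14 1
#> 3          H 5         0.428      0.9935 1.44e-14 1
#> 4          C 5         0.284      0.0115 1.44e-14 1

res$psd_peaks
#>                region hemisphere sex n_channels peak_freq_hz
#> 1 supramarginal gyrus          L   F         10            7
#> 2 supramarginal gyrus          L   M         10           10
```

The steep-exponent female channels are far less entropic (median H ≈ 0.38
vs ≈ 0.98 at D = 6) and far more complex (median C ≈ 0.31 vs ≈ 0.06) than
the near-white male channels; the Mann–Whitney test rejects at every
configuration (`h = 1`), and the group-median Welch spectra recover the
injected 7 and 10 Hz peaks exactly. `res` also carries the per-region age
table, the FDR-corrected decisions, per-group PSD median/IQR curves, the
window-level `(H, C)` plane points and notched boxplot summaries; with
`run_config(output_dir = ...)` everything is written as CSV plus a JSON
run manifest.

The same analysis runs from the shell:

```sh
Rscript inst/cli/entroplane.R simulate --out cohort --seed 1 \
    --beta-female 2 --beta-male 0 --peak-freq-female 7 --peak-freq-male 10
Rscript inst/cli/entroplane.R analyze --input cohort --out report
```

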