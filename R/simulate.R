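#' Monte-Carlo sex-comparison simulation on synthetic cohorts
#'
#' Repeatedly generates a two-sex cohort under a given [group_effect()],
#' computes the windowed entropy-complexity points per channel at embedding
#' dimension `D`, runs the pooled Mann-Whitney comparison for both
#' quantifiers, and (optionally) the group-median Welch PSD peak per sex.
#' With an identical-law effect (the default) the rejection rate estimates
#' the type-I error of the pipeline; with a real difference it estimates
#' power and effect recovery.
#'
#' @param n_seeds number of replicate cohorts.
#' @param effect a [group_effect()] shared by all replicates.
#' @param D embedding dimension.
#' @param alpha Mann-Whitney significance level.
#' @param include_psd also compute per-sex group-median PSD peak frequencies
#'   (first `psd_seconds` of each record, peak searched in `peak_band`).
#' @param psd_seconds,peak_band see [run_config()].
#' @param base_seed cohort `i` uses seed `base_seed + i`.
#' @param ... further arguments to [cohort_spec()] (patient counts,
#'   channels, duration, fs, ...).
#' @return `data.frame` with one row per seed: `seed`, `p_H`, `p_C`, `h_H`,
#'   `h_C`, and with `include_psd` also `peak_female_hz`, `peak_male_hz`.
#' @export
simulate_sex_comparison <- function(n_seeds, effect = group_effect(),
                                    D = 6L, alpha = 0.05,
                                    include_psd = FALSE, psd_seconds = 60,
                                    peak_band = c(3, 30), base_seed = 0L, ...) {
  emb <- embedding_config(D = D)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    spec <- cohort_spec(effect = effect, seed = base_seed + i, ...)
    coh <- gen_cohort(spec)
    sexes <- vapply(coh$records, function(r) r$sex, character(1))
    pts <- lapply(coh$records, channel_quantifiers, cfg = emb)
    pf <- do.call(rbind, pts[sexes == "F"])
    pm <- do.call(rbind, pts[sexes == "M"])
    p_H <- mann_whitney_u(pf$H, pm$H)$p
    p_C <- mann_whitney_u(pf$C, pm$C)$p
    row <- data.frame(seed = base_seed + i, p_H = p_H, p_C = p_C,
                      h_H = h_index(p_H, alpha), h_C = h_index(p_C, alpha))
    if (include_psd) {
      n_use <- as.integer(round(min(psd_seconds, spec$duration_s) * spec$fs))
      peak <- function(sx) {
        ests <- lapply(coh$records[sexes == sx], function(r)
          welch_psd(r$x[seq_len(min(n_use, length(r$x)))], r$fs))
        psd_peak_frequency(group_psd_summary(ests), band = peak_band)
      }
      row$peak_female_hz <- peak("F")
      row$peak_male_hz <- peak("M")
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
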