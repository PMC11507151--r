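#' Pipeline run configuration
#'
#' Collects every analysis parameter in one object. The defaults reproduce
#' the standard wake-iEEG configuration: ordinal embedding dimensions 6 and
#' 5 with delay 1 sample, 15 s non-overlapping quantifier windows, Welch PSD
#' on the first 60 s of each record with 2 s Hamming blocks advanced by 1 s
#' (59 blocks, 0.5 Hz resolution), eligibility of at least 5 patients per
#' sex per (region, hemisphere), Mann-Whitney tests at alpha = 0.05 and
#' Benjamini-Hochberg FDR at q = 0.05.
#'
#' @param input_dir directory with `metadata.csv` plus `signals.csv` or
#'   `*.edf` (ignored when a cohort is passed to [run_pipeline()] directly).
#' @param output_dir directory for report files, or `NULL` for in-memory
#'   results only.
#' @param D_list ordinal embedding dimensions analyzed.
#' @param tau embedding delay in samples.
#' @param window_s quantifier window length in seconds.
#' @param min_patients_per_sex cohort eligibility threshold.
#' @param alpha Mann-Whitney significance level.
#' @param fdr_q FDR level of the BH correction.
#' @param bands a [band_scheme()].
#' @param psd_seconds seconds of signal (from record start) used for the
#'   Welch PSD.
#' @param peak_band `c(low, high)` Hz search band for [psd_peak_frequency()].
#' @param age_match also run the age-matched subsample analysis.
#' @param age_match_k patients per sex in the age-matched subsample.
#' @param fs_expected expected sampling rate in Hz.
#' @param seed integer seed (age-match random-search fallback and any other
#'   stochastic step).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL,
                       D_list = c(6L, 5L), tau = 1L, window_s = 15,
                       min_patients_per_sex = 5L, alpha = 0.05, fdr_q = 0.05,
                       bands = band_scheme(), psd_seconds = 60,
                       peak_band = c(3, 30), age_match = FALSE,
                       age_match_k = 5L, fs_expected = 200, seed = 1L) {
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         D_list = as.integer(D_list), tau = as.integer(tau),
         window_s = window_s,
         min_patients_per_sex = as.integer(min_patients_per_sex),
         alpha = alpha, fdr_q = fdr_q, bands = bands,
         psd_seconds = psd_seconds, peak_band = peak_band,
         age_match = isTRUE(age_match), age_match_k = as.integer(age_match_k),
         fs_expected = fs_expected, seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full cohort analysis pipeline
#'
#' End-to-end orchestration: load (or accept in-memory) signals and channel
#' metadata, group channels by region/hemisphere and evaluate eligibility,
#' compute windowed entropy-complexity points per channel for every
#' embedding dimension in `cfg$D_list`, Welch PSDs per channel, and per
#' eligible group the sex comparison (Mann-Whitney, h at `alpha`) with a
#' BH-FDR correction across each (quantifier, D) family. With
#' `cfg$age_match = TRUE` the comparison and FDR tables are additionally
#' computed on age-matched subsamples of `cfg$age_match_k` patients per sex.
#'
#' @param cfg a [run_config()].
#' @param cohort optional in-memory cohort (list with `records`,
#'   `metadata`, e.g. from [gen_cohort()]); when `NULL`, data are read from
#'   `cfg$input_dir`.
#' @return Object of class `pipeline_result`: list with `age_table`,
#'   `comparison_table`, `fdr_table`, `psd_summary` (long data.frame of
#'   per-group median/quartile curves), `psd_peaks`, `plane_points`,
#'   `boxplot_table`, and `manifest`. When `cfg$output_dir` is set the
#'   tables are also written as CSV plus a JSON run manifest.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cohort)) {
    if (is.null(cfg$input_dir)) stop("cfg$input_dir is required without an in-memory cohort")
    metadata <- read_metadata(file.path(cfg$input_dir, "metadata.csv"))
    records <- read_signals(cfg$input_dir, metadata, cfg$fs_expected)
  } else {
    metadata <- cohort$metadata
    records <- cohort$records
  }
  names(records) <- vapply(records, function(r) r$channel_id, character(1))

  groups <- build_groups(metadata, cfg$min_patients_per_sex)
  age_table <- do.call(rbind, lapply(groups, function(g) {
    s <- age_summary(g)
    cbind(region = g$region, hemisphere = g$hemisphere, s,
          eligible = g$eligible)
  }))
  eligible <- Filter(function(g) g$eligible, groups)
  if (length(eligible) == 0L)
    warning("no (region, hemisphere) group meets the patient-per-sex minimum; report is empty")

  # Quantifier points for every channel in an eligible group, per D.
  cfgs <- lapply(cfg$D_list, function(D)
    embedding_config(D = D, tau = cfg$tau, window_s = cfg$window_s))
  plane_points <- list()
  for (g in eligible) {
    gmeta <- rbind(g$female, g$male)
    for (i in seq_along(cfg$D_list)) {
      for (j in seq_len(nrow(gmeta))) {
        rec <- records[[gmeta$channel_id[j]]]
        qp <- channel_quantifiers(rec, cfgs[[i]])
        if (nrow(qp) == 0L) next
        plane_points[[length(plane_points) + 1L]] <- cbind(
          region = g$region, hemisphere = g$hemisphere,
          patient_id = gmeta$patient_id[j], sex = gmeta$sex[j],
          D = cfg$D_list[i], qp)
      }
    }
  }
  plane_points <- if (length(plane_points)) do.call(rbind, plane_points) else
    data.frame(region = character(), hemisphere = character(),
               patient_id = character(), sex = character(), D = integer(),
               channel_id = character(), window_index = integer(),
               H = numeric(), C = numeric(), n_vectors = integer())

  analyses <- list(full = eligible)
  if (cfg$age_match && length(eligible) > 0L)
    analyses$age_matched <- lapply(eligible, age_matched_subsample,
                                   k = cfg$age_match_k, seed = cfg$seed)

  comparison_table <- list()
  boxplot_table <- list()
  for (an in names(analyses)) {
    for (g in analyses[[an]]) {
      for (D in cfg$D_list) {
        for (qn in c("H", "C")) {
          pts <- plane_points[plane_points$region == g$region &
                                plane_points$hemisphere == g$hemisphere &
                                plane_points$D == D, ]
          pf <- pts[pts$patient_id %in% unique(g$female$patient_id), ]
          pm <- pts[pts$patient_id %in% unique(g$male$patient_id), ]
          if (nrow(pf) == 0L || nrow(pm) == 0L) next
          row <- compare_region(pf, pm, quantifier = qn, alpha = cfg$alpha,
                                region = g$region, hemisphere = g$hemisphere,
                                D = D)
          comparison_table[[length(comparison_table) + 1L]] <-
            cbind(analysis = an, row)
          for (sx in c("F", "M")) {
            bs <- boxplot_summary((if (sx == "F") pf else pm)[[qn]])
            boxplot_table[[length(boxplot_table) + 1L]] <- data.frame(
              analysis = an, region = g$region, hemisphere = g$hemisphere,
              D = D, quantifier = qn, sex = sx, n = bs$n, median = bs$median,
              q1 = bs$q1, q3 = bs$q3, whisker_lo = bs$whisker_lo,
              whisker_hi = bs$whisker_hi, notch_lo = bs$notch_lo,
              notch_hi = bs$notch_hi, n_outliers = length(bs$outliers))
          }
        }
      }
    }
  }
  comparison_table <- if (length(comparison_table))
    do.call(rbind, comparison_table) else
    data.frame(analysis = character(), region = character(),
               hemisphere = character(), quantifier = character(),
               D = integer(), p_value = numeric(), h = integer())
  boxplot_table <- if (length(boxplot_table)) do.call(rbind, boxplot_table)
    else data.frame()

  # BH-FDR families: all eligible (region x hemisphere) tests for one
  # (analysis, quantifier, D) configuration.
  fdr_table <- list()
  if (nrow(comparison_table) > 0L) {
    fam <- split(seq_len(nrow(comparison_table)),
                 interaction(comparison_table$analysis,
                             comparison_table$quantifier,
                             comparison_table$D, drop = TRUE))
    for (idx in fam) {
      fc <- bh_fdr(comparison_table$p_value[idx], q = cfg$fdr_q)
      fdr_table[[length(fdr_table) + 1L]] <- data.frame(
        analysis = comparison_table$analysis[idx],
        region = comparison_table$region[idx],
        hemisphere = comparison_table$hemisphere[idx],
        quantifier = comparison_table$quantifier[idx],
        D = comparison_table$D[idx],
        p_value = comparison_table$p_value[idx],
        p_corrected = fc$adjusted, h_corrected = as.integer(fc$reject))
    }
  }
  fdr_table <- if (length(fdr_table)) do.call(rbind, fdr_table) else
    data.frame()

  # Per-group PSD median/IQR curves and dominant peaks.
  psd_summary <- list(); psd_peaks <- list()
  for (g in eligible) {
    for (sx in c("F", "M")) {
      gmeta <- if (sx == "F") g$female else g$male
      ests <- lapply(gmeta$channel_id, function(cid) {
        rec <- records[[cid]]
        n_use <- min(length(rec$x), as.integer(round(cfg$psd_seconds * rec$fs)))
        welch_psd(rec$x[seq_len(n_use)], rec$fs, channel_id = cid)
      })
      sm <- group_psd_summary(ests)
      psd_summary[[length(psd_summary) + 1L]] <- cbind(
        region = g$region, hemisphere = g$hemisphere, sex = sx, sm)
      psd_peaks[[length(psd_peaks) + 1L]] <- data.frame(
        region = g$region, hemisphere = g$hemisphere, sex = sx,
        n_channels = length(ests),
        peak_freq_hz = psd_peak_frequency(sm, band = cfg$peak_band))
    }
  }
  psd_summary <- if (length(psd_summary)) do.call(rbind, psd_summary) else
    data.frame()
  psd_peaks <- if (length(psd_peaks)) do.call(rbind, psd_peaks) else
    data.frame()

  manifest <- list(
    package = "entroplane",
    version = as.character(utils::packageVersion("entroplane")),
    seed = cfg$seed,
    # run-location paths are excluded: the manifest describes the analysis,
    # and identical configurations must produce identical manifests
    config = cfg[setdiff(names(cfg), c("bands", "input_dir", "output_dir"))],
    bands = cfg$bands$edges,
    n_channels = length(records),
    n_groups = length(groups), n_eligible = length(eligible))

  result <- structure(
    list(age_table = age_table, comparison_table = comparison_table,
         fdr_table = fdr_table, psd_summary = psd_summary,
         psd_peaks = psd_peaks, plane_points = plane_points,
         boxplot_table = boxplot_table, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_result(result, cfg$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("entroplane pipeline result: %d/%d eligible groups, %d comparison rows, %d plane points\n",
              x$manifest$n_eligible, x$manifest$n_groups,
              nrow(x$comparison_table), nrow(x$plane_points)))
  invisible(x)
}

# Write the report bundle: CSV tables + JSON manifest.
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("age_table", "comparison_table", "fdr_table", "psd_summary",
            "psd_peaks", "plane_points", "boxplot_table")
  for (tb in tabs)
    data.table::fwrite(result[[tb]], file.path(dir, paste0(tb, ".csv")))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
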