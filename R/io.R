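#' Read and validate a channel metadata table
#'
#' Reads a CSV with one row per channel and normalizes it for the cohort
#' stage: required columns `patient_id`, `sex`, `age`, `region`,
#' `hemisphere`, `channel_id` (any order; extra columns are preserved), ages
#' coerced to numeric, sex labels normalized to `F`/`M` from common aliases
#' (`female`, `f`, `woman`, `male`, `m`, `man`, case-insensitive), hemisphere
#' normalized to `L`/`R` from `left`/`right`.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: %s", path))
  meta <- as.data.frame(data.table::fread(path))
  req <- c("patient_id", "sex", "age", "region", "hemisphere", "channel_id")
  for (col in intersect(c("patient_id", "sex", "region", "hemisphere", "channel_id"),
                        names(meta)))
    meta[[col]] <- as.character(meta[[col]])
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stop(sprintf("metadata is missing required columns: %s",
                 paste(miss, collapse = ", ")))
  sex_map <- c(f = "F", female = "F", woman = "F",
               m = "M", male = "M", man = "M")
  sx <- tolower(trimws(as.character(meta$sex)))
  bad <- !(sx %in% names(sex_map))
  if (any(bad))
    stop(sprintf("unrecognized sex label(s) in rows: %s",
                 paste(which(bad), collapse = ", ")))
  meta$sex <- unname(sex_map[sx])
  hemi_map <- c(l = "L", left = "L", r = "R", right = "R")
  hm <- tolower(trimws(as.character(meta$hemisphere)))
  bad <- !(hm %in% names(hemi_map))
  if (any(bad))
    stop(sprintf("unrecognized hemisphere label(s) in rows: %s",
                 paste(which(bad), collapse = ", ")))
  meta$hemisphere <- unname(hemi_map[hm])
  ages <- suppressWarnings(as.numeric(meta$age))
  if (anyNA(ages))
    stop(sprintf("unparseable age in rows: %s",
                 paste(which(is.na(ages)), collapse = ", ")))
  meta$age <- ages
  if (anyDuplicated(meta$channel_id))
    stop("duplicate channel_id values in metadata")
  meta
}

#' Write a synthetic cohort to disk
#'
#' Writes `metadata.csv` (columns `patient_id`, `sex`, `age`, `region`,
#' `hemisphere`, `channel_id`, `fs_hz`) plus the signals, either as a single
#' wide `signals.csv` (one column per channel, `format = "csv"`) or as one
#' EDF file per patient (`format = "edf"`). Both layouts are readable by
#' [read_signals()].
#'
#' @param cohort a list with `records` and `metadata`, as from [gen_cohort()].
#' @param dir output directory (created if absent).
#' @param format `"csv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.csv"))
  if (format == "csv") {
    sig <- as.data.frame(lapply(cohort$records, function(r) r$x))
    names(sig) <- vapply(cohort$records, function(r) r$channel_id, character(1))
    data.table::fwrite(sig, file.path(dir, "signals.csv"))
  } else {
    pids <- vapply(cohort$records, function(r) r$patient_id, character(1))
    for (pid in unique(pids)) {
      recs <- cohort$records[pids == pid]
      write_edf(recs, file.path(dir, paste0(pid, ".edf")))
    }
  }
  invisible(dir)
}

#' Read signal records from a cohort directory
#'
#' Loads channel voltage series from either a wide `signals.csv` (one column
#' per channel) or a set of `.edf` files in `path`, joins them to `metadata`
#' on `channel_id`, and verifies the sampling rate. Channels present in the
#' signal files but absent from the metadata are an error (orphans are
#' listed); metadata rows without signals are likewise reported.
#'
#' @param path directory holding `signals.csv` or `*.edf`.
#' @param metadata validated metadata table (see [read_metadata()]); its
#'   `fs_hz` column, when present, is checked against the signals.
#' @param fs_expected expected sampling rate in Hz.
#' @return List of [signal_record()].
#' @export
read_signals <- function(path, metadata, fs_expected = 200) {
  csv <- file.path(path, "signals.csv")
  edfs <- sort(list.files(path, pattern = "\\.edf$", full.names = TRUE))
  if (file.exists(csv)) {
    sig <- as.data.frame(data.table::fread(csv))
    if (nrow(sig) == 0L) stop(sprintf("empty signal file: %s", csv))
    channels <- lapply(sig, as.numeric)
    # CSV bundles carry no rate; take it from metadata fs_hz when available
    fs_by_channel <- rep(fs_expected, length(channels))
    names(fs_by_channel) <- names(channels)
    if ("fs_hz" %in% names(metadata)) {
      known <- intersect(names(channels), metadata$channel_id)
      fs_by_channel[known] <-
        metadata$fs_hz[match(known, metadata$channel_id)]
    }
  } else if (length(edfs) > 0L) {
    channels <- list(); fs_by_channel <- numeric()
    for (f in edfs) {
      edf <- read_edf(f)
      for (i in seq_along(edf$signals)) {
        lab <- edf$labels[i]
        channels[[lab]] <- edf$signals[[i]]
        fs_by_channel[lab] <- edf$fs[i]
      }
    }
  } else {
    stop(sprintf("no signals.csv or *.edf found under %s", path))
  }
  orphans <- setdiff(names(channels), metadata$channel_id)
  if (length(orphans) > 0L)
    stop(sprintf("channels missing from metadata: %s",
                 paste(orphans, collapse = ", ")))
  missing_sig <- setdiff(metadata$channel_id, names(channels))
  if (length(missing_sig) > 0L)
    stop(sprintf("metadata channels without signals: %s",
                 paste(missing_sig, collapse = ", ")))
  lapply(seq_len(nrow(metadata)), function(i) {
    cid <- metadata$channel_id[i]
    fs <- fs_by_channel[[cid]]
    x <- channels[[cid]]
    if (!isTRUE(all.equal(fs, fs_expected))) {
      warning(sprintf("channel %s sampled at %g Hz; resampling to %g Hz",
                      cid, fs, fs_expected))
      x <- resample_linear(x, fs, fs_expected)
      fs <- fs_expected
    }
    signal_record(x, fs, channel_id = cid,
                  patient_id = metadata$patient_id[i], sex = metadata$sex[i],
                  age = metadata$age[i], region = metadata$region[i],
                  hemisphere = metadata$hemisphere[i])
  })
}

# Linear-interpolation resampling onto the target rate's time grid.
resample_linear <- function(x, fs_in, fs_out) {
  t_in <- (seq_along(x) - 1) / fs_in
  n_out <- floor(t_in[length(t_in)] * fs_out) + 1
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}
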