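# Minimal EDF (European Data Format) i/o: 16-bit integer signals, one data
# record per second. Covers plain EDF only (no EDF+ annotations or
# discontinuous records), which is all a resampled fixed-length iEEG export
# needs. Field layout follows the published EDF header specification.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write signal records to an EDF file
#'
#' Encodes each channel as a 16-bit EDF signal with per-channel physical
#' scaling (physical min/max taken from the data range), one data record per
#' second. All channels must share one sampling rate and an integer-second
#' common duration; series are truncated to whole records.
#'
#' @param records list of [signal_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(records, path) {
  stopifnot(length(records) >= 1L)
  fs <- unique(vapply(records, function(r) r$fs, numeric(1)))
  if (length(fs) != 1L) stop("all channels in one EDF must share the sampling rate")
  ns <- length(records)
  n_rec <- min(vapply(records, function(r) length(r$x) %/% r$fs, numeric(1)))
  if (n_rec < 1L) stop("signals shorter than one 1 s data record")
  spr <- as.integer(fs)
  con <- file(path, "wb")
  on.exit(close(con))
  pid <- records[[1]]$patient_id
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field(if (is.na(pid)) "X" else pid, 80L),
    pad_field("Startdate X", 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (ns + 1L), 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L), pad_field(1L, 8L), pad_field(ns, 4L))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(records[[i]]$x)
    if (rng[1] == rng[2]) rng <- rng + c(-1, 1)
    phys_min[i] <- rng[1]; phys_max[i] <- rng[2]
  }
  field <- function(vals, width)
    paste(vapply(vals, pad_field, character(1), width = width), collapse = "")
  sig_hdr <- paste0(
    field(vapply(records, function(r) r$channel_id, character(1)), 16L),
    field(rep("", ns), 80L),
    field(rep("uV", ns), 8L),
    field(formatC(phys_min, format = "g", digits = 7), 8L),
    field(formatC(phys_max, format = "g", digits = 7), 8L),
    field(rep(-32768L, ns), 8L),
    field(rep(32767L, ns), 8L),
    field(rep("", ns), 80L),
    field(rep(spr, ns), 8L),
    field(rep("", ns), 32L))
  writeChar(sig_hdr, con, nchars = nchar(sig_hdr), eos = NULL)
  dig <- lapply(seq_len(ns), function(i) {
    x <- records[[i]]$x[seq_len(n_rec * spr)]
    as.integer(round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the header and the 16-bit data records of a plain EDF file,
#' rescaling each signal to physical units.
#'
#' @param path EDF file.
#' @return List with `labels`, `fs` (per-signal sampling rates), `signals`
#'   (list of numeric series), `n_records`, `record_duration_s`,
#'   `patient_id`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  if (file.size(path) < 256) stop(sprintf("not a valid EDF file (too short): %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8L)
  patient <- rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L)); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L || is.na(n_rec))
    stop(sprintf("corrupt EDF header in %s", path))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  invisible(vapply(seq_len(ns), function(i) rd(80L), character(1)))
  invisible(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  invisible(vapply(seq_len(ns), function(i) rd(80L), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  invisible(vapply(seq_len(ns), function(i) rd(32L), character(1)))
  seek(con, header_bytes)
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[i]) stop(sprintf("truncated EDF data in %s", path))
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      signals[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        phys_min[i] + (raw - dig_min[i]) * scale
    }
  }
  list(labels = labels, fs = spr / rec_dur, signals = signals,
       n_records = n_rec, record_duration_s = rec_dur, patient_id = patient)
}
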