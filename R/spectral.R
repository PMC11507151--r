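#' Welch power spectral density, normalized to unit total power
#'
#' Averages Hamming-windowed periodograms over overlapping blocks of
#' `block_s` seconds advanced by `step_s` seconds (defaults 2 s / 1 s, the
#' standard wake-iEEG segmentation: a 60 s record at these settings yields
#' exactly 59 blocks and a 0.5 Hz frequency resolution). Each block is
#' mean-detrended before windowing. The one-sided spectrum is restricted to
#' `freq_range` (default 0.5-100 Hz, excluding the DC bin, which is
#' meaningless for zero-padded records) and normalized to sum to 1, making
#' the estimate independent of signal amplitude.
#'
#' @param x numeric series of at least `block_s * fs` samples.
#' @param fs sampling rate in Hz.
#' @param block_s block duration in seconds.
#' @param step_s step between block starts in seconds.
#' @param freq_range `c(low, high)`: bins with `low <= f < high` are kept.
#' @param channel_id optional label carried on the estimate.
#' @return Object of class `spectral_estimate`: list with `freqs` (Hz,
#'   strictly increasing), `power` (non-negative, sums to 1), `n_blocks`,
#'   `df` (Hz resolution), `fs`, `channel_id`.
#' @examples
#' est <- welch_psd(gen_colored_noise(12000, 200, 1, seed = 1), fs = 200)
#' est$n_blocks   # 59
#' @export
welch_psd <- function(x, fs, block_s = 2, step_s = 1,
                      freq_range = c(0.5, 100), channel_id = NA_character_) {
  stopifnot(fs > 0, block_s > 0, step_s > 0)
  nblk <- as.integer(round(block_s * fs))
  nstep <- as.integer(round(step_s * fs))
  if (length(x) < nblk)
    stop(sprintf("series too short: %d samples < one %g s block", length(x), block_s))
  n_blocks <- (length(x) - nblk) %/% nstep + 1L
  win <- signal::hamming(nblk)
  m <- nblk %/% 2L
  acc <- numeric(m)
  for (b in seq_len(n_blocks)) {
    seg <- x[((b - 1L) * nstep + 1L):((b - 1L) * nstep + nblk)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[2:(m + 1L)]  # one-sided, DC dropped
  }
  freqs <- (1:m) * fs / nblk
  keep <- freqs >= freq_range[1] & freqs < min(freq_range[2], fs / 2)
  freqs <- freqs[keep]
  pw <- acc[keep]
  pw <- pw / sum(pw)
  structure(
    list(freqs = freqs, power = pw, n_blocks = n_blocks, df = fs / nblk,
         fs = fs, channel_id = as.character(channel_id)),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("Welch PSD %s: %d blocks, %g Hz resolution, %g-%g Hz\n",
              x$channel_id, x$n_blocks, x$df, min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Pointwise median and quartile PSD across channels
#'
#' Summarizes a group of spectral estimates on a common frequency grid by
#' the pointwise median and first/third quartiles — the solid line and IQR
#' band of a group PSD figure.
#'
#' @param estimates list of [welch_psd()] results sharing one frequency grid.
#' @return `data.frame` with columns `freq`, `median`, `q1`, `q3`.
#' @export
group_psd_summary <- function(estimates) {
  if (length(estimates) < 1L) stop("need at least one estimate")
  f0 <- estimates[[1]]$freqs
  for (e in estimates)
    if (length(e$freqs) != length(f0) || any(e$freqs != f0))
      stop("estimates are not on a common frequency grid")
  P <- vapply(estimates, function(e) e$power, numeric(length(f0)))
  P <- matrix(P, nrow = length(f0))
  data.frame(
    freq = f0,
    median = apply(P, 1, median),
    q1 = apply(P, 1, quantile, probs = 0.25, names = FALSE),
    q3 = apply(P, 1, quantile, probs = 0.75, names = FALSE)
  )
}

#' Clinical EEG frequency-band scheme
#'
#' Contiguous, non-overlapping `[low, high)` intervals. Defaults are the
#' conventional clinical edges: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-100 Hz.
#'
#' @param edges named list of `c(low, high)` pairs in Hz.
#' @return Object of class `band_scheme`.
#' @export
band_scheme <- function(edges = list(delta = c(0.5, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30),
                                     gamma = c(30, 100))) {
  lows <- vapply(edges, `[`, numeric(1), 1)
  highs <- vapply(edges, `[`, numeric(1), 2)
  if (any(highs < lows)) stop("band high edge below low edge")
  o <- order(lows)
  if (any(highs[o][-length(o)] > lows[o][-1] + 1e-12))
    stop("bands must not overlap")
  structure(list(edges = edges), class = "band_scheme")
}

#' Fraction of spectral power per frequency band
#'
#' @param est a [welch_psd()] estimate.
#' @param scheme a [band_scheme()].
#' @return Named numeric vector of per-band power fractions; each `>= 0`,
#'   summing to at most 1 (bins outside the scheme are excluded).
#' @export
band_power <- function(est, scheme = band_scheme()) {
  stopifnot(inherits(est, "spectral_estimate"), inherits(scheme, "band_scheme"))
  vapply(scheme$edges, function(e) {
    sum(est$power[est$freqs >= e[1] & est$freqs < e[2]])
  }, numeric(1))
}

#' Frequency of the dominant spectral peak within a search band
#'
#' Argmax of the PSD restricted to `band` (default 3-30 Hz, the range where
#' wake iEEG theta/alpha/beta peaks live). Restricting the search keeps the
#' steep low-frequency flank of 1/f-like spectra from masking an injected or
#' physiological oscillatory peak.
#'
#' @param est a [welch_psd()] estimate, or a `data.frame` with `freq` and a
#'   power column (e.g. a [group_psd_summary()] row set, using `median`).
#' @param band `c(low, high)` search interval in Hz.
#' @param column power column used when `est` is a data.frame.
#' @return Peak frequency in Hz.
#' @export
psd_peak_frequency <- function(est, band = c(3, 30), column = "median") {
  if (inherits(est, "spectral_estimate")) {
    f <- est$freqs; p <- est$power
  } else {
    f <- est$freq; p <- est[[column]]
  }
  keep <- f >= band[1] & f < band[2]
  if (!any(keep)) stop("no frequency bins inside the search band")
  f[keep][which.max(p[keep])]
}
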