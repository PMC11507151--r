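#' Embedding configuration for ordinal-pattern analysis
#'
#' Bundles the Bandt-Pompe embedding dimension `D`, embedding delay `tau`
#' (in samples) and the length of the non-overlapping analysis windows (in
#' seconds). The defaults (`D = 6`, `tau = 1`, 15 s windows) are the standard
#' configuration for wake iEEG sampled at 200 Hz, where a window holds 3000
#' samples.
#'
#' A window of `M` samples yields `n = M - (D-1)*tau` embedded vectors, which
#' should be much larger than the number of possible patterns `D!` for the
#' pattern histogram to be well populated. The rule of thumb enforced here is
#' `n >= min_factor * D!` (default `min_factor = 5`); configurations between
#' `1*D!` and `min_factor*D!` trigger a warning at [bp_pdf()] time, below
#' `1*D!` an error.
#'
#' @param D integer embedding dimension, `>= 2`.
#' @param tau integer embedding delay in samples, `>= 1`.
#' @param window_s analysis window length in seconds, `> 0`.
#' @param min_factor multiple of `D!` that the number of embedded vectors per
#'   window should reach before the pattern histogram is considered well
#'   sampled.
#' @return An object of class `embedding_config`.
#' @examples
#' embedding_config(D = 6, tau = 1, window_s = 15)
#' @export
embedding_config <- function(D = 6L, tau = 1L, window_s = 15, min_factor = 5) {
  D <- as.integer(D)
  tau <- as.integer(tau)
  if (is.na(D) || D < 2L) stop("D must be an integer >= 2")
  if (D > 10L) stop("D > 10 is not supported (D! pattern bins)")
  if (is.na(tau) || tau < 1L) stop("tau must be an integer >= 1")
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be > 0")
  structure(
    list(D = D, tau = tau, window_s = window_s, min_factor = min_factor),
    class = "embedding_config"
  )
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("Ordinal embedding: D = %d (%d patterns), tau = %d, window = %g s\n",
              x$D, factorial(x$D), x$tau, x$window_s))
  invisible(x)
}

#' Lexicographic index of the ordinal pattern of a vector
#'
#' Maps a length-`D` vector to the rank (0-based, in `0 .. D!-1`) of the
#' permutation that sorts it ascending, under lexicographic ordering of
#' permutations. Ties are broken by temporal order: of two equal values the
#' earlier sample is ranked lower (stable sort), the convention of reference
#' ordinal-pattern implementations.
#'
#' @param v numeric vector of length `D >= 2`, finite values.
#' @return Integer pattern id in `0 .. D!-1`. The strictly increasing vector
#'   maps to 0, the strictly decreasing one to `D!-1`.
#' @examples
#' pattern_index(c(1, 2, 3))   # 0
#' pattern_index(c(3, 2, 1))   # 5
#' @export
pattern_index <- function(v) {
  if (length(v) < 2L) stop("v must have at least 2 entries")
  if (anyNA(v) || !all(is.finite(v))) stop("v must be finite")
  ord_pattern_ids_cpp(as.numeric(v), length(v), 1L)[1L]
}

#' Bandt-Pompe ordinal-pattern probability distribution
#'
#' Scans a series with overlapping delay-embedded vectors
#' `(x_t, x_{t+tau}, ..., x_{t+(D-1)tau})`, maps each to its ordinal pattern
#' (see [pattern_index()]) and returns the histogram over all `D!` patterns
#' together with its relative-frequency normalization. The series contributes
#' `n = M - (D-1)*tau` vectors, so `probs` sums to exactly 1.
#'
#' Ordinal patterns depend only on the relative order of samples, so the
#' result is invariant under `a*x + b` for `a > 0`.
#'
#' @param x numeric series, finite values, length `M >= (D-1)*tau + 1`.
#' @param cfg an [embedding_config()].
#' @param warn warn when `n` is under `min_factor * D!` (poorly populated
#'   histogram).
#' @return Object of class `ordinal_pdf`: list with `D`, `tau`, integer
#'   `counts` (length `D!`), `probs`, and `n_vectors`.
#' @examples
#' p <- bp_pdf(sin(1:1000 / 7), embedding_config(D = 3, window_s = 5))
#' sum(p$probs)
#' @export
bp_pdf <- function(x, cfg, warn = TRUE) {
  stopifnot(inherits(cfg, "embedding_config"))
  if (anyNA(x) || !all(is.finite(x))) stop("x contains NA or non-finite values")
  D <- cfg$D; tau <- cfg$tau
  M <- length(x)
  n <- M - (D - 1L) * tau
  nf <- factorial(D)
  if (n < 1L) stop(sprintf("series too short: M = %d gives %d embedded vectors", M, n))
  if (warn && n < cfg$min_factor * nf)
    warning(sprintf(
      "only %d embedded vectors for D! = %d patterns (< %g * D!); histogram may be undersampled",
      n, nf, cfg$min_factor))
  ids <- ord_pattern_ids_cpp(as.numeric(x), D, tau)
  counts <- tabulate(ids + 1L, nbins = nf)
  structure(
    list(D = D, tau = tau, counts = counts, probs = counts / n, n_vectors = n),
    class = "ordinal_pdf"
  )
}

#' @export
print.ordinal_pdf <- function(x, ...) {
  cat(sprintf("Ordinal pattern PDF: D = %d, tau = %d, %d vectors, %d/%d patterns observed\n",
              x$D, x$tau, x$n_vectors, sum(x$counts > 0L), length(x$counts)))
  invisible(x)
}

#' Split a series into non-overlapping analysis windows
#'
#' Cuts consecutive, non-overlapping windows of `round(window_s * fs)` samples
#' from the start of `x`; a trailing partial window is discarded. Each window
#' is checked for long constant runs (at least `fs/2` identical consecutive
#' samples), which flag stretches of zero-padding or flat-lined recording; the
#' quantifier stage excludes flagged windows by default since a constant run
#' injects spurious mass on a single ordinal pattern.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param cfg an [embedding_config()] providing `window_s`.
#' @return A list with one element per full window: `samples` (the data),
#'   `index` (1-based window number), `padding` (logical flag). A series
#'   shorter than one window gives an empty list.
#' @examples
#' w <- window_iter(rnorm(13600), fs = 200, cfg = embedding_config())
#' length(w)          # 4 windows of 3000 samples; 1600 samples discarded
#' @export
window_iter <- function(x, fs, cfg) {
  stopifnot(inherits(cfg, "embedding_config"), fs > 0)
  wlen <- as.integer(round(cfg$window_s * fs))
  n_win <- length(x) %/% wlen
  if (n_win < 1L) return(list())
  run_thresh <- fs / 2
  lapply(seq_len(n_win), function(i) {
    w <- x[((i - 1L) * wlen + 1L):(i * wlen)]
    runs <- rle(w)
    list(samples = w, index = i, padding = any(runs$lengths >= run_thresh))
  })
}
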