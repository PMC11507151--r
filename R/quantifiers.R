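#' Shannon entropy of a discrete distribution (bits)
#'
#' `S[P] = -sum_j p_j log2(p_j)` with the convention `0 * log2(0) = 0`.
#' Probabilities below 1e-15 are treated as exact zeros to keep floating-point
#' dust out of the sum.
#'
#' @param p probability vector: non-negative, summing to 1 (within 1e-9 by
#'   default).
#' @param tol tolerance on the normalization check.
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' shannon_entropy(rep(1 / 720, 720))  # log2(720) = 9.4919 bits
#' @export
shannon_entropy <- function(p, tol = 1e-9) {
  p <- .check_dist(p, tol)
  nz <- p > 1e-15
  -sum(p[nz] * log2(p[nz]))
}

#' Normalized permutation Shannon entropy
#'
#' `H[P] = S[P] / log2(N)` where `N = length(p)` is the number of states
#' (for an ordinal-pattern PDF, `N = D!`). `H` is dimensionless in `[0, 1]`:
#' 0 for a point mass (fully ordered dynamics), 1 for the uniform
#' distribution (full randomness).
#'
#' @inheritParams shannon_entropy
#' @return `H` in `[0, 1]`.
#' @export
normalized_entropy <- function(p, tol = 1e-9) {
  if (length(p) < 2L) stop("need at least N = 2 states")
  shannon_entropy(p, tol) / log2(length(p))
}

#' Jensen-Shannon divergence between two distributions
#'
#' Evaluated with normalized entropies:
#' `J[P, Q] = H[(P+Q)/2] - H[P]/2 - H[Q]/2`, where `H` is
#' [normalized_entropy()]. `J >= 0`, symmetric, and 0 iff `P = Q`. In the
#' complexity computation `Q` is the uniform distribution, and the common
#' `log2(N)` normalization cancels against the constant of [q0()], so the
#' resulting complexity is independent of this convention.
#'
#' @param p,q probability vectors over the same `N` states.
#' @param tol normalization tolerance.
#' @return Non-negative divergence (dimensionless).
#' @export
jensen_shannon <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  normalized_entropy((p + q) / 2, tol) -
    normalized_entropy(p, tol) / 2 - normalized_entropy(q, tol) / 2
}

#' Normalization constant of the Jensen-Shannon disequilibrium
#'
#' `Q0 = 1 / J[P_delta, P_e]`, the reciprocal of the divergence between a
#' point mass and the uniform distribution over `N` states — the largest value
#' `J` can take — so that the disequilibrium `Q_J = Q0 * J` lies in `[0, 1]`
#' and equals 1 at a point mass. Evaluated numerically from
#' [jensen_shannon()] rather than from a closed form.
#'
#' @param N number of states, `>= 2`.
#' @return Positive scalar.
#' @examples
#' q0(720) * jensen_shannon(c(1, rep(0, 719)), rep(1 / 720, 720))  # 1
#' @export
q0 <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  delta <- c(1, rep(0, N - 1L))
  1 / jensen_shannon(delta, rep(1 / N, N))
}

#' MPR statistical complexity
#'
#' The Martin-Plastino-Rosso complexity
#' `C = Q_J[P, P_e] * H[P] = Q0 * J[P, P_e] * H[P]`, the product of the
#' normalized Jensen-Shannon disequilibrium from the uniform distribution
#' `P_e` and the normalized entropy. `C` is 0 both at perfect order (point
#' mass, `H = 0`) and at full randomness (uniform, `J = 0`), and is positive
#' for structured dynamics in between; chaotic maps populate the
#' high-complexity band of the complexity-entropy plane.
#'
#' @param p probability vector (e.g. `$probs` of a [bp_pdf()] result).
#' @param tol normalization tolerance.
#' @return `C` in `[0, 1]`.
#' @export
mpr_complexity <- function(p, tol = 1e-9) {
  N <- length(p)
  pe <- rep(1 / N, N)
  q0(N) * jensen_shannon(p, pe, tol) * normalized_entropy(p, tol)
}

#' Windowed entropy-complexity points for one channel
#'
#' Cuts the channel into non-overlapping windows (see [window_iter()]),
#' computes the Bandt-Pompe PDF per window and returns one
#' (`H`, `C`) point per retained window — the atoms of the complexity-entropy
#' causality plane. Windows flagged as padding (long constant runs, e.g. the
#' zero-padded tail of a fixed-length record) are excluded by default.
#'
#' @param record a [signal_record()].
#' @param cfg an [embedding_config()].
#' @param drop_padding exclude padding-flagged windows (default `TRUE`).
#' @param warn passed to [bp_pdf()].
#' @return `data.frame` with columns `channel_id`, `window_index`, `H`, `C`,
#'   `n_vectors`. Zero rows (with a warning) when no window is retained.
#' @export
channel_quantifiers <- function(record, cfg, drop_padding = TRUE, warn = FALSE) {
  stopifnot(inherits(record, "signal_record"))
  wins <- window_iter(record$x, record$fs, cfg)
  if (drop_padding) wins <- Filter(function(w) !w$padding, wins)
  if (length(wins) == 0L) {
    warning(sprintf("channel %s: no retained windows", record$channel_id))
    return(data.frame(channel_id = character(), window_index = integer(),
                      H = numeric(), C = numeric(), n_vectors = integer()))
  }
  rows <- lapply(wins, function(w) {
    pdf <- bp_pdf(w$samples, cfg, warn = warn)
    data.frame(channel_id = record$channel_id, window_index = w$index,
               H = normalized_entropy(pdf$probs),
               C = mpr_complexity(pdf$probs),
               n_vectors = pdf$n_vectors)
  })
  do.call(rbind, rows)
}

.check_dist <- function(p, tol) {
  if (!is.numeric(p) || length(p) < 1L) stop("p must be a numeric vector")
  if (anyNA(p) || any(p < 0)) stop("p must be non-negative with no NA")
  s <- sum(p)
  if (abs(s - 1) > tol) stop(sprintf("p sums to %.12f, not 1", s))
  p / s
}
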