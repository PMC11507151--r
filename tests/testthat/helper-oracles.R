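# Independent naive oracles, deliberately kept apart from the package's
# implementation paths: explicit sorting, direct enumeration, hand step-up.

# Lexicographic rank of the stable sorting permutation of v (0-based).
naive_pattern_rank <- function(v) {
  D <- length(v)
  perm <- order(v) - 1L  # order() is stable: earlier index wins ties
  r <- 0
  for (i in seq_len(D - 1L))
    r <- r + sum(perm[(i + 1L):D] < perm[i]) * factorial(D - i)
  r
}

# Bandt-Pompe counts by explicitly sorting every embedded vector.
naive_bp_counts <- function(x, D, tau = 1L) {
  n <- length(x) - (D - 1L) * tau
  counts <- integer(factorial(D))
  for (t in seq_len(n)) {
    v <- x[t + (0:(D - 1L)) * tau]
    counts[naive_pattern_rank(v) + 1L] <- counts[naive_pattern_rank(v) + 1L] + 1L
  }
  counts
}

# Exact two-sided Mann-Whitney p by enumerating all label assignments.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    xa <- pooled[idx]; xb <- pooled[-idx]
    ua <- sum(outer(xa, xb, `>`))
    min(ua, length(xa) * length(xb) - ua)
  }
  u_obs <- u_of(seq_len(na))
  all_idx <- combn(length(pooled), na)
  us <- apply(all_idx, 2, u_of)
  mean(us <= u_obs)
}

# Benjamini-Hochberg step-up by hand.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Shannon entropy in bits, written independently of the package.
naive_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# Small deterministic metadata table for cohort tests.
toy_metadata <- function(n_f = 5L, n_m = 5L, channels = 2L,
                         region = "precuneus", hemisphere = "L",
                         ages_f = NULL, ages_m = NULL) {
  if (is.null(ages_f)) ages_f <- seq(22, by = 4, length.out = n_f)
  if (is.null(ages_m)) ages_m <- seq(28, by = 4, length.out = n_m)
  rows <- list()
  for (sex in c("F", "M")) {
    n <- if (sex == "F") n_f else n_m
    ages <- if (sex == "F") ages_f else ages_m
    for (p in seq_len(n)) for (ch in seq_len(channels)) {
      pid <- sprintf("%s%02d", sex, p)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, sex = sex, age = ages[p], region = region,
        hemisphere = hemisphere,
        channel_id = sprintf("%s_ch%02d", pid, ch),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
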