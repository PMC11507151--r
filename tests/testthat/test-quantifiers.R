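test_that("entropy closed forms: uniform, point mass, fair coin", {
  expect_equal(shannon_entropy(rep(1 / 720, 720)), log2(720), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, rep(0, 23))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, rep(0, 10))), 1)
  expect_equal(normalized_entropy(rep(1 / 120, 120)), 1, tolerance = 1e-12)
  expect_equal(normalized_entropy(c(1, rep(0, 119))), 0)
  # two equiprobable patterns among N = 6 states
  expect_equal(normalized_entropy(c(0.5, 0.5, 0, 0, 0, 0)), 1 / log2(6),
               tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.6, 0.6)), "sums to")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("entropy agrees with an independent summation on random distributions", {
  set.seed(5)
  for (k in 1:20) {
    N <- sample(c(6, 24, 120, 720), 1)
    p <- rexp(N); p <- p / sum(p)
    expect_equal(shannon_entropy(p), naive_entropy_bits(p), tolerance = 1e-10)
  }
})

test_that("Jensen-Shannon divergence is symmetric, zero at equality, maximal at a point mass", {
  set.seed(8)
  for (N in c(6, 24, 120)) {
    pe <- rep(1 / N, N)
    expect_equal(jensen_shannon(pe, pe), 0, tolerance = 1e-14)
    p <- rexp(N); p <- p / sum(p)
    expect_equal(jensen_shannon(p, pe), jensen_shannon(pe, p), tolerance = 1e-14)
    expect_gte(jensen_shannon(p, pe), 0)
    delta <- c(1, rep(0, N - 1))
    expect_lte(jensen_shannon(p, pe), jensen_shannon(delta, pe) + 1e-12)
  }
  expect_error(jensen_shannon(c(0.5, 0.5), rep(1 / 3, 3)), "same length")
})

test_that("q0 normalizes the disequilibrium to 1 at a point mass", {
  for (N in c(2, 6, 24, 120, 720)) {
    delta <- c(1, rep(0, N - 1))
    expect_equal(q0(N) * jensen_shannon(delta, rep(1 / N, N)), 1,
                 tolerance = 1e-10)
    expect_gt(q0(N), 0)
  }
  expect_error(q0(1), "N must be")
})

test_that("complexity vanishes at both entropy extremes and stays in [0, 1]", {
  for (N in c(6, 24, 120, 720)) {
    expect_equal(mpr_complexity(rep(1 / N, N)), 0, tolerance = 1e-10)
    expect_equal(mpr_complexity(c(1, rep(0, N - 1))), 0, tolerance = 1e-10)
  }
  set.seed(13)
  for (k in 1:100) {
    N <- sample(c(6, 24, 120, 720), 1)
    p <- rexp(N)^sample(1:3, 1); p <- p / sum(p)
    H <- normalized_entropy(p)
    C <- mpr_complexity(p)
    expect_gte(H, 0); expect_lte(H, 1)
    expect_gte(C, 0); expect_lte(C, 1)
  }
})

test_that("chaotic logistic dynamics land in the high-complexity band", {
  x <- gen_logistic_map(1e6, r = 4, x0 = 0.3, burn_in = 100)
  pdf <- suppressWarnings(bp_pdf(x, embedding_config(D = 6)))
  expect_gt(mpr_complexity(pdf$probs), 0.3)
})

test_that("channel_quantifiers emits one point per retained window", {
  rec <- signal_record(gen_colored_noise(13600, 200, 1, seed = 4), 200, "chA")
  qp <- channel_quantifiers(rec, embedding_config(D = 6))
  expect_equal(nrow(qp), 4L)
  expect_equal(qp$window_index, 1:4)
  expect_true(all(qp$H > 0 & qp$H < 1))
  # strictly increasing channel: single pattern, H = C = 0
  mono <- signal_record(seq_len(13600) + 0, 200, "chMono")
  qm <- channel_quantifiers(mono, embedding_config(D = 3), drop_padding = FALSE)
  expect_true(all(qm$H == 0))
  expect_true(all(qm$C == 0))
  # zero-padded tail windows are excluded when flagged
  padded <- signal_record(c(gen_colored_noise(10000, 200, 0, seed = 1),
                            rep(0, 3600)), 200, "chPad")
  qpad <- channel_quantifiers(padded, embedding_config(D = 5))
  expect_equal(nrow(qpad), 3L)
  short <- signal_record(rnorm(100), 200, "chShort")
  expect_warning(qs <- channel_quantifiers(short, embedding_config(D = 5)),
                 "no retained windows")
  expect_equal(nrow(qs), 0L)
})

test_that("white-noise windows are near maximal entropy for D = 5 and D = 6", {
  rec <- signal_record(gen_colored_noise(12000, 200, 0, seed = 21), 200, "wn")
  for (D in c(5L, 6L)) {
    qp <- channel_quantifiers(rec, embedding_config(D = D))
    expect_true(all(qp$H > 0.95))
  }
})
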