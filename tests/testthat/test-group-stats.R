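test_that("Mann-Whitney exact p matches full enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  expect_equal(r$p, enumerate_mw_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  set.seed(42)
  for (k in 1:10) {
    a <- rnorm(sample(3:5, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney_u(a, b)$p, enumerate_mw_p(a, b), tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney is rank-invariant and near 1 for identical samples", {
  a <- c(5, 1, 9, 4); b <- c(2, 8, 3, 7)
  p1 <- mann_whitney_u(a, b)$p
  p2 <- mann_whitney_u(exp(a), exp(b))$p  # common strictly monotone transform
  expect_equal(p1, p2, tolerance = 1e-12)
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_gte(mann_whitney_u(x, x, method = "normal")$p, 0.99)
})

test_that("exact and corrected-normal p agree closely for tie-free n = 8 samples", {
  # the worst case over all U values at nA = nB = 8 is |diff| = 0.0109
  set.seed(3)
  for (k in 1:20) {
    a <- rnorm(8); b <- rnorm(8, mean = runif(1, -1, 1))
    pe <- mann_whitney_u(a, b, method = "exact")$p
    pn <- mann_whitney_u(a, b, method = "normal")$p
    expect_lt(abs(pe - pn), 0.011)
  }
})

test_that("h_index applies the strict-inequality rejection rule", {
  expect_identical(h_index(0.01), 1L)
  expect_identical(h_index(0.05), 0L)  # p exactly at alpha is not a rejection
  expect_identical(h_index(0.81), 0L)
  expect_identical(h_index(c(0.049, 0.05, 0.051)), c(1L, 0L, 0L))
  expect_error(h_index(1.2), "0, 1|\\[0, 1\\]")
})

test_that("BH adjustment matches the hand step-up and an independent oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.04, 0.05))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.05, 0.05), tolerance = 1e-12)
  expect_identical(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_equal(bh_fdr(rep(0.2, 5))$adjusted, rep(0.2, 5))
  set.seed(11)
  for (k in 1:100) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p)$adjusted, naive_bh(p), tolerance = 1e-12)
  }
  # adjusted values never drop below raw
  p <- runif(10)
  expect_true(all(bh_fdr(p)$adjusted >= p))
})

test_that("compare_region pools windows and reports per-sex summaries", {
  pf <- data.frame(H = c(0.91, 0.93, 0.92, 0.94), C = c(0.11, 0.13, 0.12, 0.14))
  pm <- data.frame(H = c(0.81, 0.83, 0.82, 0.84), C = c(0.21, 0.23, 0.22, 0.24))
  row <- compare_region(pf, pm, "H", region = "precuneus", hemisphere = "L", D = 6)
  expect_equal(row$mean_female, mean(pf$H))
  expect_equal(row$median_male, median(pm$H))
  expect_equal(row$n_female, 4L)
  expect_identical(row$h, 1L)  # fully separated samples
  same <- compare_region(pf, pf, "C")
  expect_identical(same$h, 0L)
})

test_that("boxplot_summary follows Tukey and notch conventions", {
  b <- boxplot_summary(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q1, 25.75)   # type-7 linear interpolation
  expect_equal(b$q3, 75.25)
  expect_equal(b$notch_hi - b$notch_lo, 2 * 1.57 * (b$q3 - b$q1) / sqrt(100))
  expect_length(b$outliers, 0L)
  # an extreme point beyond 1.5 IQR becomes an outlier
  b2 <- boxplot_summary(c(1:20, 100))
  expect_equal(b2$outliers, 100)
  expect_lte(b2$whisker_hi, b2$q3 + 1.5 * (b2$q3 - b2$q1))
  # constant sample: degenerate notch at the constant
  b3 <- boxplot_summary(rep(4, 7))
  expect_equal(b3$notch_lo, 4)
  expect_equal(b3$notch_hi, 4)
  expect_equal(b3$whisker_lo, 4)
  # notch width shrinks as 1/sqrt(n) for fixed IQR
  w <- function(n) {
    s <- boxplot_summary(rep(c(0, 1, 2, 3), n))
    s$notch_hi - s$notch_lo
  }
  expect_equal(w(100) / w(25), 1 / 2, tolerance = 1e-10)
})

test_that("separated cohorts co-produce non-overlapping notches and h = 1", {
  set.seed(19)
  hits <- 0L
  for (k in 1:50) {
    a <- rnorm(40, 0, 1)
    b <- rnorm(40, 2, 1)
    ba <- boxplot_summary(a); bb <- boxplot_summary(b)
    disjoint <- ba$notch_hi < bb$notch_lo || bb$notch_hi < ba$notch_lo
    h <- h_index(mann_whitney_u(a, b)$p)
    if (disjoint == (h == 1L)) hits <- hits + 1L
  }
  expect_gt(hits / 50, 0.9)
})
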