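test_that("generators are deterministic in their seed and leave the global RNG alone", {
  expect_identical(gen_colored_noise(512, 200, 1.5, seed = 11),
                   gen_colored_noise(512, 200, 1.5, seed = 11))
  expect_identical(gen_oscillatory_channel(512, 200, 1, 10, 0.4, seed = 3),
                   gen_oscillatory_channel(512, 200, 1, 10, 0.4, seed = 3))
  expect_identical(gen_logistic_map(50, 3.9, 0.2), gen_logistic_map(50, 3.9, 0.2))
  set.seed(99)
  before <- .Random.seed
  invisible(gen_colored_noise(128, 200, 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("colored noise recovers the target spectral slope on average", {
  fit_slope <- function(beta) {
    mean(vapply(1:20, function(s) {
      x <- gen_colored_noise(2^16, 200, beta, seed = s)
      n <- length(x)
      sp <- Mod(fft(x))^2
      f <- (1:(n %/% 2)) * 200 / n
      keep <- f > 1 & f < 90
      unname(coef(lm(log(sp[2:(n %/% 2 + 1)][keep]) ~ log(f[keep])))[2])
    }, numeric(1)))
  }
  expect_lt(abs(fit_slope(0)), 0.1)
  expect_lt(abs(fit_slope(2) - (-2)), 0.15)
})

test_that("colored noise rejects degenerate arguments", {
  expect_error(gen_colored_noise(1, 200, 1, seed = 1), "n must be")
  expect_error(gen_colored_noise(100, 200, -0.5, seed = 1), "beta")
})

test_that("oscillatory channel degenerates to colored noise at zero peak amplitude", {
  expect_identical(gen_oscillatory_channel(2048, 200, 1.2, 9, 0, seed = 7),
                   gen_colored_noise(2048, 200, 1.2, seed = 7))
  expect_error(gen_oscillatory_channel(100, 200, 1, 150, 0.2, seed = 1),
               "peak_freq")
})

test_that("oscillatory peak dominates the Welch PSD and carries its variance fraction", {
  x <- gen_oscillatory_channel(12000, 200, 0, 10, 0.5, seed = 2)
  est <- welch_psd(x, 200)
  expect_equal(est$freqs[which.max(est$power)], 10, tolerance = 1e-9)
  # band power within peak_freq +/- 2*bandwidth ~ peak_amplitude, 20-seed mean
  frac <- mean(vapply(1:20, function(s) {
    e <- welch_psd(gen_oscillatory_channel(12000, 200, 0, 10, 0.5, seed = s,
                                           peak_bw = 0.5), 200)
    sum(e$power[e$freqs >= 9 & e$freqs <= 11])
  }, numeric(1)))
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("logistic map matches direct iteration and its fixed point", {
  expect_equal(gen_logistic_map(5, r = 4, x0 = 0.3),
               c(0.3, 0.84, 0.5376, 0.99434496, 0.02249224),
               tolerance = 1e-7)
  expect_equal(gen_logistic_map(10, r = 2, x0 = 0.5), rep(0.5, 10))
  expect_error(gen_logistic_map(10, r = 4, x0 = 1.2), "x0")
  # burn-in discards exactly the leading samples
  full <- gen_logistic_map(30, r = 3.7, x0 = 0.4)
  expect_equal(gen_logistic_map(20, r = 3.7, x0 = 0.4, burn_in = 10), full[11:30])
})

test_that("gen_cohort realizes the spec: counts, padding, reproducible metadata", {
  spec <- cohort_spec(n_female_patients = 5, n_male_patients = 5,
                      channels_per_patient = 2, seed = 42)
  coh <- gen_cohort(spec)
  expect_length(coh$records, 20L)
  expect_equal(nrow(coh$metadata), 20L)
  expect_setequal(unique(coh$metadata$sex), c("F", "M"))
  # 8 s zero-pad at 200 Hz: the last 1600 samples of every channel are 0
  for (r in coh$records) {
    expect_length(r$x, 13600L)
    expect_true(all(tail(r$x, 1600) == 0))
    expect_false(all(head(r$x, 12000) == 0))
  }
  # ages within the truncated law's support, whole years
  expect_true(all(coh$metadata$age >= 18 & coh$metadata$age <= 65))
  expect_true(all(coh$metadata$age == round(coh$metadata$age)))
  coh2 <- gen_cohort(cohort_spec(n_female_patients = 5, n_male_patients = 5,
                                 channels_per_patient = 2, seed = 42))
  expect_identical(coh$metadata, coh2$metadata)
  expect_identical(coh$records[[7]]$x, coh2$records[[7]]$x)
})

test_that("per-sex generative parameters land on the right channels", {
  eff <- group_effect(beta_female = 2, beta_male = 0,
                      peak_freq_female = 7, peak_freq_male = 10,
                      peak_amplitude = 0.4)
  coh <- gen_cohort(cohort_spec(effect = eff, seed = 3))
  sexes <- vapply(coh$records, function(r) r$sex, character(1))
  peak_of <- function(r) {
    est <- welch_psd(r$x[1:12000], r$fs)
    psd_peak_frequency(est, band = c(3, 30))
  }
  pf <- vapply(coh$records[sexes == "F"], peak_of, numeric(1))
  pm <- vapply(coh$records[sexes == "M"], peak_of, numeric(1))
  expect_true(all(abs(pf - 7) <= 0.5))
  expect_true(all(abs(pm - 10) <= 0.5))
})
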