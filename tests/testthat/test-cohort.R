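test_that("build_groups enforces the distinct-patient eligibility rule", {
  meta <- toy_metadata(n_f = 5, n_m = 5)
  g <- build_groups(meta)
  expect_length(g, 1L)
  expect_true(g[[1]]$eligible)
  expect_equal(g[[1]]$n_female, 5L)
  # 4 F + 12 M: boundary fails
  g2 <- build_groups(toy_metadata(n_f = 4, n_m = 12))
  expect_false(g2[[1]]$eligible)
  # one patient with 10 channels counts once
  meta10 <- toy_metadata(n_f = 5, n_m = 4, channels = 1)
  extra <- meta10[meta10$patient_id == "M01", ][rep(1, 9), ]
  extra$channel_id <- sprintf("M01_extra%02d", 1:9)
  g3 <- build_groups(rbind(meta10, extra))
  expect_equal(g3[[1]]$n_male, 4L)
  expect_false(g3[[1]]$eligible)
  expect_error(build_groups(meta[, -1]), "missing required columns")
  bad <- meta; bad$sex[1] <- "X"
  expect_error(build_groups(bad), "sex")
})

test_that("eligibility is monotone in added patients", {
  base <- toy_metadata(n_f = 4, n_m = 7)
  expect_false(build_groups(base)[[1]]$eligible)
  add <- data.frame(patient_id = "F99", sex = "F", age = 33,
                    region = "precuneus", hemisphere = "L",
                    channel_id = "F99_ch01")
  expect_true(build_groups(rbind(base, add, data.frame(
    patient_id = "F98", sex = "F", age = 41, region = "precuneus",
    hemisphere = "L", channel_id = "F98_ch01")))[[1]]$eligible)
})

test_that("age_summary collapses channels to patients and uses sample sd", {
  meta <- toy_metadata(n_f = 3, n_m = 1, channels = 4,
                       ages_f = c(20, 30, 40), ages_m = 50)
  s <- age_summary(build_groups(meta, min_patients = 1)[[1]])
  f <- s[s$sex == "F", ]
  expect_equal(f$n, 3L)
  expect_equal(f$mean_years, 30)
  expect_equal(f$sd_years, 10)  # sample sd of {20,30,40}
  m <- s[s$sex == "M", ]
  expect_equal(m$sd_years, 0)
  expect_false(m$sd_defined)
})

test_that("age-matched subsampling matches the exhaustive oracle", {
  meta <- toy_metadata(n_f = 6, n_m = 5, channels = 1,
                       ages_f = c(20, 25, 30, 35, 40, 60),
                       ages_m = c(30, 35, 40, 45, 50))
  g <- build_groups(meta)[[1]]
  sub <- age_matched_subsample(g, k = 5, seed = 1)
  # independent oracle: enumerate all 6 female subsets against the fixed males
  ages_f <- c(20, 25, 30, 35, 40, 60)
  objs <- vapply(1:6, function(drop) {
    af <- ages_f[-drop]
    abs(mean(af) - 40) + 0.1 * (sd(af) + sd(c(30, 35, 40, 45, 50)))
  }, numeric(1))
  kept <- unique(sub$female$patient_id)
  dropped <- setdiff(sprintf("F%02d", 1:6), kept)
  expect_identical(dropped, sprintf("F%02d", which.min(objs)))
  expect_equal(attr(sub, "objective"), min(objs), tolerance = 1e-12)
  # males unchanged: nM = k keeps the full group
  expect_setequal(unique(sub$male$patient_id), sprintf("M%02d", 1:5))
  # determinism
  sub2 <- age_matched_subsample(g, k = 5, seed = 1)
  expect_identical(sub$female, sub2$female)
  expect_error(age_matched_subsample(build_groups(toy_metadata(4, 9))[[1]], k = 5),
               "at least 5 patients")
})

test_that("subsampling never does worse than the exhaustive optimum", {
  set.seed(77)
  for (k in 1:5) {
    nf <- sample(5:9, 1); nm <- sample(5:9, 1)
    meta <- toy_metadata(n_f = nf, n_m = nm, channels = 1,
                         ages_f = sample(18:65, nf), ages_m = sample(18:65, nm))
    g <- build_groups(meta)[[1]]
    sub <- age_matched_subsample(g, k = 5, seed = k)
    # brute-force optimum over all subset pairs
    uf <- sort(unique(meta$age[meta$sex == "F"] * 0 + meta$age[meta$sex == "F"]))
    af <- meta$age[meta$sex == "F"][!duplicated(meta$patient_id[meta$sex == "F"])]
    am <- meta$age[meta$sex == "M"][!duplicated(meta$patient_id[meta$sex == "M"])]
    cf <- combn(af, 5); cm <- combn(am, 5)
    best <- Inf
    for (i in seq_len(ncol(cf))) for (j in seq_len(ncol(cm))) {
      o <- abs(mean(cf[, i]) - mean(cm[, j])) + 0.1 * (sd(cf[, i]) + sd(cm[, j]))
      if (o < best) best <- o
    }
    expect_equal(attr(sub, "objective"), best, tolerance = 1e-10)
  }
})

test_that("random-search fallback engages for large cohorts and is seeded", {
  nf <- 16L
  meta <- toy_metadata(n_f = nf, n_m = nf, channels = 1,
                       ages_f = seq(18, 63, length.out = nf),
                       ages_m = seq(20, 65, length.out = nf))
  g <- build_groups(meta)[[1]]
  s1 <- age_matched_subsample(g, k = 5, seed = 9, max_pairs = 1000,
                              n_random = 500)
  s2 <- age_matched_subsample(g, k = 5, seed = 9, max_pairs = 1000,
                              n_random = 500)
  expect_identical(unique(s1$female$patient_id), unique(s2$female$patient_id))
  expect_equal(s1$n_female, 5L)
})
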