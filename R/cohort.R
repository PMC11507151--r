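#' Group channel metadata by region and hemisphere
#'
#' Splits a channel metadata table into one group per (region, hemisphere)
#' cell, splits each group by sex, and evaluates the cohort eligibility rule:
#' a group is analyzable only when it holds at least `min_patients` distinct
#' female patients and at least `min_patients` distinct male patients
#' (channels never count — a patient with ten electrodes counts once).
#' Ineligible groups are retained with `eligible = FALSE` so the exclusion is
#' auditable downstream.
#'
#' @param metadata `data.frame` with columns `patient_id`, `sex` (`"F"`/`"M"`),
#'   `age`, `region`, `hemisphere`, `channel_id` (extra columns pass through).
#' @param min_patients minimum distinct patients per sex (default 5).
#' @return List of `region_group` objects, each a list with `region`,
#'   `hemisphere`, `female`/`male` (metadata subsets), `n_female`/`n_male`
#'   (distinct patients) and `eligible`.
#' @export
build_groups <- function(metadata, min_patients = 5L) {
  req <- c("patient_id", "sex", "age", "region", "hemisphere", "channel_id")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0L)
    stop(sprintf("metadata is missing required columns: %s",
                 paste(miss, collapse = ", ")))
  if (!all(metadata$sex %in% c("F", "M")))
    stop("sex must be coded F/M (see read_metadata for alias normalization)")
  cells <- unique(metadata[, c("region", "hemisphere")])
  cells <- cells[order(cells$region, cells$hemisphere), , drop = FALSE]
  lapply(seq_len(nrow(cells)), function(i) {
    sub <- metadata[metadata$region == cells$region[i] &
                      metadata$hemisphere == cells$hemisphere[i], , drop = FALSE]
    fem <- sub[sub$sex == "F", , drop = FALSE]
    mal <- sub[sub$sex == "M", , drop = FALSE]
    nf <- length(unique(fem$patient_id))
    nm <- length(unique(mal$patient_id))
    structure(
      list(region = cells$region[i], hemisphere = cells$hemisphere[i],
           female = fem, male = mal, n_female = nf, n_male = nm,
           eligible = nf >= min_patients && nm >= min_patients),
      class = "region_group")
  })
}

#' @export
print.region_group <- function(x, ...) {
  cat(sprintf("region_group %s (%s): %d F / %d M patients, %s\n",
              x$region, x$hemisphere, x$n_female, x$n_male,
              if (x$eligible) "eligible" else "NOT eligible"))
  invisible(x)
}

# Distinct patients with one age each (duplicated channel rows collapse).
distinct_patients <- function(df) {
  u <- df[!duplicated(df$patient_id), c("patient_id", "age"), drop = FALSE]
  u[order(u$patient_id), , drop = FALSE]
}

#' Per-sex age summary of a region group
#'
#' Mean and sample standard deviation (denominator n-1) of distinct patients'
#' ages. A single-patient sex gets `sd = 0` with `sd_defined = FALSE`.
#'
#' @param group a `region_group` from [build_groups()].
#' @return `data.frame` with one row per sex: `sex`, `n`, `mean_years`,
#'   `sd_years`, `sd_defined`.
#' @export
age_summary <- function(group) {
  stopifnot(inherits(group, "region_group"))
  one <- function(df, sex) {
    u <- distinct_patients(df)
    n <- nrow(u)
    s <- if (n >= 2L) sd(u$age) else 0
    data.frame(sex = sex, n = n,
               mean_years = if (n > 0L) mean(u$age) else NA_real_,
               sd_years = s, sd_defined = n >= 2L)
  }
  rbind(one(group$female, "F"), one(group$male, "M"))
}

# Objective for age matching: |meanF - meanM| + lambda * (sdF + sdM).
match_objective <- function(ages_f, ages_m, lambda) {
  abs(mean(ages_f) - mean(ages_m)) + lambda * (sd(ages_f) + sd(ages_m))
}

#' Age-matched subsampling of a region group
#'
#' Selects `k` patients per sex minimizing
#' `|mean(age_F) - mean(age_M)| + lambda * (sd(age_F) + sd(age_M))`,
#' prioritizing the between-sex mean-age difference while shrinking the
#' within-sex spread. The search is exhaustive over all
#' `choose(nF,k) * choose(nM,k)` subset pairs when that product is at most
#' `max_pairs`, otherwise a seeded random search of `n_random` draws. Ties
#' are broken deterministically by the lexicographic order of the sorted
#' selected patient ids.
#'
#' @param group an eligible `region_group`.
#' @param k patients kept per sex (default 5).
#' @param lambda weight of the sd term (default 0.1).
#' @param seed integer seed (used only by the random-search fallback).
#' @param max_pairs exhaustive-search budget on subset-pair count.
#' @param n_random draws of the random-search fallback.
#' @return A `region_group` restricted to the selected patients (channels of
#'   unselected patients dropped), with attribute `"objective"`.
#' @export
age_matched_subsample <- function(group, k = 5L, lambda = 0.1, seed = 1L,
                                  max_pairs = 4e6, n_random = 10000L) {
  stopifnot(inherits(group, "region_group"))
  uf <- distinct_patients(group$female)
  um <- distinct_patients(group$male)
  if (nrow(uf) < k || nrow(um) < k)
    stop(sprintf("need at least %d patients per sex (have %d F, %d M)",
                 k, nrow(uf), nrow(um)))
  subsets <- function(u) {
    idx <- combn(nrow(u), k)
    list(idx = idx,
         mean = apply(idx, 2, function(j) mean(u$age[j])),
         sd = apply(idx, 2, function(j) sd(u$age[j])),
         key = apply(idx, 2, function(j) paste(sort(u$patient_id[j]), collapse = "|")))
  }
  n_pairs <- choose(nrow(uf), k) * choose(nrow(um), k)
  if (n_pairs <= max_pairs) {
    sf <- subsets(uf); sm <- subsets(um)
    obj <- abs(outer(sf$mean, sm$mean, `-`)) + lambda * outer(sf$sd, sm$sd, `+`)
    best <- min(obj)
    cand <- which(obj <= best + 1e-12, arr.ind = TRUE)
    key <- paste(sf$key[cand[, 1]], sm$key[cand[, 2]], sep = "||")
    pick <- cand[order(key)[1L], ]
    sel_f <- uf$patient_id[sf$idx[, pick[1]]]
    sel_m <- um$patient_id[sm$idx[, pick[2]]]
    best_obj <- obj[pick[1], pick[2]]
  } else {
    best_obj <- Inf; sel_f <- sel_m <- NULL; best_key <- ""
    draws <- with_seed(seed, lapply(seq_len(n_random), function(i)
      list(f = sample(nrow(uf), k), m = sample(nrow(um), k))))
    for (d in draws) {
      o <- match_objective(uf$age[d$f], um$age[d$m], lambda)
      key <- paste(paste(sort(uf$patient_id[d$f]), collapse = "|"),
                   paste(sort(um$patient_id[d$m]), collapse = "|"), sep = "||")
      if (o < best_obj - 1e-12 ||
          (abs(o - best_obj) <= 1e-12 && key < best_key)) {
        best_obj <- o
        sel_f <- uf$patient_id[d$f]; sel_m <- um$patient_id[d$m]
        best_key <- key
      }
    }
  }
  fem <- group$female[group$female$patient_id %in% sel_f, , drop = FALSE]
  mal <- group$male[group$male$patient_id %in% sel_m, , drop = FALSE]
  out <- structure(
    list(region = group$region, hemisphere = group$hemisphere,
         female = fem, male = mal, n_female = k, n_male = k,
         eligible = group$eligible),
    class = "region_group")
  attr(out, "objective") <- best_obj
  out
}
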