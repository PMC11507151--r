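#' Mann-Whitney U test (two-sample rank test)
#'
#' Wraps the Wilcoxon rank-sum machinery with the conventions used
#' throughout this package: the exact null distribution when the smaller
#' sample has at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections.
#' The reported statistic is `U = min(U_a, U_b)` (equivalent under the
#' two-sided alternative).
#'
#' Being rank-based, the p-value is invariant under any common strictly
#' monotone transform of both samples.
#'
#' @param a,b numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param method `"auto"` (exact when small and tie-free), `"exact"`, or
#'   `"normal"`.
#' @param exact_max largest min-sample size for which `"auto"` uses the
#'   exact distribution.
#' @return List with `U`, `U_a` (U of sample `a`), `p`, `method` used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p   # exact two-sided p = 0.1
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided",
                           method = c("auto", "exact", "normal"),
                           exact_max = 8L) {
  method <- match.arg(method)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(method,
    auto = min(length(a), length(b)) <= exact_max && !ties,
    exact = TRUE,
    normal = FALSE)
  if (use_exact && ties)
    stop("exact method is unavailable with ties")
  wt <- suppressWarnings(wilcox.test(
    a, b, alternative = alternative, exact = use_exact,
    correct = TRUE))
  u_a <- unname(wt$statistic)                # U of sample a
  u_b <- length(a) * length(b) - u_a
  list(U = min(u_a, u_b), U_a = u_a, p = unname(wt$p.value),
       method = if (use_exact) "exact" else "normal")
}

#' Binary rejection indicator
#'
#' `1` iff `p < alpha` (strict inequality: a p-value exactly at the level is
#' not a rejection).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @return Integer 0/1, vectorized over `p`.
#' @export
h_index <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  as.integer(p < alpha)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' family of tests, with decisions `adjusted < q`.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.05))$adjusted  # 0.04 0.04 0.05 0.05
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj < q)
}

#' Compare one quantifier between sexes within a region
#'
#' Pools window-level quantifier values (entropy `H` or complexity `C`)
#' across all channels and patients of each sex — the accumulation unit of
#' the cohort analysis; note this treats windows as exchangeable and ignores
#' within-patient correlation — then reports per-sex mean/median/sd, the
#' Mann-Whitney U test and the rejection indicator at level `alpha`.
#'
#' @param points_f,points_m `data.frame`s of quantifier points (from
#'   [channel_quantifiers()] or the pipeline), holding the `quantifier`
#'   column.
#' @param quantifier `"H"` or `"C"`.
#' @param alpha significance level.
#' @param region,hemisphere,D labels carried into the output row.
#' @return One-row `data.frame`: region, hemisphere, quantifier, D, per-sex
#'   n/mean/median/sd, `U`, `p_value`, `h`.
#' @export
compare_region <- function(points_f, points_m, quantifier = c("H", "C"),
                           alpha = 0.05, region = NA_character_,
                           hemisphere = NA_character_, D = NA_integer_) {
  quantifier <- match.arg(quantifier)
  vf <- points_f[[quantifier]]
  vm <- points_m[[quantifier]]
  if (length(vf) < 1L || length(vm) < 1L) stop("both groups must be non-empty")
  mw <- mann_whitney_u(vf, vm)
  data.frame(
    region = region, hemisphere = hemisphere, quantifier = quantifier, D = D,
    n_female = length(vf), mean_female = mean(vf), median_female = median(vf),
    sd_female = sd(vf),
    n_male = length(vm), mean_male = mean(vm), median_male = median(vm),
    sd_male = sd(vm),
    U = mw$U, p_value = mw$p, h = h_index(mw$p, alpha),
    stringsAsFactors = FALSE
  )
}

#' Five-number boxplot summary with notch
#'
#' Tukey conventions: quartiles by linear interpolation (quantile type 7),
#' whiskers at the most extreme observations within `1.5 * IQR` of the
#' quartiles, points beyond as outliers, and the notch
#' `median +/- 1.57 * IQR / sqrt(n)` — an approximate 95% confidence
#' interval for the median.
#'
#' @param x numeric sample, `n >= 1`.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `notch_lo`, `notch_hi`, `n`.
#' @export
boxplot_summary <- function(x) {
  n <- length(x)
  if (n < 1L) stop("need at least one observation")
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  half_notch <- 1.57 * iqr / sqrt(n)
  list(median = qs[2], q1 = qs[1], q3 = qs[3],
       whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
       outliers = sort(x[!inside]),
       notch_lo = qs[2] - half_notch, notch_hi = qs[2] + half_notch,
       n = n)
}
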