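#' Vulval induction index
#'
#' The mean number of induced vulval precursor cells (VPCs) per animal: the
#' total number of induced VPCs divided by the number of animals scored. The
#' wild-type value is 3.0 (P5.p, P6.p, P7.p induced in every animal). Reported
#' to one decimal, as is customary.
#'
#' @param induced per-animal induced-VPC counts, each in `[0, 6]` (a vector,
#'   or a data.frame with an `induced_vpcs` column).
#' @return list with `VI` (rounded to one decimal), `VI_raw`, `n`.
#' @export
induction_index <- function(induced) {
  if (is.data.frame(induced)) induced <- induced$induced_vpcs
  if (length(induced) == 0) stop("empty scoring table")
  if (any(is.na(induced)) || any(induced < 0 | induced > 6))
    stop("induced-VPC counts must lie in [0, 6]")
  vi <- sum(induced) / length(induced)
  list(VI = round(vi, 1), VI_raw = vi, n = length(induced))
}

#' Wilson score interval for a proportion
#'
#' The default interval behind every "fraction of animals" error bar:
#' `p_hat = k/n` with the Wilson score interval (via `prop.test` without
#' continuity correction). The Clopper-Pearson interval (`binom.test`) is
#' available by flag.
#'
#' @param k number of positive animals.
#' @param n number scored, `>= 1`.
#' @param level confidence level.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return data.frame `p_hat`, `lo`, `hi`.
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  ci <- if (method == "wilson")
    suppressWarnings(prop.test(k, n, conf.level = level,
                               correct = FALSE)$conf.int)
  else stats::binom.test(k, n, conf.level = level)$conf.int
  data.frame(p_hat = k / n, lo = ci[1], hi = ci[2])
}

#' Welch two-sample t-test
#'
#' Student's t-test for independent samples of unequal variance (Welch
#' statistic with Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param x,y numeric samples, each of size `>= 2` with finite variance.
#' @return list `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    stop("degenerate samples: zero variance and equal means")
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Nonparametric, unpaired rank-sum test. The p-value is exact (by the null
#' permutation distribution of U) when both samples have at most
#' `exact_max_n` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max_n largest per-sample size for the exact path.
#' @return list `U`, `p`, `exact` (flag).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 8L) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Two-sided F-test for equality of variances
#'
#' `F = s_x^2 / s_y^2` referred to the F distribution with `(n_x - 1,
#' n_y - 1)` degrees of freedom; two-sided p-value.
#'
#' @param x,y numeric samples, each of size `>= 2`; `y` must have nonzero
#'   variance.
#' @return list `F`, `df`, `p`.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (sd(y) == 0) stop("zero variance in denominator sample")
  ht <- var.test(x, y)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Significance star code
#'
#' The legend convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Group summary with a chosen test
#'
#' Per-group n, mean, s.d., median and quartiles of a metric, plus the chosen
#' two-group test (Welch t, Mann-Whitney U, or the F-test for variance) with
#' its star code. Groups with a single value have their s.d. flagged as
#' undefined.
#'
#' @param table data.frame of per-animal records.
#' @param metric name of the numeric column to summarize.
#' @param group_col name of the grouping column (default `"genotype"`).
#' @param test `"welch"`, `"mwu"` or `"ftest"` (two groups), or `"none"`.
#' @return list with `summary` (per-group data.frame) and, when a test is
#'   requested, `test`, `statistic`, `p`, `stars`.
#' @export
summarize_groups <- function(table, metric,
                             group_col = "genotype",
                             test = c("none", "welch", "mwu", "ftest")) {
  test <- match.arg(test)
  if (!metric %in% names(table)) stop("unknown metric: ", metric)
  if (!group_col %in% names(table)) stop("unknown group column: ", group_col)
  groups <- split(table[[metric]], table[[group_col]])
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2) stop("need at least 2 groups")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               sd_flag = if (length(v) > 1) "" else "undefined (n = 1)",
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  out <- list(summary = summ)
  if (test != "none") {
    if (length(groups) != 2)
      stop("two-group test requested for ", length(groups), " groups")
    x <- groups[[1]]; y <- groups[[2]]
    res <- switch(test,
                  welch = { r <- welch_t(x, y); list(s = r$t, p = r$p) },
                  mwu = { r <- mann_whitney_u(x, y); list(s = r$U, p = r$p) },
                  ftest = { r <- variance_f_test(x, y); list(s = r$F, p = r$p) })
    out$test <- test
    out$statistic <- res$s
    out$p <- res$p
    out$stars <- star_code(res$p)
  }
  out
}
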