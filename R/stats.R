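#' Independent-samples t test with pooled variance and Cohen's d
#'
#' Student's (pooled-variance) two-sample t test, `df = n1 + n2 - 2`;
#' Cohen's d is the mean difference over the pooled SD. The pooled variant is
#' used throughout because regional synchrony contrasts are reported with
#' pooled degrees of freedom and pooled-SD effect sizes.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List of class `ibs_ttest`: `t`, `df`, `p`, `cohen_d`, `mean_diff`,
#'   `n1`, `n2`.
#' @export
independent_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("degenerate input: zero pooled variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, cohen_d = (mean(a) - mean(b)) / sqrt(sp2),
              mean_diff = mean(a) - mean(b),
              n1 = length(a), n2 = length(b))
  class(res) <- "ibs_ttest"
  res
}

#' Pooled-variance t test from summary statistics
#'
#' Produces the identical result to [independent_ttest()] applied to raw data
#' with the given means, SDs and sizes; used to recover test statistics from
#' published mean +/- SD tables.
#'
#' @param mean1,sd1,n1 Group 1 summary.
#' @param mean2,sd2,n2 Group 2 summary.
#' @return List of class `ibs_ttest` (see [independent_ttest()]).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("degenerate input: zero pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  res <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
              cohen_d = (mean1 - mean2) / sqrt(sp2),
              mean_diff = mean1 - mean2, n1 = n1, n2 = n2)
  class(res) <- "ibs_ttest"
  res
}

#' One-sample t test against a reference value
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param mu Reference value (default 0).
#' @return List of class `ibs_ttest` (`cohen_d` is `(mean - mu) / sd`).
#' @export
one_sample_ttest <- function(values, mu = 0) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s <= 0) stop("degenerate input: zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu)
  res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, cohen_d = (mean(values) - mu) / s,
              mean_diff = mean(values) - mu,
              n1 = length(values), n2 = NA_integer_)
  class(res) <- "ibs_ttest"
  res
}

#' @export
print.ibs_ttest <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, d = %.3f, mean diff = %.4g\n",
              x$df, x$t, x$p, x$cohen_d, x$mean_diff))
  invisible(x)
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg step-up FDR adjustment (default, as used for regional
#' synchrony tables) or Bonferroni.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param method `"fdr_bh"` or `"bonferroni"`.
#' @return Adjusted p values, same order as input.
#' @export
correct_multiple <- function(pvals, method = c("fdr_bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = switch(method, fdr_bh = "BH",
                                         bonferroni = "bonferroni"))
}

#' Pearson correlation with significance
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return List `r`, `p`, `df` (`= n - 2`).
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}

#' Simple-slopes moderation analysis
#'
#' Splits the data by group and fits an ordinary least-squares regression of
#' `y` on `x` within each group, reporting the unstandardized slope, its
#' standard error, t and two-sided p. A group whose slope differs in
#' significance from the other's indicates moderation of the x-y relation by
#' group.
#'
#' @param x Predictor (e.g. frontal delta-PLV).
#' @param y Outcome (e.g. closeness rating).
#' @param groups Group labels, same length as `x`.
#' @return Data frame with one row per group: `group`, `n`, `beta`, `se`,
#'   `t`, `p`.
#' @export
simple_slopes <- function(x, y, groups) {
  stopifnot(length(x) == length(y), length(x) == length(groups))
  out <- lapply(unique(groups), function(g) {
    xi <- x[groups == g]; yi <- y[groups == g]
    if (length(xi) < 3) stop("group ", g, " has fewer than 3 observations",
                             call. = FALSE)
    if (stats::sd(xi) == 0) stop("degenerate input: constant predictor in group ",
                                 g, call. = FALSE)
    fit <- stats::lm(yi ~ xi)
    cf <- summary(fit)$coefficients
    data.frame(group = g, n = length(xi), beta = cf["xi", 1],
               se = cf["xi", 2], t = cf["xi", 3], p = cf["xi", 4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group contrast table over ROI delta-PLV columns
#'
#' Runs [independent_ttest()] (happy vs sad) for each ROI's `dplv_<roi>`
#' column of a dyad summary table and applies multiple-comparison correction
#' across ROIs.
#'
#' @param summary_df Data frame with `group` and `dplv_<roi>` columns.
#' @param rois ROI names (default: every `dplv_` column).
#' @param method Correction method for [correct_multiple()].
#' @return Data frame: `roi`, `t`, `df`, `p`, `p_adj`, `cohen_d`, `mean_diff`.
#' @export
roi_group_contrasts <- function(summary_df, rois = NULL, method = "fdr_bh") {
  cols <- grep("^dplv_", names(summary_df), value = TRUE)
  if (!is.null(rois)) cols <- paste0("dplv_", rois)
  stopifnot(all(cols %in% names(summary_df)), "group" %in% names(summary_df))
  res <- lapply(cols, function(cn) {
    a <- summary_df[[cn]][summary_df$group == "happy"]
    b <- summary_df[[cn]][summary_df$group == "sad"]
    tt <- independent_ttest(a, b)
    data.frame(roi = sub("^dplv_", "", cn), t = tt$t, df = tt$df, p = tt$p,
               cohen_d = tt$cohen_d, mean_diff = tt$mean_diff,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- correct_multiple(res$p, method)
  res[, c("roi", "t", "df", "p", "p_adj", "cohen_d", "mean_diff")]
}
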