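#' Pearson or Spearman correlation with t-based P
#'
#' Pearson by the product-moment formula; Spearman as Pearson on mid-ranks
#' (ties averaged). In both cases the two-sided P comes from the t
#' transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. Constant input is
#' an error (r undefined), as is a length mismatch or n < 3.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row data.frame: `method`, `r`, `p`, `n`.
#' @examples
#' correlate(1:10, (1:10)^3, method = "spearman")  # r = 1
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("'x' and 'y' lengths differ")
  n <- length(x)
  if (n < 3) stopf("correlation needs n >= 3")
  if (anyNA(x) || anyNA(y)) stopf("missing values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 0))
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), n - 2) else 0
  data.frame(method = method, r = r, p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Partial correlation controlling for one or more covariates
#'
#' Correlation between `x` and `y` with the linear influence of the control
#' variables removed, by the recursion
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`
#' applied control-by-control (equivalent to correlating the residuals of
#' regressions on the controls). The two-sided P uses the t transform on
#' `n - 2 - k` df for `k` controls.
#'
#' @param x,y numeric vectors.
#' @param controls numeric vector, matrix or data.frame of control
#'   variables (columns).
#' @return one-row data.frame: `method`, `controls`, `r`, `p`, `n`.
#' @examples
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, z)
#' @export
partial_correlation <- function(x, y, controls) {
  z <- as.matrix(controls)
  n <- length(x)
  if (length(y) != n || nrow(z) != n) stopf("input lengths differ")
  k <- ncol(z)
  if (n < k + 3) stopf("partial correlation needs n >= %d for %d control(s)",
                       k + 3, k)
  cols <- cbind(x = x, y = y, z)
  if (any(apply(cols, 2, stats::sd) == 0)) stopf("constant input variable")

  partial_r <- function(i, j, ctrl) {
    if (!length(ctrl)) {
      r <- stats::cor(cols[, i], cols[, j])
      return(min(max(r, -1), 1))
    }
    c0 <- ctrl[length(ctrl)]
    rest <- ctrl[-length(ctrl)]
    rxy <- partial_r(i, j, rest)
    rxz <- partial_r(i, c0, rest)
    ryz <- partial_r(j, c0, rest)
    den2 <- (1 - rxz^2) * (1 - ryz^2)
    if (den2 <= 0) {
      stopf("degenerate control: |correlation with a control| = 1")
    }
    (rxy - rxz * ryz) / sqrt(den2)
  }
  r <- partial_r(1L, 2L, 2L + seq_len(k))
  r <- min(max(r, -1), 1)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, 0))
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
  cn <- colnames(z)
  data.frame(method = "partial",
             controls = if (is.null(cn)) paste0("z", seq_len(k),
                                                collapse = ",")
                        else paste(cn, collapse = ","),
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Overall F and P from the one-way layout, then each non-control stratum
#' compared with the designated control by Dunnett's test: the two-sided
#' family-wise adjusted P of comparison i is
#' `1 - P(max_j |T_j| <= |t_i|)` under the multivariate t distribution of
#' the comparison statistics (correlation `sqrt(n_i n_j /((n_i+n_0)(n_j+n_0)))`,
#' residual df), evaluated with [mvtnorm::pmvt()].
#'
#' @param values numeric response vector.
#' @param group factor (or coercible) of strata.
#' @param control label of the control stratum (default: first level).
#' @return list of class `group_comparison`: `strata` (per-stratum n,
#'   mean, sd), `F`, `p_overall`, `comparisons` (data.frame with raw t and
#'   Dunnett-adjusted p per stratum vs control).
#' @export
anova_dunnett <- function(values, group, control = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need >= 2 strata")
  if (length(values) != length(group)) stopf("input lengths differ")
  if (is.null(control)) control <- levels(group)[1]
  if (!control %in% levels(group)) stopf("unknown control stratum '%s'", control)
  ns <- tapply(values, group, length)
  if (any(ns < 2)) stopf("every stratum needs n >= 2")
  means <- tapply(values, group, mean)
  sds <- tapply(values, group, stats::sd)
  k <- nlevels(group)
  N <- length(values)
  ss_between <- sum(ns * (means - mean(values))^2)
  ss_within <- sum((values - means[group])^2)
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0 && ss_between == 0) stopf("all observations identical")
  mse <- ss_within / df2
  Fstat <- (ss_between / df1) / mse
  p_overall <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  others <- setdiff(levels(group), control)
  n0 <- ns[[control]]
  lam <- sqrt(ns[others] / (ns[others] + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  tstat <- (means[others] - means[[control]]) /
    sqrt(mse * (1 / ns[others] + 1 / n0))
  adj <- vapply(tstat, function(t0) {
    if (!is.finite(t0)) return(0)
    q <- abs(t0)
    pr <- mvtnorm::pmvt(lower = rep(-q, length(others)),
                        upper = rep(q, length(others)),
                        df = df2, corr = corr, type = "shifted")
    max(0, min(1, 1 - pr))
  }, numeric(1))
  structure(list(
    strata = data.frame(stratum = levels(group), n = as.integer(ns),
                        mean = as.numeric(means), sd = as.numeric(sds)),
    F = Fstat, p_overall = p_overall,
    comparisons = data.frame(stratum = others, t = as.numeric(tstat),
                             p_adjusted = adj, stringsAsFactors = FALSE),
    control = control
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, P = %.4g (control: %s)\n",
              x$F, x$p_overall, x$control))
  print(x$strata, row.names = FALSE)
  cat("Dunnett comparisons vs control:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Chi-square test for rates across conditions
#'
#' Pearson chi-square on the 2 x k table of damaged vs undamaged counts
#' (`k - 1` df, no continuity correction), the standard test for comparing
#' damage rates between several independent experiments.
#'
#' @param damaged integer vector of damaged counts per condition (k >= 2).
#' @param total integer vector of total counts per condition (all > 0).
#' @return one-row data.frame: `statistic`, `df`, `p`.
#' @examples
#' chi_square_rate(c(10, 30), c(100, 100))
#' @export
chi_square_rate <- function(damaged, total) {
  if (length(damaged) != length(total)) stopf("input lengths differ")
  if (length(damaged) < 2) stopf("need >= 2 conditions")
  if (any(total <= 0)) stopf("all totals must be > 0")
  if (any(damaged < 0 | damaged > total)) {
    stopf("damaged counts must lie in [0, total]")
  }
  tab <- rbind(damaged = damaged, undamaged = total - damaged)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stopf("expected cell count of zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(statistic = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value)
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Fold change of a target transcript normalized to a reference gene and a
#' calibrator sample: `fold = 2^-ddCt` with
#' `ddCt = (Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   cycle-threshold values (finite; vectorized).
#' @return fold change(s).
#' @examples
#' relative_quantification(22, 20, 25, 20)  # ddCt = -3, fold = 8
#' @export
relative_quantification <- function(ct_target_sample, ct_ref_sample,
                                    ct_target_calibrator,
                                    ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_calibrator,
               ct_ref_calibrator)
  if (any(!is.finite(cts))) stopf("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Stratify an exposure variable at fixed cut points
#'
#' Half-open intervals, lower-closed/upper-open (`[low, high)`), with the
#' last stratum open above — a value equal to a cut point enters the
#' higher-labelled stratum. A value below the first cut point is an error.
#'
#' @param values numeric exposure values.
#' @param cuts strictly increasing cut points; the first is the lower
#'   bound of the first stratum.
#' @return factor of stratum labels (e.g. `"[0,2)"`, `"[2,5)"`, `">=5"`),
#'   with per-stratum counts in attribute `"counts"`.
#' @examples
#' table(stratify_exposure(c(0.5, 2, 7), cuts = c(0, 2, 5)))
#' @export
stratify_exposure <- function(values, cuts) {
  if (is.unsorted(cuts, strictly = TRUE)) {
    stopf("'cuts' must be strictly increasing")
  }
  if (any(values < cuts[1])) {
    stopf("value(s) below the lower bound %g: %s", cuts[1],
          toString(utils::head(values[values < cuts[1]], 3)))
  }
  labels <- c(sprintf("[%g,%g)", cuts[-length(cuts)], cuts[-1]),
              sprintf(">=%g", cuts[length(cuts)]))
  idx <- findInterval(values, cuts)  # lower-closed by construction
  out <- factor(labels[idx], levels = labels)
  attr(out, "counts") <- table(out)
  out
}
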