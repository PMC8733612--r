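# Mass-univariate group statistics: ANCOVA with an age covariate per
# frequency bin / electrode, Bonferroni correction, partial correlation
# with clinical scales controlling age, age-slope regressions, Welch
# t-tests.

#' ANCOVA of one measure on group with age as covariate
#'
#' Fits the equal-slopes linear model `y = b0 + b1 * group + b2 * age`
#' (group coded 0/1, age centered) and tests the group term with the nested
#' F statistic `F = ((SSE_reduced - SSE_full) / 1) / (SSE_full / (n - 3))`,
#' where the reduced model omits group; p from F(1, n - 3).
#'
#' @param values numeric outcome vector.
#' @param group_labels two-level factor/character vector (the second level,
#'   or `"patient"`, is coded 1).
#' @param ages numeric covariate.
#' @return Named numeric vector: `F`, `p`, `df1`, `df2`, `group_effect`
#'   (the adjusted group coefficient).
#' @export
ancova_group_age <- function(values, group_labels, ages) {
  stopifnot(length(values) == length(group_labels),
            length(values) == length(ages), all(is.finite(ages)))
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  g <- code_group(group_labels)
  if (length(unique(g)) < 2) stop("both groups must be non-empty")
  if (stats::var(values) == 0) {
    return(c(F = 0, p = 1, df1 = 1, df2 = n - 3, group_effect = 0))
  }
  a <- ages - mean(ages)
  Xf <- cbind(1, g, a)
  if (qr(Xf)$rank < 3) stop("group and age are collinear")
  full <- stats::lm.fit(Xf, values)
  red <- stats::lm.fit(cbind(1, a), values)
  sse_f <- sum(full$residuals^2)
  sse_r <- sum(red$residuals^2)
  Fv <- ((sse_r - sse_f) / 1) / (sse_f / (n - 3))
  c(F = Fv, p = stats::pf(Fv, 1, n - 3, lower.tail = FALSE), df1 = 1,
    df2 = n - 3, group_effect = unname(full$coefficients[2]))
}

code_group <- function(group_labels) {
  if (is.numeric(group_labels)) return(as.numeric(group_labels != group_labels[1]))
  gl <- as.character(group_labels)
  lev <- unique(gl)
  if (length(lev) != 2) stop("exactly two groups required")
  ref <- if ("control" %in% lev) "control" else lev[1]
  as.numeric(gl != ref)
}

#' Per-bin ANCOVA across a measure spectrum
#'
#' Runs [ancova_group_age()] for every frequency bin of a subjects x bins
#' matrix (typically whole-brain values) and applies Bonferroni correction
#' across bins (threshold `alpha / m_bins`; 353 for 0.125-Hz power bins,
#' 44 for 1-Hz DFA/fE/I bins).
#'
#' @param values subjects x bins numeric matrix.
#' @param groups,ages per-subject group labels and ages.
#' @param m_bins Bonferroni family size (defaults to `ncol(values)`).
#' @param alpha nominal significance level.
#' @param bins optional bin identifiers for the output.
#' @return A `group_test` data frame: bin, F, p, significant_unc,
#'   significant_bonf; attribute `"ranges"` lists contiguous
#'   Bonferroni-significant bin runs.
#' @export
spectrum_group_test <- function(values, groups, ages, m_bins = NULL,
                                alpha = 0.05, bins = NULL) {
  values <- as.matrix(values)
  if (is.null(m_bins)) m_bins <- ncol(values)
  if (is.null(bins)) bins <- colnames(values) %||% seq_len(ncol(values))
  res <- t(apply(values, 2, function(v) {
    r <- ancova_group_age(v, groups, ages)
    c(r["F"], r["p"])
  }))
  out <- data.frame(bin = bins, F = res[, 1], p = res[, 2],
                    significant_unc = res[, 2] < alpha,
                    significant_bonf = res[, 2] < alpha / m_bins,
                    row.names = NULL)
  attr(out, "bonferroni_threshold") <- alpha / m_bins
  attr(out, "ranges") <- significant_ranges(out$bin, out$significant_bonf)
  class(out) <- c("group_test", "data.frame")
  out
}

significant_ranges <- function(bins, sig) {
  if (!any(sig)) return(list())
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(which(r$values), function(k) c(bins[starts[k]], bins[ends[k]]))
}

#' Per-electrode ANCOVA for topographic statistics
#'
#' [ancova_group_age()] at every electrode of a subjects x electrodes
#' matrix, Bonferroni-corrected across the 19 electrodes.
#'
#' @param values subjects x electrodes numeric matrix.
#' @param groups,ages per-subject group labels and ages.
#' @param alpha nominal significance level.
#' @return A `group_test` data frame with one row per electrode.
#' @export
electrode_group_test <- function(values, groups, ages, alpha = 0.05) {
  values <- as.matrix(values)
  spectrum_group_test(values, groups, ages, m_bins = ncol(values),
                      alpha = alpha,
                      bins = colnames(values) %||% seq_len(ncol(values)))
}

#' Partial correlation controlling for age
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' regressing each on age; two-sided t test with `n - 3` degrees of
#' freedom. Incomplete observations are dropped pairwise.
#'
#' @param x,y numeric vectors (e.g. an EEG measure and a clinical scale;
#'   either may contain NA).
#' @param age numeric covariate.
#' @return Named vector: `rho`, `p`, `n`.
#' @export
partial_correlation_age <- function(x, y, age) {
  keep <- stats::complete.cases(x, y, age)
  x <- x[keep]; y <- y[keep]; age <- age[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete observations")
  rx <- stats::lm.fit(cbind(1, age), x)$residuals
  ry <- stats::lm.fit(cbind(1, age), y)$residuals
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  tval <- rho * sqrt((n - 3) / max(1e-300, 1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tval), n - 3), n = n)
}

#' Age-slope regression within a group
#'
#' OLS regression of a measure on age; reports the slope with its t value
#' and two-sided p. Subset the inputs to one group before calling.
#'
#' @param values numeric outcomes.
#' @param ages numeric ages (must vary).
#' @return Named vector: `slope`, `t`, `p`, `df`.
#' @export
age_slope <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  if (length(values) < 3) stop("need at least 3 observations")
  if (stats::var(ages) == 0) stop("ages are constant; slope undefined")
  fit <- stats::lm(values ~ ages)
  sm <- summary(fit)$coefficients
  c(slope = unname(sm[2, 1]), t = unname(sm[2, 3]), p = unname(sm[2, 4]),
    df = fit$df.residual)
}

#' Welch two-sample t test between subgroups
#'
#' Independent-samples t test with unequal variances (Welch), e.g. for
#' comparing recording cohorts within a group.
#'
#' @param values numeric outcomes.
#' @param labels two-level subgroup labels.
#' @return Named vector: `t`, `p`, `df`.
#' @export
subgroup_ttest <- function(values, labels) {
  lev <- unique(as.character(labels))
  if (length(lev) != 2) stop("exactly two subgroups required")
  a <- values[labels == lev[1]]
  b <- values[labels == lev[2]]
  if (length(a) < 2 || length(b) < 2) stop("each subgroup needs >= 2 observations")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  c(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
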