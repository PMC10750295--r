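# Associating gene-set scores with drug sensitivity and patient outcome:
# Pearson correlation with OLS regression line, mutation-stratified
# regression, expression dichotomization and the two-group log-rank test
# with Kaplan-Meier curves.

#' Pearson correlation with OLS regression line
#'
#' Pairs with a missing value on either side are dropped (pairwise-complete
#' deletion) and counted. The two-sided p-value comes from the t transform
#' of r; the line is ordinary least squares of y on x.
#'
#' @param x a `ScoreVector` or numeric vector.
#' @param y numeric response per sample (same order/length as `x`).
#' @param x_name,y_name labels for the report.
#' @param stratum optional stratum label carried through.
#' @return a list of class `AssociationResult`: `x_name`, `y_name`, `n`,
#'   `n_dropped`, `pearson_r`, `r_p`, `slope`, `intercept`, `stratum`.
#' @export
correlate <- function(x, y, x_name = NULL, y_name = "response", stratum = NULL) {
  if (inherits(x, "ScoreVector")) {
    x_name <- x_name %||% x$score_name
    x <- x$values
  }
  x_name <- x_name %||% "score"
  if (length(x) != length(y)) stop_sx("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_sx("correlate needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_sx("degenerate correlation: zero variance in x or y")
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  structure(list(x_name = x_name, y_name = y_name, n = n,
                 n_dropped = n_dropped, pearson_r = r, r_p = p,
                 slope = slope, intercept = intercept, stratum = stratum),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("%s vs %s%s: n = %d, r = %.3f (p = %.3g), y = %.3f %+.3f x\n",
              x$x_name, x$y_name,
              if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              x$n, x$pearson_r, x$r_p, x$intercept, x$slope))
  invisible(x)
}

#' Mutation-stratified regression
#'
#' Fits an independent OLS line per stratum (wild-type vs mutant) and reports
#' the vertical offset between the stratum lines evaluated at the pooled mean
#' of x — the operational reading of "less sensitive regardless of expression
#' level". Samples with unknown status are excluded and counted; strata with
#' fewer than `min_n` pairs are skipped with a log entry.
#'
#' @param x a `ScoreVector` or numeric vector.
#' @param y numeric response per sample.
#' @param strata character vector per sample: `"wild_type"`, `"mutant"` or
#'   `"unknown"`/NA.
#' @param min_n minimum pairs per stratum (default 3).
#' @param x_name,y_name labels.
#' @return list with `per_stratum` (named list of `AssociationResult`),
#'   `offset_at_mean` (line of the second stratum minus the first at pooled
#'   mean x; NA if < 2 strata fitted), `pooled_mean_x`, `n_unknown`.
#' @export
stratified_regression <- function(x, y, strata, min_n = 3L,
                                  x_name = NULL, y_name = "response") {
  if (inherits(x, "ScoreVector")) {
    x_name <- x_name %||% x$score_name
    x <- x$values
  }
  x_name <- x_name %||% "score"
  strata <- as.character(strata)
  known <- !is.na(strata) & strata %in% c("wild_type", "mutant")
  n_unknown <- sum(!known)
  if (n_unknown > 0L) sx_log(n_unknown, " sample(s) with unknown status excluded")
  levels_present <- intersect(c("wild_type", "mutant"), unique(strata[known]))
  fits <- list()
  for (s in levels_present) {
    sel <- known & strata == s & is.finite(x) & is.finite(y)
    if (sum(sel) < min_n) {
      sx_log("stratum ", s, " below min_n = ", min_n, ", skipped")
      next
    }
    fits[[s]] <- correlate(x[sel], y[sel], x_name = x_name, y_name = y_name,
                           stratum = s)
  }
  pooled_ok <- known & is.finite(x) & is.finite(y)
  pooled_mean_x <- mean(x[pooled_ok])
  offset <- NA_real_
  if (length(fits) == 2L) {
    pred <- vapply(fits, function(f) f$intercept + f$slope * pooled_mean_x, 0)
    offset <- pred[[2L]] - pred[[1L]]
  }
  list(per_stratum = fits, offset_at_mean = offset,
       pooled_mean_x = pooled_mean_x, n_unknown = n_unknown)
}

#' Dichotomize a score into high/low groups
#'
#' High = strictly above the cutpoint; low = at or below (ties at the
#' cutpoint go low, and are counted in a log entry). Default cutpoint is the
#' median; a different quantile may be configured.
#'
#' @param scores a `ScoreVector` or numeric vector; needs >= 4 values.
#' @param rule `"median"` or `"quantile"`.
#' @param q quantile in (0,1) when `rule = "quantile"`.
#' @return factor with levels `c("low", "high")` plus attributes `cutpoint`
#'   and `n_ties`.
#' @export
dichotomize <- function(scores, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  v <- if (inherits(scores, "ScoreVector")) scores$values else scores
  if (length(v) < 4L) stop_sx("dichotomize needs >= 4 samples")
  if (length(unique(v)) == 1L) stop_sx("all score values identical; cannot split")
  cut <- if (rule == "median") stats::median(v) else stats::quantile(v, q, names = FALSE)
  n_ties <- sum(v == cut)
  if (n_ties > 0L) sx_log(n_ties, " value(s) tied at cutpoint assigned to 'low'")
  g <- factor(ifelse(v > cut, "high", "low"), levels = c("low", "high"))
  attr(g, "cutpoint") <- cut
  attr(g, "n_ties") <- n_ties
  g
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard 1-df log-rank chi-square over the pooled event times, with
#' product-limit survival curves per group. The statistic uses the usual
#' observed-minus-expected form with hypergeometric variance.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param group two-level factor or character vector.
#' @return a list of class `SurvivalComparison`: `n_per_group`,
#'   `logrank_chi2`, `logrank_p`, `observed`, `expected`, `km_curves`
#'   (per group, data.frame of `time`, `surv`).
#' @export
logrank_test <- function(time, event, group) {
  if (!(length(time) == length(event) && length(event) == length(group))) {
    stop_sx("time, event, group must have equal length")
  }
  ok <- is.finite(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- as.integer(event[ok]); group <- as.character(group[ok])
  levs <- sort(unique(group))
  if (length(levs) != 2L) stop_sx("log-rank comparison needs exactly 2 groups")
  if (sum(event) < 1L) stop_sx("log-rank needs >= 1 event")
  g1 <- group == levs[[1L]]

  # walk the pooled distinct event times
  etimes <- sort(unique(time[event == 1L]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1L, lower.tail = FALSE) else 1

  km <- lapply(levs, function(lv) {
    sel <- group == lv
    km_curve(time[sel], event[sel])
  })
  names(km) <- levs

  structure(list(groups = levs,
                 n_per_group = stats::setNames(c(sum(g1), sum(!g1)), levs),
                 logrank_chi2 = chi2, logrank_p = p,
                 observed = O1, expected = E1, variance = V,
                 km_curves = km),
            class = "SurvivalComparison")
}

# Product-limit estimator; curve starts at (0, 1) and steps at event times.
km_curve <- function(time, event) {
  ts <- sort(unique(time[event == 1L]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[[i]])
    d <- sum(time == ts[[i]] & event == 1L)
    s <- s * (1 - d / n)
    surv[[i]] <- s
  }
  data.frame(time = c(0, ts), surv = c(1, surv))
}

#' @export
print.SurvivalComparison <- function(x, ...) {
  cat(sprintf("Log-rank: chi2 = %.4f (1 df), p = %.4g; groups %s (n=%d) vs %s (n=%d)\n",
              x$logrank_chi2, x$logrank_p,
              x$groups[[1L]], x$n_per_group[[1L]],
              x$groups[[2L]], x$n_per_group[[2L]]))
  invisible(x)
}

#' Median-split survival comparison for a score
#'
#' Dichotomizes a score ([dichotomize()]) and compares survival between the
#' high and low groups by log-rank. The cutpoint choice is the dominant
#' reproducibility knob and is therefore echoed loudly in the result.
#'
#' @param scores a `ScoreVector` or numeric vector (one value per subject).
#' @param time,event survival follow-up and 0/1 event indicator.
#' @param rule,q passed to [dichotomize()].
#' @return a `SurvivalComparison` with extra fields `cutpoint_rule`,
#'   `cutpoint`, `n_high`, `n_low`.
#' @export
survival_by_score <- function(scores, time, event, rule = "median", q = 0.5) {
  g <- dichotomize(scores, rule = rule, q = q)
  if (length(unique(g[!is.na(g)])) < 2L) {
    stop_sx("dichotomization produced a single group")
  }
  res <- logrank_test(time, event, g)
  res$cutpoint_rule <- if (rule == "median") "median" else sprintf("quantile %g", q)
  res$cutpoint <- attr(g, "cutpoint")
  res$n_high <- sum(g == "high")
  res$n_low <- sum(g == "low")
  sx_log("survival split by ", res$cutpoint_rule, " at cutpoint ",
         signif(res$cutpoint, 4),
         " — cutpoint choice drives this comparison; report it with results")
  res
}
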