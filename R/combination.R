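# Chou-Talalay median-effect synergy analysis: fraction-affected conversion,
# median-effect fitting on the log-odds linearization, dose-for-effect
# inversion, the two-term (mutually exclusive) combination index, and the
# checkerboard CI surface.

FA_EPS <- 0.01  # boundary clamp for fraction affected before log-odds

#' Convert percent-of-control viability to fraction affected
#'
#' `fa = 1 - percent/100`, then clamped into `[eps, 1 - eps]` because the
#' median-effect linearization takes log-odds of fa. Clamps are logged.
#'
#' @param percent_of_control viability as percent of untreated control.
#' @param eps boundary clamp (default 0.01).
#' @return numeric vector of fa values strictly inside (0, 1).
#' @export
fa_from_viability <- function(percent_of_control, eps = FA_EPS) {
  if (any(percent_of_control < 0, na.rm = TRUE)) {
    stop_sx("negative percent-of-control viability")
  }
  fa <- 1 - percent_of_control / 100
  n_clamp <- sum(fa < eps | fa > 1 - eps, na.rm = TRUE)
  if (n_clamp > 0L) sx_log(n_clamp, " fa value(s) clamped to [", eps, ", ", 1 - eps, "]")
  pmin(pmax(fa, eps), 1 - eps)
}

#' Fit the median-effect equation to a single-agent dose response
#'
#' The median-effect model is `fa/fu = (D/Dm)^m`; on the linearization
#' `log(fa/(1-fa)) = m log D - m log Dm` it is fit by least squares.
#' Replicate fa values at the same dose are averaged on the fa scale first.
#'
#' @param doses strictly positive doses.
#' @param fa fraction affected per dose, strictly inside (0, 1).
#' @return list of class `MedianEffectParams`: `m` (slope), `Dm` (median
#'   effect dose), `r` (correlation of the linearized fit), `n_points`,
#'   `flagged` (TRUE when m <= 0).
#' @export
fit_median_effect <- function(doses, fa) {
  if (length(doses) != length(fa)) stop_sx("doses and fa must match")
  ok <- is.finite(doses) & is.finite(fa)
  doses <- doses[ok]; fa <- fa[ok]
  if (any(doses <= 0)) stop_sx("doses must be strictly positive")
  if (any(fa <= 0 | fa >= 1)) stop_sx("fa must be strictly inside (0, 1)")
  fa <- tapply(fa, doses, mean)
  d <- as.numeric(names(fa))
  fa <- as.numeric(fa)
  if (length(d) < 2L) stop_sx("median-effect fit needs >= 2 distinct doses")
  x <- log(d)
  y <- log(fa / (1 - fa))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- fit$coefficients[[2L]]
  b <- fit$coefficients[[1L]]
  flagged <- FALSE
  if (!is.finite(m) || m <= 0) {
    warning("median-effect slope m <= 0; fit flagged", call. = FALSE)
    flagged <- TRUE
  }
  r <- if (length(d) > 2L) stats::cor(x, y) else 1
  structure(list(m = m, Dm = exp(-b / m), r = r, n_points = length(d),
                 flagged = flagged),
            class = "MedianEffectParams")
}

#' @export
print.MedianEffectParams <- function(x, ...) {
  cat(sprintf("Median-effect fit: m = %.4g, Dm = %.4g (r = %.4f, %d doses)%s\n",
              x$m, x$Dm, x$r, x$n_points, if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm (fa/(1-fa))^(1/m)`.
#'
#' @param params a `MedianEffectParams`.
#' @param fa effect level strictly inside (0, 1).
#' @return dose(s) in the agent's concentration units.
#' @export
dose_for_effect <- function(params, fa) {
  if (any(fa <= 0 | fa >= 1)) stop_sx("fa must be strictly inside (0, 1)")
  params$Dm * (fa / (1 - fa))^(1 / params$m)
}

#' Effect at a dose under a median-effect fit
#'
#' @param params a `MedianEffectParams`.
#' @param dose strictly positive dose(s).
#' @return fraction affected.
#' @export
effect_at_dose <- function(params, dose) {
  if (any(dose <= 0)) stop_sx("dose must be strictly positive")
  1 / (1 + (params$Dm / dose)^params$m)
}

#' Chou-Talalay combination index at an observed combination effect
#'
#' `CI = D1/Dx1(fa) + D2/Dx2(fa)` where `Dxi` is the single-agent dose of
#' agent i producing the combination's observed effect (the classic
#' mutually-exclusive two-term form). The non-exclusive variant adds the
#' cross term `(D1 D2)/(Dx1 Dx2)`. CI below `1 - delta` is called synergy,
#' above `1 + delta` antagonism, otherwise additive.
#'
#' @param fit1,fit2 `MedianEffectParams` for the two agents.
#' @param D1,D2 combination doses (either may be 0, reducing to the other
#'   agent's single term).
#' @param fa_combo observed fraction affected of the combination, interior.
#' @param delta additive band half-width (default 0.1).
#' @param exclusive use the two-term form (default TRUE).
#' @return list of class `CIResult`: `fa`, `D1`, `D2`, `Dx1`, `Dx2`, `CI`,
#'   `call`, `flagged`.
#' @export
combination_index <- function(fit1, fit2, D1, D2, fa_combo, delta = 0.1,
                              exclusive = TRUE) {
  if (fa_combo <= 0 || fa_combo >= 1) stop_sx("fa_combo must be interior")
  if (D1 < 0 || D2 < 0) stop_sx("doses must be non-negative")
  flagged <- isTRUE(fit1$flagged) || isTRUE(fit2$flagged)
  Dx1 <- dose_for_effect(fit1, fa_combo)
  Dx2 <- dose_for_effect(fit2, fa_combo)
  ci <- D1 / Dx1 + D2 / Dx2
  if (!exclusive) ci <- ci + (D1 * D2) / (Dx1 * Dx2)
  call <- if (ci < 1 - delta) "synergy" else if (ci > 1 + delta) "antagonism" else "additive"
  structure(list(fa = fa_combo, D1 = D1, D2 = D2, Dx1 = Dx1, Dx2 = Dx2,
                 CI = ci, call = call, flagged = flagged),
            class = "CIResult")
}

#' Combination-index surface over a checkerboard grid
#'
#' Takes a full two-agent grid including single-agent margins (rows where the
#' other agent's dose is 0), fits the median-effect model per agent from its
#' margin, and computes one `CIResult` per interior combination cell using
#' that cell's observed fa.
#'
#' @param grid data.frame with columns `agent1_dose`, `agent2_dose`, `fa`
#'   (or `percent_of_control`, converted via [fa_from_viability()]).
#'   Rows with both doses 0 (untreated control) are ignored.
#' @param delta,exclusive passed to [combination_index()].
#' @return data.frame of class `ci_surface`: one row per interior cell with
#'   `agent1_dose`, `agent2_dose`, `fa`, `Dx1`, `Dx2`, `CI`, `call`.
#' @export
ci_surface <- function(grid, delta = 0.1, exclusive = TRUE) {
  if (!"fa" %in% colnames(grid)) {
    if (!"percent_of_control" %in% colnames(grid)) {
      stop_sx("grid needs an 'fa' or 'percent_of_control' column")
    }
    grid$fa <- fa_from_viability(grid$percent_of_control)
  }
  need <- c("agent1_dose", "agent2_dose", "fa")
  if (!all(need %in% colnames(grid))) {
    stop_sx("grid needs columns: ", paste(need, collapse = ", "))
  }
  m1 <- grid$agent2_dose == 0 & grid$agent1_dose > 0
  m2 <- grid$agent1_dose == 0 & grid$agent2_dose > 0
  interior <- grid$agent1_dose > 0 & grid$agent2_dose > 0
  if (!any(m1) || !any(m2)) stop_sx("grid is missing single-agent margins")
  fit1 <- fit_median_effect(grid$agent1_dose[m1], grid$fa[m1])
  fit2 <- fit_median_effect(grid$agent2_dose[m2], grid$fa[m2])
  cells <- grid[interior, , drop = FALSE]
  # average replicates per interior dose pair on the fa scale
  key <- paste(cells$agent1_dose, cells$agent2_dose, sep = "\r")
  fa_cell <- tapply(cells$fa, key, mean)
  keys <- names(fa_cell)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- do.call(rbind, lapply(seq_along(keys), function(i) {
    d1 <- as.numeric(parts[i, 1L]); d2 <- as.numeric(parts[i, 2L])
    ci <- combination_index(fit1, fit2, d1, d2, fa_cell[[i]],
                            delta = delta, exclusive = exclusive)
    data.frame(agent1_dose = d1, agent2_dose = d2, fa = ci$fa,
               Dx1 = ci$Dx1, Dx2 = ci$Dx2, CI = ci$CI, call = ci$call,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$agent1_dose, out$agent2_dose), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit1") <- fit1
  attr(out, "fit2") <- fit2
  class(out) <- c("ci_surface", "data.frame")
  out
}
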