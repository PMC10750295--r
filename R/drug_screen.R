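# Subtype-stratified drug-specificity screen over IC50 z-scores:
# per-drug one-way ANOVA as a gate, Tukey HSD post-hoc, and the
# lowest-mean-with-significance specificity rule.

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups a named list of numeric vectors (one per group); NAs dropped.
#' @return list with `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `group_means`, `group_ns`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  k <- length(groups)
  if (k < 2L) stop_sx("one_way_anova needs >= 2 groups with >= 2 finite values")
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0) stop_sx("degenerate ANOVA: all within-group variances are zero")
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2, ms_within = ssw / df2,
       group_means = means, group_ns = ns)
}

#' Tukey HSD pairwise comparisons (Tukey-Kramer for unbalanced groups)
#'
#' Every unordered pair of groups gets a studentized-range adjusted p-value
#' based on the pooled within-group variance. Pairs are reported in canonical
#' alphabetical order with `mean_diff = mean_a - mean_b`.
#'
#' @param groups a named list of numeric vectors; NAs dropped.
#' @return data.frame with columns `subtype_a`, `subtype_b`, `mean_diff`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  a <- one_way_anova(groups)
  nms <- names(a$group_means)
  if (is.null(nms)) stop_sx("tukey_hsd needs named groups")
  k <- length(nms)
  pairs <- utils::combn(sort(nms), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[[1L]]; j <- pr[[2L]]
    diff <- a$group_means[[i]] - a$group_means[[j]]
    se <- sqrt(a$ms_within / 2 * (1 / a$group_ns[[i]] + 1 / a$group_ns[[j]]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
    c(mean_diff = diff, p_adj = p)
  })
  data.frame(subtype_a = pairs[1L, ], subtype_b = pairs[2L, ],
             mean_diff = res["mean_diff", ], p_adj = res["p_adj", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify subtype specificity of a drug
#'
#' A drug is S-specific iff, for every other subtype T, the mean response in
#' S is strictly lower (more sensitive, lower IC50 z) than in T and the
#' Tukey-adjusted p for the (S, T) pair is below `alpha`. The rule is applied
#' symmetrically to every subtype; at most one subtype can satisfy it. Ties
#' at the minimum mean yield `"none"`.
#'
#' @param pairwise data.frame as returned by [tukey_hsd()].
#' @param group_means named numeric vector of per-subtype means.
#' @param alpha significance level (default 0.05).
#' @return a label: `"<subtype>_specific"`, `"none"`, or
#'   `"insufficient_data"` when a required pair is missing.
#' @export
classify_specificity <- function(pairwise, group_means, alpha = 0.05) {
  subtypes <- names(group_means)
  pair_p <- function(s, t) {
    hit <- (pairwise$subtype_a == s & pairwise$subtype_b == t) |
      (pairwise$subtype_a == t & pairwise$subtype_b == s)
    if (!any(hit)) return(NA_real_)
    pairwise$p_adj[which(hit)[[1L]]]
  }
  for (s in subtypes) {
    others <- setdiff(subtypes, s)
    ps <- vapply(others, function(t) pair_p(s, t), 0)
    if (anyNA(ps)) return("insufficient_data")
    lower <- vapply(others, function(t) group_means[[s]] < group_means[[t]], NA)
    if (all(lower) && all(ps < alpha)) return(paste0(s, "_specific"))
  }
  "none"
}

#' Run the full subtype-specificity drug screen
#'
#' For each drug: drop missing responses, require at least `min_n` lines in
#' every subtype (otherwise the drug is labelled `insufficient_data`), run
#' one-way ANOVA; drugs passing the raw ANOVA gate (`anova_p < alpha`)
#' proceed to Tukey HSD and the specificity rule, all others are labelled
#' `none`. Results are sorted by ANOVA p.
#'
#' @param resp a [drug_response_matrix()].
#' @param ann a [sample_annotation()] covering every line in `resp`.
#' @param alpha ANOVA gate and pairwise significance level (default 0.05).
#' @param min_n minimum non-missing lines per subtype per drug (default 3).
#' @param adjust_anova if `TRUE`, apply Benjamini-Hochberg across drugs to the
#'   ANOVA p before gating (off by default; the gate is on raw p).
#' @return list of class `screen_result` with elements `results` (data.frame:
#'   `drug_id`, `anova_p`, `label`, per-subtype n columns), `pairwise`
#'   (data.frame of per-drug Tukey comparisons) and `p_matrix` (pairs x drugs
#'   matrix of adjusted p-values for heat-map rendering).
#' @export
run_screen <- function(resp, ann, alpha = 0.05, min_n = 3L, adjust_anova = FALSE) {
  if (!all(rownames(resp) %in% ann$sample_id)) {
    stop_sx("every line in the response matrix needs a subtype annotation")
  }
  subtype <- ann$subtype[match(rownames(resp), ann$sample_id)]
  subtypes <- sort(unique(subtype))
  if (length(subtypes) < 2L) stop_sx("screen needs >= 2 subtypes")

  per_drug <- lapply(colnames(resp), function(d) {
    z <- resp[, d]
    ok <- is.finite(z)
    groups <- split(z[ok], subtype[ok])
    ns <- vapply(subtypes, function(s) length(groups[[s]] %||% numeric(0)), 0L)
    names(ns) <- subtypes
    if (any(ns < min_n)) {
      sx_log("drug ", d, ": subtype below min_n, labelled insufficient_data")
      return(list(drug_id = d, anova_p = NA_real_, label = "insufficient_data",
                  ns = ns, pairwise = NULL, means = NULL))
    }
    a <- one_way_anova(groups)
    list(drug_id = d, anova_p = a$p, label = NA_character_, ns = ns,
         means = a$group_means, groups = groups)
  })

  anova_p <- vapply(per_drug, function(x) x$anova_p, 0)
  gate_p <- if (adjust_anova) stats::p.adjust(anova_p, "BH") else anova_p

  pairwise_all <- list()
  for (i in seq_along(per_drug)) {
    x <- per_drug[[i]]
    if (!is.na(x$label)) next  # insufficient_data
    if (is.na(gate_p[[i]]) || gate_p[[i]] >= alpha) {
      per_drug[[i]]$label <- "none"
      next
    }
    pw <- tukey_hsd(x$groups)
    per_drug[[i]]$label <- classify_specificity(pw, x$means, alpha)
    pw$drug_id <- x$drug_id
    pairwise_all[[length(pairwise_all) + 1L]] <- pw
  }

  results <- data.frame(
    drug_id = vapply(per_drug, `[[`, "", "drug_id"),
    anova_p = anova_p,
    label = vapply(per_drug, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  ns_mat <- t(vapply(per_drug, `[[`,
                     stats::setNames(integer(length(subtypes)), subtypes), "ns"))
  colnames(ns_mat) <- paste0("n_", subtypes)
  results <- cbind(results, as.data.frame(ns_mat))
  results <- results[order(results$anova_p), , drop = FALSE]
  rownames(results) <- NULL

  pairwise <- if (length(pairwise_all) > 0L) {
    do.call(rbind, pairwise_all)
  } else {
    data.frame(subtype_a = character(0), subtype_b = character(0),
               mean_diff = numeric(0), p_adj = numeric(0),
               drug_id = character(0), stringsAsFactors = FALSE)
  }

  pair_names <- apply(utils::combn(subtypes, 2L), 2L,
                      function(pr) paste(pr, collapse = "-"))
  p_matrix <- matrix(NA_real_, length(pair_names), ncol(resp),
                     dimnames = list(pair_names, colnames(resp)))
  if (nrow(pairwise) > 0L) {
    key <- paste(pairwise$subtype_a, pairwise$subtype_b, sep = "-")
    p_matrix[cbind(match(key, pair_names), match(pairwise$drug_id, colnames(resp)))] <-
      pairwise$p_adj
  }

  structure(list(results = results, pairwise = pairwise, p_matrix = p_matrix,
                 alpha = alpha, min_n = min_n),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  hits <- x$results[!x$results$label %in% c("none", "insufficient_data"), ]
  cat(sprintf("Drug screen: %d drugs, %d subtype-specific hits (alpha = %g)\n",
              nrow(x$results), nrow(hits), x$alpha))
  if (nrow(hits) > 0L) print(utils::head(hits, 20L))
  invisible(x)
}

#' Re-standardize a drug-response matrix per drug
#'
#' Recomputes z-scores per drug column across the supplied panel (mean 0,
#' sample sd with n-1 denominator), ignoring missing cells. Intended for
#' synthetic panels; real GDSC exports come pre-standardized.
#'
#' @param resp a [drug_response_matrix()].
#' @return a re-standardized [drug_response_matrix()].
#' @export
standardize_response <- function(resp) {
  z <- apply(unclass(resp), 2L, function(col) {
    ok <- is.finite(col)
    if (sum(ok) < 2L) return(col)
    (col - mean(col[ok])) / stats::sd(col[ok])
  })
  rownames(z) <- rownames(resp)
  drug_response_matrix(z)
}
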