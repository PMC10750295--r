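# Formula-defined expression scores: per-gene z-standardization across
# samples, sum-of-z signature scores (YAP/TAZ target score, focal-adhesion
# score), raw-sum scores (CLDN score, YAP1+WWTR1), and the expressed-gene
# filter used to narrow a candidate list to genes actually expressed.

#' Standardize each gene across samples
#'
#' Each gene row is mapped to (x - mean) / sd with the sample standard
#' deviation (n - 1 denominator). Zero-variance rows map to all-zero and are
#' logged. An optional `log2(x + 1)` pre-transform is available but off by
#' default: scores are computed on the matrix as supplied.
#'
#' @param mat an [expression_matrix()]; needs >= 2 samples.
#' @param log_transform apply `log2(x + 1)` before standardizing.
#' @return an [expression_matrix()] with `value_kind = "zscore"`.
#' @export
zscore_by_gene <- function(mat, log_transform = FALSE) {
  if (ncol(mat) < 2L) stop_sx("z-standardization needs >= 2 samples")
  v <- unclass(mat)
  if (log_transform) v <- log2(v + 1)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  degenerate <- sdv == 0 | !is.finite(sdv)
  if (any(degenerate)) {
    sx_log(sum(degenerate), " zero-variance gene row(s) mapped to all-zero z")
    sdv[degenerate] <- 1
    mu[degenerate] <- v[degenerate, 1L]
  }
  z <- (v - mu) / sdv
  expression_matrix(z, value_kind = "zscore")
}

#' Gene-set activity score per sample
#'
#' `kind = "z_sum"`: per-sample sum of per-gene z-scores (computed across
#' samples with [zscore_by_gene()]) over the set genes present in the matrix
#' — the form of the YAP/TAZ target score and the focal-adhesion score.
#' `kind = "raw_sum"`: per-sample sum of raw expression values — the form of
#' the CLDN score and the YAP1+WWTR1 expression sum. Set genes absent from
#' the matrix are reported in `genes_missing`, never imputed.
#'
#' @param mat an [expression_matrix()].
#' @param set a [gene_set()].
#' @param kind `"z_sum"` or `"raw_sum"`.
#' @param log_transform passed to [zscore_by_gene()] when `kind = "z_sum"`.
#' @return a list of class `ScoreVector`: `score_name`, `sample_ids`,
#'   `values`, `value_kind`, `genes_used`, `genes_missing`.
#' @export
geneset_score <- function(mat, set, kind = c("z_sum", "raw_sum"),
                          log_transform = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(set, "GeneSet"))
  row_canon <- canon_gene(rownames(mat))
  idx <- match(set$genes, row_canon)
  used <- set$genes[!is.na(idx)]
  missing <- set$genes[is.na(idx)]
  if (length(used) == 0L) {
    stop_sx("no genes of set '", set$name, "' are present in the matrix")
  }
  if (length(missing) > 0L) {
    sx_log("set '", set$name, "': ", length(missing), " gene(s) absent from matrix")
  }
  basis <- if (kind == "z_sum") {
    zscore_by_gene(mat, log_transform = log_transform)
  } else {
    mat
  }
  vals <- colSums(unclass(basis)[idx[!is.na(idx)], , drop = FALSE])
  structure(list(score_name = set$name, sample_ids = colnames(mat),
                 values = unname(vals), value_kind = kind,
                 genes_used = used, genes_missing = missing),
            class = "ScoreVector")
}

#' @export
print.ScoreVector <- function(x, ...) {
  cat(sprintf("ScoreVector '%s' (%s): %d samples, %d/%d set genes used\n",
              x$score_name, x$value_kind, length(x$values),
              length(x$genes_used),
              length(x$genes_used) + length(x$genes_missing)))
  invisible(x)
}

#' CLDN score: raw sum of the claudin-low marker quartet
#'
#' Per-sample sum of raw CLDN3 + CLDN4 + CLDN7 + CDH1 expression. Low values
#' mark the claudin-low subtype.
#'
#' @param mat an [expression_matrix()].
#' @return a `ScoreVector` with `score_name = "CLDN"`.
#' @export
cldn_score <- function(mat) {
  geneset_score(mat, cldn_gene_set(), kind = "raw_sum")
}

#' Filter a candidate gene list to expressed genes
#'
#' Mirrors the narrowing of a gene-ontology candidate list to the genes
#' confirmed expressed in the cohort (e.g. ~420 focal-adhesion candidates to
#' the 408 expressed ones). Default policy: nonzero in at least `min_frac`
#' of samples.
#'
#' @param mat an [expression_matrix()].
#' @param candidate_genes character vector of candidate symbols.
#' @param policy `"nonzero_frac"` (default) or `"present"` (simply present as
#'   a row of the matrix).
#' @param min_frac fraction of samples that must be nonzero (default 0.5).
#' @param name name for the returned set.
#' @return a [gene_set()] of retained candidates (input order preserved).
#' @export
filter_expressed <- function(mat, candidate_genes,
                             policy = c("nonzero_frac", "present"),
                             min_frac = 0.5, name = "expressed") {
  policy <- match.arg(policy)
  if (length(candidate_genes) == 0L) stop_sx("empty candidate list")
  cand <- canon_gene(candidate_genes)
  row_canon <- canon_gene(rownames(mat))
  idx <- match(cand, row_canon)
  keep <- !is.na(idx)
  if (policy == "nonzero_frac") {
    frac <- rep(0, length(cand))
    frac[keep] <- rowMeans(unclass(mat)[idx[keep], , drop = FALSE] != 0, na.rm = TRUE)
    keep <- keep & frac >= min_frac
  }
  sx_log("expressed-gene filter: ", sum(keep), " of ", length(cand),
         " candidates retained (policy ", policy, ")")
  if (!any(keep)) stop_sx("no candidate genes pass the expression filter")
  gene_set(name, cand[keep])
}

#' Compare a score across subtypes
#'
#' Per-subtype summary (n, mean, median, IQR) plus the screen module's
#' one-way ANOVA and Tukey HSD applied to the score values. Subtypes with
#' fewer than 2 samples are excluded with a log entry.
#'
#' @param scores a `ScoreVector`.
#' @param ann a [sample_annotation()] covering the score's samples.
#' @return list with `summary` (data.frame), `anova` (list from
#'   [one_way_anova()]) and `pairwise` (data.frame from [tukey_hsd()]).
#' @export
subtype_score_comparison <- function(scores, ann) {
  subtype <- ann$subtype[match(scores$sample_ids, ann$sample_id)]
  if (anyNA(subtype)) stop_sx("every scored sample needs a subtype annotation")
  groups <- split(scores$values, subtype)
  small <- names(groups)[vapply(groups, length, 0L) < 2L]
  if (length(small) > 0L) {
    sx_log("excluding subtype(s) with < 2 samples: ", paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2L) stop_sx("need >= 2 subtypes with >= 2 samples")
  summary_df <- data.frame(
    subtype = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    median = vapply(groups, stats::median, 0),
    iqr = vapply(groups, stats::IQR, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(summary = summary_df,
       anova = one_way_anova(groups),
       pairwise = tukey_hsd(groups))
}
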