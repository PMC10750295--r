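# Domain containers. Deliberately light S3 wrappers around base structures:
# the matrices stay plain numeric matrices with dimnames so that every stats
# function in base R applies directly, and the class carries the invariants.

#' Construct an expression matrix
#'
#' A gene-by-sample matrix of non-negative expression values (counts or
#' normalized expression) or per-gene z-scores, with unique gene and sample
#' identifiers carried as dimnames.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene symbols, colnames are sample identifiers.
#' @param value_kind one of `"counts"`, `"normalized"`, `"zscore"`. Unless
#'   `"zscore"`, all finite entries must be non-negative.
#' @return an object of class `ExpressionMatrix` (a classed matrix).
#' @export
expression_matrix <- function(values,
                              value_kind = c("counts", "normalized", "zscore")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_sx("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_sx("gene identifiers must be unique")
  if (anyDuplicated(colnames(values))) stop_sx("sample identifiers must be unique")
  if (value_kind != "zscore") {
    fin <- values[is.finite(values)]
    if (any(fin < 0)) stop_sx("expression values must be non-negative")
  }
  structure(values, value_kind = value_kind,
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "value_kind")))
  invisible(x)
}

#' Construct a drug-response matrix of IC50 z-scores
#'
#' Cell lines in rows, drugs in columns; entries are z-scores of ln IC50
#' across the panel each drug was standardized on. Missing values (drug not
#' assayed on a line) are allowed and never imputed.
#'
#' @param z_ic50 numeric matrix with line rownames and drug colnames.
#' @return an object of class `DrugResponseMatrix`.
#' @export
drug_response_matrix <- function(z_ic50) {
  z_ic50 <- as.matrix(z_ic50)
  storage.mode(z_ic50) <- "double"
  if (is.null(rownames(z_ic50)) || is.null(colnames(z_ic50))) {
    stop_sx("drug-response matrix needs line rownames and drug colnames")
  }
  if (anyDuplicated(rownames(z_ic50))) stop_sx("line identifiers must be unique")
  if (anyDuplicated(colnames(z_ic50))) stop_sx("drug identifiers must be unique")
  structure(z_ic50, class = c("DrugResponseMatrix", "matrix", "array"))
}

#' @export
print.DrugResponseMatrix <- function(x, ...) {
  cat(sprintf("DrugResponseMatrix: %d lines x %d drugs, %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Construct a named gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols; must be non-empty and unique
#'   after canonicalization (trimming, upper case).
#' @return an object of class `GeneSet`.
#' @export
gene_set <- function(name, genes) {
  genes <- canon_gene(genes)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop_sx("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) stop_sx("gene set '", name, "' has duplicate genes")
  structure(list(name = as.character(name), genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' The claudin-low marker quartet
#'
#' Low expression of claudin-3, -4, -7 and E-cadherin defines the claudin-low
#' intrinsic subtype; their raw-sum is the CLDN score.
#'
#' @return a `GeneSet` containing CLDN3, CLDN4, CLDN7, CDH1.
#' @export
cldn_gene_set <- function() {
  gene_set("CLDN", c("CLDN3", "CLDN4", "CLDN7", "CDH1"))
}

#' Construct per-sample annotations
#'
#' @param sample_id character vector of unique sample/line identifiers.
#' @param subtype subtype label per sample (e.g. Luminal, Basal, HER2,
#'   ClaudinLow).
#' @param ihc_group optional receptor-status group per sample.
#' @param survival_time optional non-negative follow-up time (months).
#' @param survival_event optional 0/1 event indicator; must be present exactly
#'   where `survival_time` is.
#' @param ... further per-sample columns, e.g. `PIK3CA = c("wild_type", ...)`
#'   mutation-status vectors.
#' @return a `data.frame` of class `SampleAnnotation`.
#' @export
sample_annotation <- function(sample_id, subtype, ihc_group = NULL,
                              survival_time = NULL, survival_event = NULL, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop_sx("sample identifiers must be unique")
  ann <- data.frame(sample_id = sample_id, subtype = as.character(subtype),
                    stringsAsFactors = FALSE)
  if (!is.null(ihc_group)) ann$ihc_group <- as.character(ihc_group)
  if (xor(is.null(survival_time), is.null(survival_event))) {
    stop_sx("survival_time and survival_event must be supplied together")
  }
  if (!is.null(survival_time)) {
    if (any(survival_time < 0, na.rm = TRUE)) stop_sx("negative survival_time")
    if (!all(survival_event %in% c(0, 1, NA))) stop_sx("survival_event must be 0/1")
    if (any(xor(is.na(survival_time), is.na(survival_event)))) {
      stop_sx("survival_event present iff survival_time present")
    }
    ann$survival_time <- as.numeric(survival_time)
    ann$survival_event <- as.integer(survival_event)
  }
  extra <- list(...)
  for (nm in names(extra)) ann[[nm]] <- extra[[nm]]
  class(ann) <- c("SampleAnnotation", "data.frame")
  ann
}
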