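# Readers and writers for every external table the pipeline touches.
# All readers preserve input row/column order, treat "", "NA", "NaN", "null"
# as missing, and never impute. Writers emit "NA" for missing cells so a
# write-then-read round trip preserves values and missingness exactly.

MISSING_TOKENS <- c("", "NA", "NaN", "null")

sx_sep <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (dialect == "csv") "," else "\t"
}

read_table_raw <- function(path, sep) {
  if (!file.exists(path)) stop_sx("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      na.strings = MISSING_TOKENS, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop_sx("empty or unreadable file: ", path)
  )
  if (nrow(df) == 0L) stop_sx("empty or header-only file: ", path)
  df
}

parse_numeric_cells <- function(df, path) {
  # first column is identifiers; remaining must be numeric or missing
  ids <- df[[1L]]
  num <- as.matrix(df[, -1L, drop = FALSE])
  out <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num),
                                 dimnames = list(NULL, colnames(num))))
  bad <- which(is.na(out) & !is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_sx(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                    ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path))
  }
  rownames(out) <- ids
  out
}

#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' First column holds gene identifiers, header row the sample identifiers.
#' Duplicate gene rows are handled by `duplicate_genes`; the applied rule is
#' reported through the provenance attribute and a log message.
#'
#' @param path file path (TSV or CSV; extension decides unless `dialect` set).
#' @param dialect `"auto"` (default), `"tsv"` or `"csv"`.
#' @param duplicate_genes `"error"` (default), `"sum"`, `"mean"` or `"first"`.
#' @param value_kind passed to [expression_matrix()].
#' @return an [expression_matrix()] with a `provenance` attribute.
#' @export
read_expression_matrix <- function(path, dialect = "auto",
                                   duplicate_genes = c("error", "sum", "mean", "first"),
                                   value_kind = "counts") {
  duplicate_genes <- match.arg(duplicate_genes)
  sep <- sx_sep(path, dialect)
  df <- read_table_raw(path, sep)
  mat <- parse_numeric_cells(df, path)
  ids <- rownames(mat)
  if (anyDuplicated(ids)) {
    if (duplicate_genes == "error") {
      stop_sx("duplicate gene rows in ", path, " (set duplicate_genes to collapse)")
    }
    sx_log("collapsing duplicate gene rows by rule '", duplicate_genes, "'")
    keep_order <- unique(ids)
    mat <- switch(duplicate_genes,
      sum   = rowsum_na(mat, ids, mean_ = FALSE),
      mean  = rowsum_na(mat, ids, mean_ = TRUE),
      first = mat[!duplicated(ids), , drop = FALSE]
    )
    mat <- mat[keep_order, , drop = FALSE]
  }
  out <- expression_matrix(mat, value_kind = value_kind)
  attr(out, "provenance") <- list(path = path, duplicate_rule = duplicate_genes)
  out
}

# rowsum that keeps NA semantics: a group's cell is NA only if all its
# members are NA; otherwise the sum/mean of the finite members.
rowsum_na <- function(mat, groups, mean_ = FALSE) {
  s <- rowsum(ifelse(is.na(mat), 0, mat), groups, reorder = FALSE)
  n <- rowsum((!is.na(mat)) + 0, groups, reorder = FALSE)
  out <- if (mean_) s / n else s
  out[n == 0] <- NA_real_
  out
}

#' Write an expression matrix to TSV/CSV
#'
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_expression_matrix <- function(mat, path, dialect = "auto") {
  sep <- sx_sep(path, dialect)
  df <- data.frame(gene_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then one or more gene symbols. The description field is discarded.
#'
#' @param path GMT file path.
#' @return a named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_sx("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_sx("empty GMT file: ", path)
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L) {
      stop_sx(sprintf("GMT line %d has fewer than 3 fields (name, description, genes)", i))
    }
    gene_set(f[[1L]], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects.
#' @param path output path.
#' @param descriptions optional character vector of descriptions (default "na").
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(sets[[i]]$name, descriptions[[i]], sets[[i]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a line-by-drug IC50 z-score table
#'
#' Accepts either a wide layout (first column line identifiers, one column
#' per drug) or a long layout with columns `line`/`drug`/`z` (header names
#' containing "line", "drug" and one of "z"/"zscore"/"z_ic50"). The layout is
#' auto-detected from the header. Missing cells are preserved, never imputed.
#'
#' @param path TSV/CSV path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return a [drug_response_matrix()].
#' @export
read_drug_response <- function(path, dialect = "auto") {
  sep <- sx_sep(path, dialect)
  df <- read_table_raw(path, sep)
  hdr <- tolower(colnames(df))
  long <- ncol(df) == 3L && any(grepl("line|sample|cell", hdr[1L])) &&
    any(grepl("drug", hdr[2L]))
  if (long) {
    line <- df[[1L]]; drug <- df[[2L]]
    z <- suppressWarnings(as.numeric(df[[3L]]))
    bad <- which(is.na(z) & !is.na(df[[3L]]))
    if (length(bad) > 0L) {
      stop_sx(sprintf("non-numeric z value at data row %d in %s", bad[[1L]], path))
    }
    key <- paste(line, drug, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][[1L]]
      stop_sx("duplicate (line, drug) pair in long table: ",
              gsub("\r", " / ", d, fixed = TRUE))
    }
    lines_u <- unique(line); drugs_u <- unique(drug)
    mat <- matrix(NA_real_, length(lines_u), length(drugs_u),
                  dimnames = list(lines_u, drugs_u))
    mat[cbind(match(line, lines_u), match(drug, drugs_u))] <- z
  } else {
    mat <- parse_numeric_cells(df, path)
  }
  drug_response_matrix(mat)
}

#' Write a drug-response matrix (wide layout)
#'
#' @param resp a [drug_response_matrix()].
#' @param path output path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_drug_response <- function(resp, path, dialect = "auto") {
  sep <- sx_sep(path, dialect)
  df <- data.frame(line_id = rownames(resp), as.data.frame(unclass(resp)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read per-sample annotations from TSV/CSV
#'
#' Requires `sample_id` and `subtype` columns; any further columns (e.g.
#' `ihc_group`, mutation-status columns, `survival_time`/`survival_event`)
#' are carried through.
#'
#' @param path TSV/CSV path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return a [sample_annotation()] data frame.
#' @export
read_sample_annotation <- function(path, dialect = "auto") {
  sep <- sx_sep(path, dialect)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          na.strings = MISSING_TOKENS, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype")
  if (!all(need %in% colnames(df))) {
    stop_sx("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  args <- c(list(sample_id = df$sample_id, subtype = df$subtype),
            df[setdiff(colnames(df), need)])
  do.call(sample_annotation, args)
}

#' Write per-sample annotations
#'
#' @param ann a [sample_annotation()].
#' @param path output path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_sample_annotation <- function(ann, path, dialect = "auto") {
  sep <- sx_sep(path, dialect)
  utils::write.table(as.data.frame(ann), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and package version alongside results so
#' a run can be reconstructed.
#'
#' @param path output JSON path.
#' @param inputs named list of input file paths.
#' @param params named list of parameters.
#' @param seed integer seed used (or NULL).
#' @export
write_run_manifest <- function(path, inputs = list(), params = list(), seed = NULL) {
  manifest <- list(
    package = "subtyperx",
    version = as.character(utils::packageVersion("subtyperx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
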