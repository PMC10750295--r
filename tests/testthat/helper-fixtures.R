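# Shared fixture builders. Everything is generated in code; no binary files.

quiet_sx <- function(code) withr::with_options(list(subtyperx.quiet = TRUE), code)

# tiny gene x sample matrix with explicit values
tiny_expr <- function(values, genes, samples, value_kind = "counts") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, value_kind = value_kind)
}

# a three-subtype response panel built from per-group normal draws
make_groups <- function(ns, means, sd = 1) {
  g <- mapply(function(n, mu) rnorm(n, mu, sd), ns, means, SIMPLIFY = FALSE)
  names(g) <- names(ns) %||% paste0("g", seq_along(g))
  g
}

# permutation-based one-way ANOVA p-value: an oracle independent of the
# F-distribution path (compares the F statistic against its permutation null)
perm_anova_p <- function(groups, n_perm = 2000L) {
  obs <- one_way_anova(groups)$F
  pooled <- unlist(groups)
  sizes <- vapply(groups, length, 0L)
  idx <- rep(seq_along(groups), sizes)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    shuffled <- split(sample(pooled), idx)
    if (one_way_anova(shuffled)$F >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# write a small table to a temp file and return the path
tmp_write <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
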