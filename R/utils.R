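#' @keywords internal
"_PACKAGE"

# Run code under an explicit seed without touching the caller's RNG stream.
# Every generator in the package routes its randomness through this helper,
# so identical (config, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sx_log <- function(...) {
  if (!isTRUE(getOption("subtyperx.quiet", FALSE))) {
    message("[subtyperx] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sx <- function(...) stop(..., call. = FALSE)

# Gene identifiers are matched case-insensitively after whitespace trimming;
# no alias or ortholog mapping is attempted.
canon_gene <- function(x) toupper(trimws(as.character(x)))
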