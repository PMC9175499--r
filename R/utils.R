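# Internal helpers shared across modules.

#' @keywords internal
geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so generators are pure functions of (spec, seed).
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
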