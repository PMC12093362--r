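#' @importFrom stats median mad predict quantile rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv head modifyList
#' @importClassesFrom ChemmineR FPset
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded pipeline stages do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stage seed from a run seed; kept below .Machine$integer.max.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + as.numeric(offset)) %% 2147483587)
}

# md5 of a character vector (order-sensitive); used to fingerprint training sets.
hashStrings <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) && x >= 0
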