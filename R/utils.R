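#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded generators never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

## locale-independent (C collation) sort/order for identifiers and keys,
## so canonical orderings do not depend on the session locale
csort <- function(x, ...) x[corder(x, ...)]
corder <- function(...) order(..., method = "radix")

## named integer vector (0/1) -> stable string key, names sorted
lit_key <- function(x) {
  if (!length(x)) return("")
  x <- x[corder(names(x))]
  paste(paste0(names(x), "=", unname(x)), collapse = ",")
}
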