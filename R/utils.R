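#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global random-number stream set to `seed`, then
#' restores the previous stream so simulations do not perturb user-level
#' randomness. All generators in this package route their randomness through
#' this helper, which is what makes identical (spec, seed) pairs reproduce
#' tables bit-for-bit.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# stopifnot-style check with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "fg")
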