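stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so seeded
#' package functions do not perturb the session RNG. With `seed = NULL` the
#' expression simply uses the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# round-half-up, used for the 6:2:2 patient-count arithmetic
round_half_up <- function(x) floor(x + 0.5)

is_binary_mask <- function(m) {
  is.matrix(m) && all(m == 0L | m == 1L)
}

check_same_shape <- function(a, b, what_a = "image", what_b = "mask") {
  if (!identical(dim(a), dim(b))) {
    stopf("%s and %s shapes differ: %s vs %s", what_a, what_b,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
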