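#' @keywords internal
#' @useDynLib rhizoseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhizoseg_invalid_input", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhizoseg_config_error", "error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library functions do not
#' perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

is_binary <- function(x) all(x == 0 | x == 1)
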