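`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package route their draws through this
#' helper so that the caller's RNG state is never disturbed and every draw is
#' reproducible from an integer seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a per-task child seed from a master seed and a counter, staying
# inside 32-bit integer range so set.seed() accepts it.
child_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 16807) %% 2147483587L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single value in [0, 1]", name)
  }
  invisible(x)
}
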