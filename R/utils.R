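#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile sd var fft rnorm runif rbinom qnorm pnorm pt
#'   predict coef p.adjust setNames aggregate
#' @importFrom utils head tail
NULL

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a reproducible child seed from a parent seed, kept inside 32-bit range.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_actidep <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "actidep_error")))
}
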