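#' @importFrom stats coef lm lm.fit optim pf predict qf quantile rnorm
#'   rlnorm rmultinom runif sd setNames var
#' @importFrom utils modifyList
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rf <- function(..., class = "rumenfiber_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "rumenfiber_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_rf(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_rf(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

#' Deterministic child seed
#'
#' Derives a stream-specific 32-bit seed from a master seed so that the
#' taxonomy, community and kinetics generators draw from independent,
#' reproducible streams.
#' @noRd
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 2147483L) %% 2147480509L
}
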