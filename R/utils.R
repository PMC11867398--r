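#' @importFrom rlang .data %||% abort warn
#' @importFrom stats qnorm plnorm qlnorm rlnorm rgamma pnorm setNames
#' @importFrom stats pexp pweibull pgamma plogis runif rnorm rbinom quantile
#' @importFrom stats coef logLik AIC BIC optim sd var median qgamma qbeta rbeta
#' @importFrom stats predict uniroot
NULL

# scalar numeric check used by input validators
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_prob <- function(x, name) {
  if (!all(is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) abort(sprintf("`%s` must be %s.", name, if (strict) "positive" else "non-negative"))
  invisible(x)
}

#' Discount a value to present terms
#'
#' Convention used throughout: the first model cycle is undiscounted and cycle
#' `t` is discounted by `(1 + rate)^-(t - 1)`.
#'
#' @param value Numeric vector of amounts (costs in EUR or effects in QALYs).
#' @param rate Annual discount rate (e.g. `0.04` for costs, `0.015` for effects).
#' @param cycle Integer vector of one-based cycle indices, recycled against
#'   `value`.
#' @return Discounted numeric vector.
#' @examples
#' discount(104, 0.04, 2)  # 100
#' discount(100, 0.04, 1)  # unchanged
#' @export
discount <- function(value, rate, cycle) {
  if (any(cycle < 1)) abort("`cycle` must be >= 1 (cycle 1 is undiscounted).")
  assert_positive(rate, "rate", strict = FALSE)
  value / (1 + rate)^(cycle - 1)
}

# derive a reproducible 32-bit child seed from a master seed and a stage label
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% .Machine$integer.max
}
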