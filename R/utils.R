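# Internal helpers shared across modules.

#' Truncated normal deviates
#'
#' Draws from a normal distribution truncated to `(lower, upper)` by inverse-CDF
#' sampling. Used for ground-truth onset times, which are reported in the field
#' as mean +/- sd within a bounded observation window.
#'
#' @param n number of draws
#' @param mean,sd normal parameters; `sd` must be non-negative
#' @param lower,upper open truncation bounds
#' @return numeric vector of length `n`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(sd) == 1L)
  if (sd < 0) stop("sd must be non-negative")
  if (lower >= upper) stop("lower must be < upper")
  if (sd == 0) {
    if (mean <= lower || mean >= upper) stop("degenerate draw outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Derive a reproducible child seed from a user seed and a stage label, keeping
# the result inside the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
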