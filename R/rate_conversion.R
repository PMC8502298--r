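#' Convert an event probability to a constant instantaneous rate
#'
#' Under a constant-hazard (exponential) assumption, a probability `p` of an
#' event occurring at least once over a horizon of `t` months corresponds to
#' the rate `r = -ln(1 - p) / t` (events per month). This is the standard
#' transform used to move trial event probabilities between time horizons,
#' e.g. annual probabilities to the monthly cycle length of a Markov model.
#'
#' @param p Event probability, a numeric vector with values in `[0, 1)`.
#' @param horizon Horizon over which `p` applies, in months (> 0). Default 1.
#' @return Rate in events per month (same length as `p`).
#' @seealso [rate_to_prob()], [rescale_prob()]
#' @examples
#' prob_to_rate(0.5, horizon = 1)    # -log(0.5) ~ 0.693 per month
#' prob_to_rate(0.0906, horizon = 12)
#' @export
prob_to_rate <- function(p, horizon = 1) {
  check_prob(p, allow_one = FALSE)
  check_horizon(horizon)
  -log1p(-p) / horizon
}

#' Convert a constant rate to an event probability over a horizon
#'
#' Inverse of [prob_to_rate()]: `p = 1 - exp(-r * t)`, the probability of at
#' least one event over `horizon` months under a constant rate `r`.
#'
#' @param r Rate in events per month (>= 0), numeric vector.
#' @param horizon Horizon in months (> 0). Default 1.
#' @return Event probability over `horizon`.
#' @export
rate_to_prob <- function(r, horizon = 1) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("rate must be finite and >= 0", call. = FALSE)
  }
  check_horizon(horizon)
  -expm1(-r * horizon)
}

#' Rescale an event probability to a different horizon
#'
#' Composition of [prob_to_rate()] and [rate_to_prob()]: converts a
#' probability over `horizon` months into the equivalent probability over
#' `new_horizon` months under the constant-hazard assumption. Identity when
#' `new_horizon == horizon`. This is how annual trial probabilities become
#' monthly transition probabilities.
#'
#' @param p Event probability in `[0, 1)`.
#' @param horizon Horizon over which `p` was measured, months.
#' @param new_horizon Target horizon, months.
#' @return Probability over `new_horizon`.
#' @examples
#' rescale_prob(0.0906, horizon = 12, new_horizon = 1)  # annual -> monthly
#' @export
rescale_prob <- function(p, horizon, new_horizon) {
  rate_to_prob(prob_to_rate(p, horizon), new_horizon)
}

check_prob <- function(p, allow_one = TRUE, what = "probability") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  if (!allow_one && any(p == 1)) {
    stop(what, " of 1 has no finite rate; the model never needs certain events",
         call. = FALSE)
  }
  invisible(p)
}

check_horizon <- function(horizon) {
  if (any(!is.finite(horizon)) || any(horizon <= 0)) {
    stop("horizon must be a positive number of months", call. = FALSE)
  }
  invisible(horizon)
}
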