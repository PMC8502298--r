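#' Method-of-moments beta parameters
#'
#' Matches a beta distribution to a mean and standard deviation:
#' `nu = m(1-m)/sd^2 - 1`, `shape1 = m * nu`, `shape2 = (1-m) * nu`.
#' Used for probability and utility inputs in the probabilistic sensitivity
#' analysis.
#'
#' @param mean Target mean, in (0, 1).
#' @param sd Target standard deviation, > 0 with `sd^2 < mean*(1-mean)`.
#' @return List with `shape1`, `shape2`.
#' @examples
#' beta_from_moments(0.77, 0.016)  # shape1 ~ 531.9, shape2 ~ 158.9
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta mean must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop("beta sd must be > 0 (a zero-dispersion input is a point mass, not a beta)",
         call. = FALSE)
  }
  if (sd^2 >= mean * (1 - mean)) {
    stop("beta variance must be < mean*(1-mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = (mean/sd)^2`, `rate = shape/mean`. Used for cost inputs; with the
#' published half-ranges equal to half the mean, every cost distribution has
#' shape 4.
#'
#' @param mean Target mean, > 0.
#' @param sd Target standard deviation, > 0.
#' @return List with `shape`, `rate`.
#' @examples
#' gamma_from_moments(450, 225)  # shape 4, rate 1/112.5
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd <= 0) {
    stop("gamma mean and sd must be > 0", call. = FALSE)
  }
  shape <- (mean / sd)^2
  list(shape = shape, rate = shape / mean)
}

# Draw n values from a distribution spec; sd = 0 degenerates to the mean.
sample_spec <- function(spec, n) {
  if (spec$sd == 0) return(rep(spec$mean, n))
  if (spec$family == "beta") {
    p <- beta_from_moments(spec$mean, spec$sd)
    stats::rbeta(n, p$shape1, p$shape2)
  } else if (spec$family == "gamma") {
    p <- gamma_from_moments(spec$mean, spec$sd)
    stats::rgamma(n, shape = p$shape, rate = p$rate)
  } else {
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  }
}

# Quantile-transform a uniform draw through a distribution spec.
quantile_spec <- function(spec, u) {
  if (spec$sd == 0) return(spec$mean)
  if (spec$family == "beta") {
    p <- beta_from_moments(spec$mean, spec$sd)
    stats::qbeta(u, p$shape1, p$shape2)
  } else if (spec$family == "gamma") {
    p <- gamma_from_moments(spec$mean, spec$sd)
    stats::qgamma(u, shape = p$shape, rate = p$rate)
  } else {
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  }
}

#' Default one-way sensitivity bounds for a configuration
#'
#' The published analysis does not state its bound convention, so bounds are
#' config-first: for each parameter with a sampling distribution, the default
#' is mean +/- 1 SD for beta-distributed inputs (probabilities, utilities;
#' truncated to their valid ranges) and mean +/- the printed half-range for
#' gamma-distributed costs (the half-range equals the SD throughout).
#'
#' @param config A validated model configuration.
#' @return Data frame with `parameter`, `low`, `high`.
#' @export
default_dsa_bounds <- function(config) {
  specs <- config$distributions
  out <- data.frame(parameter = names(specs),
                    low = NA_real_, high = NA_real_)
  for (i in seq_along(specs)) {
    d <- specs[[i]]
    lo <- max(d$mean - d$sd, 0)
    hi <- d$mean + d$sd
    if (d$family == "beta") hi <- min(hi, 1)
    out$low[i] <- lo
    out$high[i] <- hi
  }
  out
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the base case once at the low and once at the high bound of each
#' parameter, holding all others at base value, and records the ICER per QALY
#' at each bound. Entries are returned sorted by span (absolute ICER
#' difference) in decreasing order — the tornado ordering. A bound that
#' violates a type invariant (e.g. probabilities summing past 1) is reported
#' as a per-parameter warning and skipped; the run continues.
#'
#' @param config A validated model configuration.
#' @param bounds Optional data frame with `parameter`, `low`, `high`
#'   (defaults to [default_dsa_bounds()]).
#' @return A data frame of class `tornado` with `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`, sorted by decreasing span.
#' @export
one_way_dsa <- function(config, bounds = NULL) {
  validate_config(config)
  bounds <- bounds %||% default_dsa_bounds(config)
  stopifnot(all(c("parameter", "low", "high") %in% names(bounds)))
  base <- vapply(bounds$parameter, function(nm) get_param(config, nm), numeric(1))
  if (any(bounds$low > base | base > bounds$high)) {
    bad <- bounds$parameter[bounds$low > base | base > bounds$high]
    stop("bounds must bracket the base value: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  icer_at <- function(nm, value) {
    res <- tryCatch(
      run_model(set_param(config, nm, value)),
      error = function(e) {
        warning("DSA bound for '", nm, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) return(NA_real_)
    r <- res$incremental$icer_per_qaly
    if (is.character(r)) {
      # dominance at a bound: sign the span by the cost increment direction
      if (identical(r, "dominant")) -Inf else Inf
    } else r
  }
  lo <- mapply(icer_at, bounds$parameter, bounds$low)
  hi <- mapply(icer_at, bounds$parameter, bounds$high)
  out <- data.frame(parameter = bounds$parameter,
                    low = bounds$low, high = bounds$high,
                    icer_at_low = lo, icer_at_high = hi,
                    span = abs(hi - lo))
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the full input uncertainty: each iteration
#' samples every parameter from its configured distribution (beta for
#' probabilities and utilities — decrements are sampled on their magnitude —
#' gamma for costs), runs both arms through the cohort engine with the
#' sampled inputs, and records the incremental cost and QALYs. A sampled
#' parameter set whose monthly probabilities sum past 1 in either arm is
#' resampled (not clipped), with the count reported. The probability of
#' cost-effectiveness at threshold `lambda` is the exact empirical fraction
#' of iterations with positive net monetary benefit.
#'
#' With the default `sampling = "paired"`, the two arms' versions of the
#' same transition probability (acute event, CV death, non-CV death) are
#' sampled at a common quantile of their respective distributions, so both
#' arms move up or down together while each arm's marginal distribution is
#' exactly the configured one. This models the dominant uncertainty as the
#' shared baseline risk, holding the relative treatment effect near its
#' estimate — the reading consistent with trial-derived inputs, where the
#' two arms' event probabilities come from one randomized comparison and
#' the published uncertainty of each arm is not evidence that the effect
#' direction itself is undetermined. `sampling = "independent"` draws every
#' parameter independently instead; because it lets the two arms' mortality
#' draws cross, it attributes far more probability to a reversed treatment
#' effect than the source trial supports, and correspondingly deflates the
#' probability of cost-effectiveness. Parameters not paired across arms
#' (costs, utilities, the drug cost) are always drawn independently of one
#' another.
#'
#' @param config A validated model configuration.
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed; identical seed and config give identical draws.
#' @param wtp Numeric vector of willingness-to-pay thresholds (US$/QALY) at
#'   which to report the probability of cost-effectiveness; defaults to the
#'   config's tiers.
#' @param sampling `"paired"` (default) or `"independent"`; see Details.
#' @return An object of class `psa_result`: `draws` (data frame with
#'   `delta_cost`, `delta_qaly` per iteration), `ce_probability` (named by
#'   threshold), `resampled` (count of rejected parameter sets), `iterations`,
#'   `seed`, and the base-case `incremental` result.
#' @export
run_psa <- function(config, iterations = 10000, seed = 1L, wtp = NULL,
                    sampling = c("paired", "independent")) {
  validate_config(config)
  sampling <- match.arg(sampling)
  stopifnot(iterations >= 1)
  wtp <- wtp %||% as.numeric(unlist(config$wtp))
  specs <- config$distributions
  settings <- do.call(sim_settings, config$settings[
    c("horizon_cycles", "annual_discount", "start_age", "cohort_size")])

  # transition parameters present in both arms share a quantile draw under
  # paired sampling
  arms <- c(config$comparator, config$intervention)
  paired_fields <- if (sampling == "paired") {
    Filter(function(fld) {
      all(paste0(arms, ".", fld) %in% names(specs))
    }, c("p_hhf", "p_cv_death", "p_noncv_death"))
  } else character(0)
  paired_names <- as.vector(outer(arms, paired_fields, paste, sep = "."))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  delta_cost <- delta_qaly <- numeric(iterations)
  resampled <- 0L
  for (i in seq_len(iterations)) {
    repeat {
      draw <- lapply(specs[setdiff(names(specs), paired_names)],
                     sample_spec, n = 1)
      for (fld in paired_fields) {
        u <- stats::runif(1)
        for (a in arms) {
          nm <- paste0(a, ".", fld)
          draw[[nm]] <- quantile_spec(specs[[nm]], u)
        }
      }
      cfg <- config
      for (nm in names(draw)) {
        value <- draw[[nm]]
        cfg <- switch(nm,
                      utility_stable = set_param(cfg, nm, min(value, 1)),
                      set_param(cfg, nm, value))
      }
      ok <- all(vapply(arms, function(a) {
        tr <- cfg$arms[[a]]$transitions
        tr$p_hhf + tr$p_cv_death + tr$p_noncv_death <= 1
      }, logical(1)))
      if (ok) break
      resampled <- resampled + 1L
    }
    outs <- lapply(arms, function(a) {
      aa <- cfg$arms[[a]]
      run_arm(aa$transitions, c(list(drug_monthly = aa$drug_monthly), cfg$costs),
              cfg$utilities, settings, arm = a)
    })
    delta_cost[i] <- outs[[2]]$cost_discounted - outs[[1]]$cost_discounted
    delta_qaly[i] <- outs[[2]]$qaly_discounted - outs[[1]]$qaly_discounted
  }
  draws <- data.frame(delta_cost = delta_cost, delta_qaly = delta_qaly)
  ce <- vapply(wtp, function(l) mean(l * delta_qaly - delta_cost > 0), numeric(1))
  names(ce) <- format(wtp, scientific = FALSE, trim = TRUE)
  structure(
    list(draws = draws,
         ce_probability = ce,
         wtp = wtp,
         resampled = resampled,
         iterations = as.integer(iterations),
         seed = as.integer(seed),
         sampling = sampling,
         incremental = run_model(config)$incremental),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the fraction of PSA draws
#' with positive net monetary benefit `lambda * dQALY - dCost`.
#'
#' @param psa A `psa_result` from [run_psa()], or a data frame of draws with
#'   `delta_cost` and `delta_qaly` columns.
#' @param wtp_grid Non-empty numeric vector of thresholds (US$/QALY).
#' @return Data frame with `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  stopifnot(is.data.frame(draws), nrow(draws) >= 1)
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  data.frame(
    wtp = wtp_grid,
    probability = vapply(
      wtp_grid,
      function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0),
      numeric(1))
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d iterations, seed %d, %d resampled>\n",
              x$iterations, x$seed, x$resampled))
  for (i in seq_along(x$ce_probability)) {
    cat(sprintf("  P(cost-effective | WTP %s US$/QALY) = %.3f\n",
                names(x$ce_probability)[i], x$ce_probability[i]))
  }
  invisible(x)
}
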