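#' Simulation settings for the cohort model
#'
#' Bundles the run-level settings of the monthly-cycle Markov model. Defaults
#' are the base case: a cohort of 1000 patients entering at age 66, simulated
#' over 180 monthly cycles (15 years) with a 3% annual discount rate applied
#' to costs and QALYs.
#'
#' @param horizon_cycles Number of monthly cycles to simulate (>= 1).
#' @param annual_discount Annual discount rate as a fraction (>= 0); applied
#'   per cycle as `(1 + annual_discount)^(-cycle / 12)`.
#' @param start_age Age in years at model entry (used for the aging utility
#'   decrement).
#' @param cohort_size Number of persons the occupancy fractions are scaled by
#'   when reporting expected event counts.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(horizon_cycles = 180, annual_discount = 0.03,
                         start_age = 66, cohort_size = 1000) {
  stopifnot(horizon_cycles >= 1, annual_discount >= 0, cohort_size > 0)
  structure(
    list(horizon_cycles = as.integer(horizon_cycles),
         annual_discount = annual_discount,
         start_age = start_age,
         cohort_size = cohort_size),
    class = "sim_settings"
  )
}

# Canonical state space: one entry state, one acute-event tunnel, two
# absorbing death states. Order is fixed so serialized traces are stable.
hf_state_names <- c("StableHF", "AcuteHFEvent", "CVDeath", "NonCVDeath")

#' Build the monthly transition matrix for one treatment arm
#'
#' Constructs the row-stochastic matrix over the four canonical health states:
#' stable HF (entry state), acute HF event (emergency visit or hospitalization
#' for HF, a one-cycle tunnel that returns to stable HF), cardiovascular
#' death, and non-cardiovascular death (both absorbing). The stable and
#' acute-event rows carry the same per-cycle probabilities — the model applies
#' one set of transition probabilities per arm — with the remainder returning
#' to stable HF. A repeat acute event (acute -> acute) counts as a new event.
#'
#' @param transitions A list (or named numeric vector) with elements `p_hhf`,
#'   `p_cv_death`, `p_noncv_death`: monthly probabilities of an acute HF
#'   event, cardiovascular death and non-cardiovascular death.
#' @param arm Optional arm label used in validation error messages.
#' @return A 4x4 row-stochastic matrix of class `hf_transition_matrix` with
#'   state roles (`stable`, `event`, `death_cv`, `death_noncv`) attached.
#' @examples
#' build_transition_matrix(list(p_hhf = 0.007881397,
#'                              p_cv_death = 0.006698743,
#'                              p_noncv_death = 0.001312441))
#' @export
build_transition_matrix <- function(transitions, arm = "arm") {
  p <- as.list(transitions)
  need <- c("p_hhf", "p_cv_death", "p_noncv_death")
  if (!all(need %in% names(p))) {
    stop("transitions must supply ", paste(need, collapse = ", "), call. = FALSE)
  }
  p_hhf <- p$p_hhf; p_cv <- p$p_cv_death; p_ncv <- p$p_noncv_death
  check_prob(c(p_hhf, p_cv, p_ncv), what = paste0("transition probability (", arm, ")"))
  total <- p_hhf + p_cv + p_ncv
  if (total > 1) {
    stop("monthly transition probabilities for '", arm,
         "' sum to ", format(total), " > 1", call. = FALSE)
  }
  alive_row <- c(1 - total, p_hhf, p_cv, p_ncv)
  P <- rbind(alive_row, alive_row, c(0, 0, 1, 0), c(0, 0, 0, 1))
  dimnames(P) <- list(hf_state_names, hf_state_names)
  structure(P,
            class = c("hf_transition_matrix", "matrix", "array"),
            roles = c(StableHF = "stable", AcuteHFEvent = "event",
                      CVDeath = "death_cv", NonCVDeath = "death_noncv"),
            arm = arm)
}

state_roles <- function(P) {
  roles <- attr(P, "roles")
  if (is.null(roles)) {
    # generic matrix support: infer death states from absorbing rows,
    # require names to locate the event state
    states <- rownames(P)
    if (is.null(states)) stop("transition matrix must have named states", call. = FALSE)
    roles <- rep("stable", length(states))
    names(roles) <- states
    absorbing <- vapply(seq_along(states), function(i) P[i, i] == 1, logical(1))
    roles[absorbing] <- "death_noncv"
    roles[states == "CVDeath"] <- "death_cv"
    roles[states == "AcuteHFEvent"] <- "event"
  }
  roles
}

validate_stochastic <- function(P, tol = 1e-10) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(P < -tol) || any(P > 1 + tol) ||
      any(abs(rowSums(P) - 1) > tol)) {
    stop("transition matrix is not row-stochastic", call. = FALSE)
  }
  invisible(P)
}

#' Run the deterministic cohort simulation
#'
#' Propagates the cohort occupancy distribution through `settings$horizon_cycles`
#' monthly cycles. The whole cohort starts in the entry (stable) state unless
#' `start` is given. Per-cycle inflows to the acute-event state (including
#' repeat events) and to each death state are recorded alongside occupancy.
#'
#' @param P Transition matrix from [build_transition_matrix()] (or any named
#'   row-stochastic matrix with absorbing death states).
#' @param settings A [sim_settings()] object.
#' @param start Optional starting occupancy vector (must sum to 1); defaults
#'   to all mass in the first (stable) state.
#' @return A `cohort_trace`: list with `occupancy` (a `(horizon+1) x states`
#'   matrix of fractions, row 0 = start), `hhf_flow` (per-cycle fraction
#'   entering the acute-event state), `death_flow` (per-cycle inflow to each
#'   death state), and `cumulative_mortality`.
#' @export
run_cohort <- function(P, settings = sim_settings(), start = NULL) {
  validate_stochastic(P)
  roles <- state_roles(P)
  S <- nrow(P)
  H <- settings$horizon_cycles
  if (is.null(start)) {
    start <- c(1, rep(0, S - 1))
  }
  stopifnot(length(start) == S, abs(sum(start) - 1) < 1e-10)

  event_idx <- which(roles == "event")
  death_idx <- which(roles %in% c("death_cv", "death_noncv"))

  occ <- matrix(0, H + 1, S, dimnames = list(0:H, rownames(P)))
  occ[1, ] <- start
  hhf_flow <- numeric(H)
  death_flow <- matrix(0, H, length(death_idx),
                       dimnames = list(1:H, rownames(P)[death_idx]))
  cur <- start
  for (t in seq_len(H)) {
    nxt <- as.vector(cur %*% P)
    # inflow to the acute-event state, counting repeat events (self-loop)
    hhf_flow[t] <- sum(cur * P[, event_idx])
    # inflow to each death state, excluding the absorbing self-loop
    for (k in seq_along(death_idx)) {
      j <- death_idx[k]
      death_flow[t, k] <- sum(cur[-j] * P[-j, j])
    }
    occ[t + 1, ] <- nxt
    cur <- nxt
  }
  structure(
    list(occupancy = occ,
         hhf_flow = hhf_flow,
         death_flow = death_flow,
         cumulative_mortality = sum(cur[death_idx]),
         states = rownames(P),
         roles = roles,
         settings = settings),
    class = "cohort_trace"
  )
}

#' Individual-level microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` independent patients through the same transition
#' matrix with per-cycle Bernoulli/categorical draws and aggregates them into
#' a trace. By the law of large numbers this converges on [run_cohort()];
#' it serves as an independent stochastic check of the deterministic engine.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated patients (>= 1).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A `cohort_trace` (occupancy as empirical fractions) with an extra
#'   element `n_individuals`.
#' @export
microsimulate_cohort <- function(P, settings = sim_settings(),
                                 n_individuals = 1e5, seed = 1L) {
  validate_stochastic(P)
  stopifnot(n_individuals >= 1)
  roles <- state_roles(P)
  S <- nrow(P)
  H <- settings$horizon_cycles
  event_idx <- which(roles == "event")
  death_idx <- which(roles %in% c("death_cv", "death_noncv"))
  cum <- t(apply(P, 1, cumsum))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  state <- rep.int(1L, n_individuals)
  occ <- matrix(0, H + 1, S, dimnames = list(0:H, rownames(P)))
  occ[1, 1] <- 1
  hhf_flow <- numeric(H)
  death_flow <- matrix(0, H, length(death_idx),
                       dimnames = list(1:H, rownames(P)[death_idx]))
  for (t in seq_len(H)) {
    alive <- which(!(state %in% death_idx))
    if (length(alive)) {
      u <- stats::runif(length(alive))
      # categorical draw per individual from its current row
      nxt <- state[alive]
      for (s in unique(state[alive])) {
        in_s <- alive[state[alive] == s]
        nxt[state[alive] == s] <- findInterval(u[state[alive] == s],
                                               cum[s, ], left.open = TRUE) + 1L
      }
      hhf_flow[t] <- sum(nxt == event_idx) / n_individuals
      for (k in seq_along(death_idx)) {
        death_flow[t, k] <- sum(nxt == death_idx[k] &
                                  state[alive] != death_idx[k]) / n_individuals
      }
      state[alive] <- nxt
    }
    occ[t + 1, ] <- tabulate(state, nbins = S) / n_individuals
  }
  structure(
    list(occupancy = occ,
         hhf_flow = hhf_flow,
         death_flow = death_flow,
         cumulative_mortality = sum(occ[H + 1, death_idx]),
         states = rownames(P),
         roles = roles,
         settings = settings,
         n_individuals = n_individuals),
    class = "cohort_trace"
  )
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
# stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Accumulate costs, QALYs and life-years over a cohort trace
#'
#' Applies the costing and utility rules cycle by cycle: every alive cycle
#' accrues the stable-state monthly cost plus the arm's drug cost; cycles
#' spent in the acute-event state additionally accrue the event-month cost;
#' the cycle of a death transition accrues the cause-specific cost of the
#' month before death, once. Utility in an alive cycle is the stable-HF
#' utility minus the aging decrement (linear in years since model entry),
#' minus the acute-event decrement in event cycles; each cycle contributes
#' utility/12 QALYs and 1/12 life-years. Costs and QALYs are discounted per
#' cycle at `(1 + annual_discount)^(-cycle/12)`; life-years are reported both
#' discounted and undiscounted.
#'
#' @param trace A `cohort_trace` from [run_cohort()] or
#'   [microsimulate_cohort()].
#' @param costs List with `drug_monthly`, `stable_monthly`, `event_month`,
#'   `death_month_cv`, `death_month_noncv` (US$, all >= 0).
#' @param utilities List with `stable_hf` (utility in `[0,1]`),
#'   `aging_decrement_per_year` and `hhf_decrement` (decrement magnitudes,
#'   >= 0).
#' @param settings Optional [sim_settings()]; defaults to the settings stored
#'   in the trace.
#' @return An `arm_outcome`: discounted and undiscounted cost, QALY and
#'   life-year totals (per person), expected acute-event count scaled to
#'   `cohort_size`, and cumulative mortality.
#' @export
accumulate_outcomes <- function(trace, costs, utilities, settings = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  settings <- settings %||% trace$settings
  H <- settings$horizon_cycles
  if (nrow(trace$occupancy) != H + 1) {
    stop("trace length does not match settings$horizon_cycles", call. = FALSE)
  }
  costs <- validate_costs(costs)
  utilities <- validate_utilities(utilities)

  roles <- trace$roles
  occ <- trace$occupancy[-1, , drop = FALSE]       # occupancy during cycles 1..H
  stable_occ <- rowSums(occ[, roles == "stable", drop = FALSE])
  event_occ  <- rowSums(occ[, roles == "event", drop = FALSE])
  alive <- stable_occ + event_occ
  cv_col  <- which(roles[colnames(trace$death_flow)] == "death_cv")
  ncv_col <- which(roles[colnames(trace$death_flow)] == "death_noncv")
  cv_flow  <- rowSums(trace$death_flow[, cv_col, drop = FALSE])
  ncv_flow <- rowSums(trace$death_flow[, ncv_col, drop = FALSE])

  t <- seq_len(H)
  disc <- (1 + settings$annual_discount)^(-t / 12)
  years_elapsed <- (t - 1) / 12

  cost_cycle <- alive * (costs$stable_monthly + costs$drug_monthly) +
    event_occ * costs$event_month +
    cv_flow * costs$death_month_cv +
    ncv_flow * costs$death_month_noncv

  u_stable <- utilities$stable_hf -
    utilities$aging_decrement_per_year * years_elapsed
  u_event <- u_stable - utilities$hhf_decrement
  if (any(u_stable < 0) || any(u_event[event_occ > 0] < 0)) {
    warning("utility fell below 0 after decrements; floored at 0")
  }
  u_stable <- pmax(u_stable, 0)
  u_event <- pmax(u_event, 0)
  qaly_cycle <- (stable_occ * u_stable + event_occ * u_event) / 12

  structure(
    list(cost_discounted = sum(cost_cycle * disc),
         cost_undiscounted = sum(cost_cycle),
         qaly_discounted = sum(qaly_cycle * disc),
         qaly_undiscounted = sum(qaly_cycle),
         ly_discounted = sum(alive / 12 * disc),
         ly_undiscounted = sum(alive / 12),
         hhf_events_expected = settings$cohort_size * sum(trace$hhf_flow),
         cumulative_mortality = trace$cumulative_mortality,
         settings = settings),
    class = "arm_outcome"
  )
}

#' Run one treatment arm end to end
#'
#' Convenience wrapper: builds the transition matrix, runs the cohort trace
#' and accumulates outcomes.
#'
#' @inheritParams build_transition_matrix
#' @inheritParams accumulate_outcomes
#' @param settings A [sim_settings()] object.
#' @return An `arm_outcome` (see [accumulate_outcomes()]).
#' @export
run_arm <- function(transitions, costs, utilities, settings = sim_settings(),
                    arm = "arm") {
  P <- build_transition_matrix(transitions, arm = arm)
  trace <- run_cohort(P, settings)
  out <- accumulate_outcomes(trace, costs, utilities, settings)
  out$arm <- arm
  out
}

validate_costs <- function(costs) {
  need <- c("drug_monthly", "stable_monthly", "event_month",
            "death_month_cv", "death_month_noncv")
  costs <- as.list(costs)
  missing <- setdiff(need, names(costs))
  if (length(missing)) {
    stop("cost inputs missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(costs[need])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("cost inputs must be finite and >= 0", call. = FALSE)
  }
  costs
}

validate_utilities <- function(utilities) {
  need <- c("stable_hf", "aging_decrement_per_year", "hhf_decrement")
  utilities <- as.list(utilities)
  missing <- setdiff(need, names(utilities))
  if (length(missing)) {
    stop("utility inputs missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (utilities$stable_hf < 0 || utilities$stable_hf > 1) {
    stop("stable_hf utility must lie in [0, 1]", call. = FALSE)
  }
  if (utilities$aging_decrement_per_year < 0 || utilities$hhf_decrement < 0) {
    stop("utility decrements are stored as magnitudes (>= 0)", call. = FALSE)
  }
  utilities
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome%s>\n",
              if (!is.null(x$arm)) paste0(": ", x$arm) else ""))
  cat(sprintf("  cost  (disc.)  %12.2f US$\n", x$cost_discounted))
  cat(sprintf("  QALY  (disc.)  %12.4f\n", x$qaly_discounted))
  cat(sprintf("  LY  (undisc.)  %12.4f\n", x$ly_undiscounted))
  cat(sprintf("  expected HHF   %12.1f events (cohort %d)\n",
              x$hhf_events_expected, x$settings$cohort_size))
  cat(sprintf("  mortality      %12.1f %%\n", 100 * x$cumulative_mortality))
  invisible(x)
}

#' Export a cohort trace as a tidy per-cycle data frame
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A data frame with one row per cycle x state: `cycle`, `state`,
#'   `occupancy`, plus per-cycle `hhf_flow` and death inflows repeated on the
#'   matching state rows.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  H <- nrow(occ) - 1
  out <- data.frame(
    cycle = rep(0:H, times = ncol(occ)),
    state = rep(colnames(occ), each = H + 1),
    occupancy = as.vector(occ),
    flow = 0
  )
  roles <- x$roles
  for (st in colnames(occ)) {
    fl <- if (!is.null(roles) && roles[[st]] == "event") {
      c(0, x$hhf_flow)
    } else if (st %in% colnames(x$death_flow)) {
      c(0, x$death_flow[, st])
    } else NULL
    if (!is.null(fl)) out$flow[out$state == st] <- fl
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
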