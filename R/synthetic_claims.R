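#' Generative parameters for synthetic longitudinal claims
#'
#' Defines the ground truth for the synthetic claims generator. Patients
#' index on a random day in the first half of `index_year` with an
#' ambulatory HF diagnosis and are followed in 30-day months until death or
#' `censor_date`. Each stable month emits one ambulatory claim whose cost is
#' gamma-distributed; from the second month on, a single categorical draw
#' per month competes an acute HF event against cardiovascular and
#' non-cardiovascular death (mirroring the transition row of the cohort
#' model). An acute event opens an inpatient episode (event-month cost),
#' followed by state-months at their own cost level until death or censoring.
#' The 30 days before death form a death month carrying only the
#' cause-specific death-month claim.
#'
#' Defaults mirror the published base-case inputs: monthly acute-event
#' hazard 0.0078814, CV death 0.0066987, non-CV death 0.0013124, stable cost
#' 450 +/- 225, event-month cost 2887 +/- 1443.5, death-month costs
#' 3430 +/- 1715 (CV) and 3390 +/- 1695 (non-CV), all 2020 US$. The
#' state-month cost (never printed in the base-case inputs; the cohort
#' model's one-cycle tunnel does not use it) defaults to 700 +/- 350, a
#' modest post-discharge elevation over the stable level.
#'
#' A small fraction of patients is generated to fail each cohort filter:
#' `lookback_admission_frac` get an HF admission during the 180-day lookback
#' and `sparse_dx_frac` carry no second ambulatory HF diagnosis within 180
#' days of the first.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed (mandatory; generation is deterministic given it).
#' @param index_year Calendar year of cohort entry.
#' @param censor_date Administrative end of observation (`Date` or string).
#' @param p_hhf,p_cv_death,p_noncv_death Monthly hazards, each in `[0, 1]`.
#' @param stable_cost,event_cost,state_cost,death_cost_cv,death_cost_noncv
#'   Length-2 numeric vectors `c(mean, sd)` of the monthly cost
#'   distributions.
#' @param hf_dx_rate Probability that a follow-up ambulatory claim carries
#'   the HF diagnosis flag.
#' @param lookback_admission_frac,sparse_dx_frac Fractions of patients
#'   constructed to fail the lookback / two-diagnoses cohort filters.
#' @return A `claims_gen_params` list.
#' @export
claims_gen_params <- function(n_patients = 2000, seed = 1L,
                              index_year = 2015,
                              censor_date = "2018-12-31",
                              p_hhf = 0.007881397,
                              p_cv_death = 0.006698743,
                              p_noncv_death = 0.001312441,
                              stable_cost = c(450, 225),
                              event_cost = c(2887, 1443.5),
                              state_cost = c(700, 350),
                              death_cost_cv = c(3430, 1715),
                              death_cost_noncv = c(3390, 1695),
                              hf_dx_rate = 0.7,
                              lookback_admission_frac = 0.05,
                              sparse_dx_frac = 0.05) {
  params <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 index_year = as.integer(index_year),
                 censor_date = as.Date(censor_date),
                 p_hhf = p_hhf, p_cv_death = p_cv_death,
                 p_noncv_death = p_noncv_death,
                 stable_cost = stable_cost, event_cost = event_cost,
                 state_cost = state_cost, death_cost_cv = death_cost_cv,
                 death_cost_noncv = death_cost_noncv,
                 hf_dx_rate = hf_dx_rate,
                 lookback_admission_frac = lookback_admission_frac,
                 sparse_dx_frac = sparse_dx_frac)
  rates <- c(params$p_hhf, params$p_cv_death, params$p_noncv_death,
             params$hf_dx_rate, params$lookback_admission_frac,
             params$sparse_dx_frac)
  if (any(rates < 0) || any(rates > 1) || sum(rates[1:3]) > 1) {
    stop("hazards and rates must lie in [0, 1] with hazards summing to <= 1",
         call. = FALSE)
  }
  for (nm in c("stable_cost", "event_cost", "state_cost",
               "death_cost_cv", "death_cost_noncv")) {
    v <- params[[nm]]
    if (length(v) != 2 || v[1] < 0 || v[2] < 0) {
      stop(nm, " must be c(mean, sd) with both >= 0", call. = FALSE)
    }
  }
  if (params$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  class(params) <- "claims_gen_params"
  params
}

# Gamma draw matched to (mean, sd); sd = 0 gives the constant mean.
rgamma_ms <- function(n, ms) {
  if (ms[2] == 0) return(rep(ms[1], n))
  if (ms[1] == 0) return(rep(0, n))
  g <- gamma_from_moments(ms[1], ms[2])
  stats::rgamma(n, shape = g$shape, rate = g$rate)
}

#' Generate synthetic longitudinal claims with known ground truth
#'
#' Produces a claims table in the schema the costing procedure reads —
#' `patient_id`, `date`, `setting` (`ambulatory` / `emergency` /
#' `inpatient`), `hf_dx` (logical), `cost`, `death_date`, `death_cause`
#' (`cv` / `noncv`, on the patient's terminal record) — together with the
#' generative parameter ledger, so every cost and hazard estimator can be
#' validated against its true value. Identical parameters (including the
#' seed) give byte-identical output.
#'
#' Partial final months at the administrative censor date carry a cost
#' prorated by the observed fraction of the month, so per-month cost means
#' are unbiased under fractional follow-up.
#'
#' @param params A [claims_gen_params()] object.
#' @return List with `claims` (data frame, sorted by patient and date) and
#'   `truth` (the input `params`).
#' @export
generate_claims <- function(params) {
  stopifnot(inherits(params, "claims_gen_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  year_start <- as.Date(sprintf("%d-01-01", params$index_year))
  n <- params$n_patients
  index_dates <- year_start + sample.int(181L, n, replace = TRUE) - 1L
  lookback_flag <- stats::runif(n) < params$lookback_admission_frac
  sparse_flag <- stats::runif(n) < params$sparse_dx_frac

  per_patient <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- index_dates[i]
    censor_days <- as.numeric(params$censor_date - idx)  # last observable day offset
    rows <- list()
    add <- function(date, setting, hf, cost) {
      rows[[length(rows) + 1L]] <<- list(date = date, setting = setting,
                                         hf_dx = hf, cost = cost)
    }
    if (lookback_flag[i]) {
      add(idx - sample(30:170, 1L), "inpatient", TRUE,
          rgamma_ms(1, params$event_cost))
    }
    phase <- "stable"
    death_cause <- NA_character_
    death_date <- as.Date(NA)
    m <- 0L
    repeat {
      s <- 30 * m
      if (s > censor_days) break
      e <- min(30 * (m + 1), censor_days + 1)
      full <- (e - s) == 30
      frac <- (e - s) / 30
      # competing transition draw at the start of every full month after the
      # first; a partial trailing month is observed stable time only
      transition <- "none"
      if (m >= 1L && full) {
        u <- stats::runif(1)
        transition <- if (phase == "stable" && u < params$p_hhf) "event"
          else if (u < params$p_hhf * (phase == "stable") + params$p_cv_death) "cv"
          else if (u < params$p_hhf * (phase == "stable") + params$p_cv_death +
                     params$p_noncv_death) "noncv"
          else "none"
      }
      if (transition %in% c("cv", "noncv")) {
        death_cause <- transition
        death_date <- idx + e - 1
        ms <- if (transition == "cv") params$death_cost_cv else params$death_cost_noncv
        add(idx + s + 14, "inpatient", FALSE, rgamma_ms(1, ms))
        break
      }
      if (transition == "event") {
        phase <- "post_event"
        add(idx + s, "inpatient", TRUE, rgamma_ms(1, params$event_cost))
      } else {
        hf <- if (m == 0L) TRUE
          else if (phase == "stable" && sparse_flag[i] && m <= 6L) FALSE
          else stats::runif(1) < params$hf_dx_rate
        ms <- if (phase == "stable") params$stable_cost else params$state_cost
        # the index diagnosis (month 0) anchors follow-up, so it sits exactly
        # at the index date; later visits fall a few days into their month
        offset <- if (m == 0L) 0 else min(5, e - s - 1)
        add(idx + s + offset, "ambulatory", hf, frac * rgamma_ms(1, ms))
      }
      m <- m + 1L
    }
    df <- do.call(rbind, lapply(rows, as.data.frame))
    df$patient_id <- i
    df$death_date <- as.Date(NA)
    df$death_cause <- NA_character_
    if (!is.na(death_cause)) {
      df$death_date[nrow(df)] <- death_date
      df$death_cause[nrow(df)] <- death_cause
    }
    per_patient[[i]] <- df
  }
  claims <- do.call(rbind, per_patient)
  claims <- claims[order(claims$patient_id, claims$date),
                   c("patient_id", "date", "setting", "hf_dx", "cost",
                     "death_date", "death_cause")]
  rownames(claims) <- NULL
  list(claims = claims, truth = params)
}

#' Write / read a claims table as CSV
#'
#' Plain-text serialization of the claims schema with ISO dates.
#'
#' @param claims Claims data frame (see [generate_claims()]).
#' @param path File path.
#' @return `read_claims()` returns the claims data frame with typed columns.
#' @export
write_claims <- function(claims, path) {
  utils::write.csv(claims, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  claims <- utils::read.csv(path, stringsAsFactors = FALSE)
  claims$date <- as.Date(claims$date)
  claims$death_date <- as.Date(claims$death_date)
  claims$hf_dx <- as.logical(claims$hf_dx)
  claims$death_cause <- as.character(claims$death_cause)
  claims$setting <- as.character(claims$setting)
  claims
}
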