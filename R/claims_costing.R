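#' Identify the stable-HF cohort from longitudinal claims
#'
#' Applies the cohort-identification filters: a patient enters the stable-HF
#' cohort if they have at least two ambulatory claims flagged with an HF
#' diagnosis within 180 days of each other inside the index year, and no HF
#' emergency visit or inpatient admission in the 180 days preceding their
#' first index-year ambulatory HF diagnosis. Per-filter attrition counts are
#' returned alongside the cohort.
#'
#' @param claims Claims data frame (schema of [generate_claims()]), sorted
#'   or not; sorting is enforced internally.
#' @param index_year Calendar year defining cohort entry.
#' @return List with `cohort` (data frame `patient_id`, `index_date` = first
#'   qualifying ambulatory HF diagnosis) and `attrition` (data frame `step`,
#'   `n` with non-increasing counts).
#' @export
identify_stable_cohort <- function(claims, index_year) {
  if (nrow(claims) == 0) {
    return(list(
      cohort = data.frame(patient_id = integer(0), index_date = as.Date(character(0))),
      attrition = data.frame(
        step = c("patients", "ge2_ambulatory_hf_dx_within_180d", "clean_180d_lookback"),
        n = c(0L, 0L, 0L))))
  }
  claims <- claims[order(claims$patient_id, claims$date), ]
  yr <- as.integer(format(claims$date, "%Y"))
  amb_hf <- claims$setting == "ambulatory" & claims$hf_dx & yr == index_year
  acute_hf <- claims$setting %in% c("emergency", "inpatient") & claims$hf_dx

  ids <- unique(claims$patient_id)
  n_input <- length(ids)
  amb_dates <- split(claims$date[amb_hf], claims$patient_id[amb_hf])
  acute_dates <- split(claims$date[acute_hf], claims$patient_id[acute_hf])

  # filter 1: >= 2 ambulatory HF diagnoses within 180 days in the index year
  keep1 <- vapply(as.character(ids), function(pid) {
    d <- amb_dates[[pid]]
    !is.null(d) && length(d) >= 2 && min(diff(sort(d))) <= 180
  }, logical(1))
  ids1 <- ids[keep1]
  idx1 <- as.Date(vapply(as.character(ids1),
                         function(pid) as.numeric(min(amb_dates[[pid]])),
                         numeric(1)),
                  origin = "1970-01-01")

  # filter 2: no HF admission/emergency visit in the 180 days before the
  # first index-year HF diagnosis
  keep2 <- vapply(seq_along(ids1), function(k) {
    d <- acute_dates[[as.character(ids1[k])]]
    is.null(d) || !any(d >= idx1[k] - 180 & d < idx1[k])
  }, logical(1))

  cohort <- data.frame(patient_id = ids1[keep2], index_date = idx1[keep2])
  attrition <- data.frame(
    step = c("patients", "ge2_ambulatory_hf_dx_within_180d", "clean_180d_lookback"),
    n = c(n_input, length(ids1), nrow(cohort)))
  list(cohort = cohort, attrition = attrition)
}

# Claims pre-split by patient id for O(1) per-patient lookup.
split_claims <- function(claims) {
  split(claims, claims$patient_id)
}

# Per-patient follow-up end for the stable period: first acute HF event,
# start of the 30-day death month, or the day after the administrative
# censor date, whichever comes first.
stable_followup_end <- function(sub, index_date, censor_date) {
  sub <- sub[sub$date >= index_date, ]
  acute <- sub$date[sub$setting %in% c("emergency", "inpatient") & sub$hf_dx]
  death <- sub$death_date[!is.na(sub$death_date)]
  ends <- as.Date(censor_date) + 1
  if (length(acute)) ends <- min(ends, min(acute))
  if (length(death)) ends <- min(ends, death[1] - 29)
  ends
}

#' Mean monthly cost of stable HF care
#'
#' For each cohort patient, sums all medical costs from the index diagnosis
#' until the first acute HF event, the month before death, or the
#' administrative end of observation — whichever comes first — and divides
#' by the follow-up duration in 30-day months. Returns the cohort mean (and
#' SD) of these per-patient monthly costs. Patients with zero follow-up are
#' skipped and counted.
#'
#' @param claims Claims data frame.
#' @param cohort Cohort data frame from [identify_stable_cohort()].
#' @param censor_date Administrative end of observation.
#' @return List with `mean`, `sd`, `n`, `total_months`, `skipped_zero_followup`.
#' @export
stable_monthly_cost <- function(claims, cohort, censor_date) {
  censor_date <- as.Date(censor_date)
  cl <- split_claims(claims)
  per <- vapply(seq_len(nrow(cohort)), function(k) {
    sub <- cl[[as.character(cohort$patient_id[k])]]
    idx <- cohort$index_date[k]
    fu_end <- stable_followup_end(sub, idx, censor_date)
    months <- as.numeric(fu_end - idx) / 30
    if (months <= 0) return(c(NA_real_, 0))
    keep <- sub$date >= idx & sub$date < fu_end
    c(sum(sub$cost[keep]) / months, months)
  }, numeric(2))
  monthly <- per[1, ]
  skipped <- sum(is.na(monthly))
  monthly <- monthly[!is.na(monthly)]
  if (skipped > 0) {
    message(skipped, " patient(s) with zero stable follow-up skipped")
  }
  list(mean = if (length(monthly)) mean(monthly) else NA_real_,
       sd = if (length(monthly) > 1) stats::sd(monthly) else NA_real_,
       n = length(monthly),
       total_months = sum(per[2, ]),
       skipped_zero_followup = skipped)
}

#' Event-month and state-month costs of acute HF episodes
#'
#' Identifies each cohort patient's first acute HF episode (first emergency
#' or inpatient claim with an HF diagnosis on or after the index date). The
#' first 30 days from the episode start form the event month; subsequent
#' complete 30-day windows, up to the month before death or the censor date,
#' form the state months. Costs falling in each window are summed; the
#' function returns the pooled mean over event months (one per patient with
#' an event) and over all state months. Additional acute HF claims inside
#' the event month are merged into the episode with a warning.
#'
#' @inheritParams stable_monthly_cost
#' @return List with `event_month_mean`, `state_month_mean`, `n_events`,
#'   `n_state_months`. Means are `NA` (flagged by `n_* = 0`) when no
#'   episodes or no complete state months exist.
#' @export
event_and_state_costs <- function(claims, cohort, censor_date) {
  censor_date <- as.Date(censor_date)
  event_pool <- numeric(0)
  state_pool <- numeric(0)
  overlaps <- 0L
  cl <- split_claims(claims)
  for (k in seq_len(nrow(cohort))) {
    sub <- cl[[as.character(cohort$patient_id[k])]]
    idx <- cohort$index_date[k]
    sub <- sub[sub$date >= idx, ]
    acute <- sort(sub$date[sub$setting %in% c("emergency", "inpatient") & sub$hf_dx])
    if (!length(acute)) next
    e0 <- acute[1]
    if (any(acute > e0 & acute < e0 + 30)) overlaps <- overlaps + 1L
    death <- sub$death_date[!is.na(sub$death_date)]
    windows_end <- min(as.Date(censor_date) + 1,
                       if (length(death)) death[1] - 29 else as.Date(censor_date) + 1)
    event_pool <- c(event_pool,
                    sum(sub$cost[sub$date >= e0 & sub$date < e0 + 30]))
    k2 <- 1L
    while (e0 + 30 * (k2 + 1) <= windows_end) {
      lo <- e0 + 30 * k2
      state_pool <- c(state_pool,
                      sum(sub$cost[sub$date >= lo & sub$date < lo + 30]))
      k2 <- k2 + 1L
    }
  }
  if (overlaps > 0) {
    warning(overlaps, " episode(s) had additional acute HF claims within the ",
            "event month; merged into the episode")
  }
  list(event_month_mean = if (length(event_pool)) mean(event_pool) else NA_real_,
       state_month_mean = if (length(state_pool)) mean(state_pool) else NA_real_,
       n_events = length(event_pool),
       n_state_months = length(state_pool))
}

#' Mean medical cost in the month before death
#'
#' For patients who died of the given cause, sums all costs dated within the
#' 30 days up to and including the death date and returns the mean over
#' patients. Deaths with an unrecognized cause are excluded and counted.
#'
#' @param claims Claims data frame.
#' @param cause `"cv"` or `"noncv"`.
#' @return List with `mean`, `n`, `excluded_unknown_cause`.
#' @export
death_month_cost <- function(claims, cause = c("cv", "noncv")) {
  cause <- match.arg(cause)
  deaths <- claims[!is.na(claims$death_date), ]
  unknown <- sum(!deaths$death_cause %in% c("cv", "noncv"))
  deaths <- deaths[deaths$death_cause %in% cause, ]
  if (nrow(deaths) == 0) {
    return(list(mean = NA_real_, n = 0L, excluded_unknown_cause = unknown))
  }
  per <- vapply(seq_len(nrow(deaths)), function(k) {
    pid <- deaths$patient_id[k]
    dd <- deaths$death_date[k]
    sub <- claims[claims$patient_id == pid &
                    claims$date > dd - 30 & claims$date <= dd, ]
    sum(sub$cost)
  }, numeric(1))
  list(mean = mean(per), n = length(per), excluded_unknown_cause = unknown)
}

#' Full claims-based cost (and hazard) estimation
#'
#' Chains the whole costing procedure: cohort identification, stable monthly
#' cost, event-month and state-month costs, and cause-specific death-month
#' costs. Also reports monthly hazard estimates over the stable follow-up —
#' acute HF events (and deaths by cause) during stable follow-up divided by
#' the total stable person-months — which is the discrete-hazard analogue of
#' the model's monthly transition probabilities. An optional CPI table
#' (`year`, `factor`) rescales each claim's cost to reference-year prices
#' before estimation.
#'
#' @inheritParams stable_monthly_cost
#' @param index_year Calendar year defining cohort entry.
#' @param cpi Optional data frame with `year` and `factor`; claim costs are
#'   multiplied by the factor of their service year.
#' @return A `cost_estimates` list: `stable_monthly`, `event_month`,
#'   `state_month`, `death_month_cv`, `death_month_noncv` (each with mean
#'   and sample size), `hazards` (event, cv death, non-cv death per month),
#'   and `attrition`.
#' @export
estimate_cost_inputs <- function(claims, index_year, censor_date, cpi = NULL) {
  if (!is.null(cpi)) {
    stopifnot(all(c("year", "factor") %in% names(cpi)))
    yr <- as.integer(format(claims$date, "%Y"))
    fac <- cpi$factor[match(yr, cpi$year)]
    if (anyNA(fac)) stop("cpi table does not cover all claim years", call. = FALSE)
    claims$cost <- claims$cost * fac
  }
  censor_date <- as.Date(censor_date)
  id <- identify_stable_cohort(claims, index_year)
  cohort <- id$cohort
  stable <- stable_monthly_cost(claims, cohort, censor_date)
  es <- event_and_state_costs(claims, cohort, censor_date)
  dcv <- death_month_cost(claims, "cv")
  dncv <- death_month_cost(claims, "noncv")

  # discrete monthly hazards over the stable follow-up
  n_event <- 0L; n_dcv <- 0L; n_dncv <- 0L
  cl <- split_claims(claims)
  for (k in seq_len(nrow(cohort))) {
    sub <- cl[[as.character(cohort$patient_id[k])]]
    idx <- cohort$index_date[k]
    sub <- sub[sub$date >= idx, ]
    acute <- sub$date[sub$setting %in% c("emergency", "inpatient") & sub$hf_dx]
    death <- sub$death_date[!is.na(sub$death_date)]
    cause <- sub$death_cause[!is.na(sub$death_date)]
    first_acute <- if (length(acute)) min(acute) else as.Date("9999-12-31")
    if (first_acute <= censor_date &&
        (!length(death) || first_acute < death[1] - 29)) {
      n_event <- n_event + 1L
    } else if (length(death) && death[1] <= censor_date) {
      if (cause[1] == "cv") n_dcv <- n_dcv + 1L else n_dncv <- n_dncv + 1L
    }
  }
  months <- stable$total_months
  structure(
    list(stable_monthly = list(mean = stable$mean, sd = stable$sd, n = stable$n),
         event_month = list(mean = es$event_month_mean, n = es$n_events),
         state_month = list(mean = es$state_month_mean, n = es$n_state_months),
         death_month_cv = list(mean = dcv$mean, n = dcv$n),
         death_month_noncv = list(mean = dncv$mean, n = dncv$n),
         hazards = list(
           event = n_event / months,
           cv_death = n_dcv / months,
           noncv_death = n_dncv / months,
           person_months = months,
           n_events = n_event, n_cv_deaths = n_dcv, n_noncv_deaths = n_dncv),
         attrition = id$attrition),
    class = "cost_estimates"
  )
}

#' @export
print.cost_estimates <- function(x, ...) {
  cat("<cost_estimates>\n")
  cat(sprintf("  stable monthly    %10.1f (n = %d)\n", x$stable_monthly$mean, x$stable_monthly$n))
  cat(sprintf("  event month       %10.1f (n = %d)\n", x$event_month$mean, x$event_month$n))
  cat(sprintf("  state month       %10.1f (n = %d)\n", x$state_month$mean, x$state_month$n))
  cat(sprintf("  death month (CV)  %10.1f (n = %d)\n", x$death_month_cv$mean, x$death_month_cv$n))
  cat(sprintf("  death month (nCV) %10.1f (n = %d)\n", x$death_month_noncv$mean, x$death_month_noncv$n))
  cat(sprintf("  monthly hazards: event %.5f, CV death %.5f, non-CV death %.5f\n",
              x$hazards$event, x$hazards$cv_death, x$hazards$noncv_death))
  invisible(x)
}
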