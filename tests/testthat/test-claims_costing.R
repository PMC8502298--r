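test_that("cohort filters admit and exclude per the identification criteria", {
  claims <- make_claims(
    # included: two ambulatory HF dx 100 days apart, clean lookback
    claim_row(1, "2015-02-01"), claim_row(1, "2015-05-12"),
    # excluded: diagnoses 200 days apart
    claim_row(2, "2015-01-10"), claim_row(2, "2015-07-29"),
    # excluded: HF admission 30 days before the first index-year dx
    claim_row(3, "2015-01-02", "inpatient"),
    claim_row(3, "2015-02-01"), claim_row(3, "2015-03-01")
  )
  id <- identify_stable_cohort(claims, 2015)
  expect_equal(id$cohort$patient_id, 1)
  expect_equal(id$cohort$index_date, as.Date("2015-02-01"))
  expect_equal(id$attrition$n, c(3L, 2L, 1L))
  expect_true(all(diff(id$attrition$n) <= 0))
})

test_that("empty claims give an empty cohort with zero counts", {
  id <- identify_stable_cohort(claim_row(1, "2015-01-01")[0, ], 2015)
  expect_equal(nrow(id$cohort), 0)
  expect_equal(id$attrition$n, c(0L, 0L, 0L))
})

test_that("stable monthly cost divides summed costs by follow-up months", {
  idx <- as.Date("2015-01-01")
  claims <- stable_patient(1, idx, months = 10, monthly_cost = 300)
  id <- identify_stable_cohort(claims, 2015)
  est <- stable_monthly_cost(claims, id$cohort, censor_date = idx + 299)
  expect_equal(est$mean, 300)
  expect_equal(est$total_months, 10)
})

test_that("stable follow-up truncates at the event month", {
  idx <- as.Date("2015-01-01")
  claims <- make_claims(
    stable_patient(1, idx, months = 2, monthly_cost = 300),
    claim_row(1, idx + 60, "inpatient", TRUE, 5000),   # acute event, month 3
    claim_row(1, idx + 95, "ambulatory", TRUE, 400),   # post-event month
    stable_patient(2, idx, months = 4, monthly_cost = 100)
  )
  id <- identify_stable_cohort(claims, 2015)
  est <- stable_monthly_cost(claims, id$cohort, censor_date = idx + 119)
  # patient 1: 600 over 2 months; patient 2: 400 over 4 months
  expect_equal(est$mean, mean(c(300, 100)))
  expect_equal(est$n, 2)
})

test_that("event-month and state-month pools split at 30 days", {
  idx <- as.Date("2015-03-01")
  e <- idx + 60
  claims <- make_claims(
    claim_row(1, idx, cost = 0), claim_row(1, idx + 30, cost = 0),
    claim_row(1, e, "inpatient", TRUE, 2800),
    claim_row(1, e + 35, "ambulatory", TRUE, 400)
  )
  id <- identify_stable_cohort(claims, 2015)
  es <- event_and_state_costs(claims, id$cohort, censor_date = e + 59)
  expect_equal(es$event_month_mean, 2800)
  expect_equal(es$state_month_mean, 400)
  expect_equal(es$n_events, 1)
  expect_equal(es$n_state_months, 1)
})

test_that("no events is flagged rather than silently zero", {
  idx <- as.Date("2015-01-01")
  claims <- stable_patient(1, idx, 4, 100)
  id <- identify_stable_cohort(claims, 2015)
  es <- event_and_state_costs(claims, id$cohort, censor_date = idx + 200)
  expect_true(is.na(es$event_month_mean))
  expect_equal(es$n_events, 0)
})

test_that("two patients pool into means by direct arithmetic", {
  idx <- as.Date("2015-01-01")
  mk <- function(pid, ev_cost, st_cost) make_claims(
    claim_row(pid, idx, cost = 0), claim_row(pid, idx + 20, cost = 0),
    claim_row(pid, idx + 40, "emergency", TRUE, ev_cost),
    claim_row(pid, idx + 75, "ambulatory", FALSE, st_cost))
  claims <- make_claims(mk(1, 2000, 300), mk(2, 4000, 500))
  id <- identify_stable_cohort(claims, 2015)
  es <- event_and_state_costs(claims, id$cohort, censor_date = idx + 40 + 59)
  expect_equal(es$event_month_mean, 3000)
  expect_equal(es$state_month_mean, 400)
})

test_that("death-month costs are cause-specific and flag unknowns", {
  d1 <- as.Date("2016-06-30"); d2 <- as.Date("2016-08-15")
  claims <- make_claims(
    claim_row(1, d1 - 10, "inpatient", FALSE, 3500, death_date = d1, death_cause = "cv"),
    claim_row(2, d2 - 5, "inpatient", FALSE, 3000, death_date = d2, death_cause = "noncv"),
    claim_row(3, d2 - 5, "inpatient", FALSE, 999, death_date = d2, death_cause = "accident")
  )
  expect_equal(death_month_cost(claims, "cv")$mean, 3500)
  ncv <- death_month_cost(claims, "noncv")
  expect_equal(ncv$mean, 3000)
  expect_equal(ncv$excluded_unknown_cause, 1L)
  no_deaths <- death_month_cost(stable_patient(9, "2015-01-01", 2), "cv")
  expect_true(is.na(no_deaths$mean))
  expect_equal(no_deaths$n, 0L)
})

test_that("no claim is double-counted across the four cost pools", {
  idx <- as.Date("2015-01-01")
  death <- idx + 149
  claims <- make_claims(
    claim_row(1, idx + 5, "ambulatory", TRUE, 100),
    claim_row(1, idx + 35, "ambulatory", TRUE, 100),
    claim_row(1, idx + 60, "inpatient", TRUE, 2800),
    claim_row(1, idx + 95, "ambulatory", TRUE, 400),
    claim_row(1, idx + 135, "inpatient", FALSE, 3500,
              death_date = death, death_cause = "cv")
  )
  # index anchors at the first ambulatory HF dx (idx + 5)
  id <- identify_stable_cohort(claims, 2015)
  censor <- as.Date("2018-12-31")
  stable <- stable_monthly_cost(claims, id$cohort, censor)
  es <- event_and_state_costs(claims, id$cohort, censor)
  dm <- death_month_cost(claims, "cv")
  stable_total <- stable$mean * stable$total_months
  pooled <- stable_total + es$event_month_mean * es$n_events +
    es$state_month_mean * es$n_state_months + dm$mean * dm$n
  expect_equal(pooled, sum(claims$cost))
})

test_that("the full estimation chain returns a coherent cost block", {
  gen <- generate_claims(claims_gen_params(n_patients = 250, seed = 42))
  est <- estimate_cost_inputs(gen$claims, index_year = 2015,
                              censor_date = gen$truth$censor_date)
  expect_s3_class(est, "cost_estimates")
  expect_true(all(diff(est$attrition$n) <= 0))
  expect_gt(est$stable_monthly$mean, 0)
  expect_gt(est$hazards$person_months, 0)
  expect_lt(est$hazards$event, 0.05)
})

test_that("CPI adjustment rescales claim costs per service year", {
  idx <- as.Date("2015-01-01")
  claims <- stable_patient(1, idx, months = 3, monthly_cost = 100)
  cpi <- data.frame(year = 2015, factor = 1.1)
  est <- estimate_cost_inputs(claims, 2015, idx + 89, cpi = cpi)
  expect_equal(est$stable_monthly$mean, 110)
  expect_error(estimate_cost_inputs(claims, 2015, idx + 89,
                                    cpi = data.frame(year = 2014, factor = 1)),
               "cover all claim years")
})
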