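test_that("transition matrix carries the printed probabilities with remainder to stable", {
  P <- build_transition_matrix(table1_sc, arm = "standard_care")
  expect_equal(unname(P["StableHF", ]),
               c(1 - 0.007881397 - 0.006698743 - 0.001312441,
                 0.007881397, 0.006698743, 0.001312441))
  expect_equal(unname(P["AcuteHFEvent", ]), unname(P["StableHF", ]))
  expect_equal(unname(P["CVDeath", ]), c(0, 0, 1, 0))
  expect_equal(unname(rowSums(P)), rep(1, 4))
})

test_that("degenerate and invalid transition inputs are handled", {
  P0 <- build_transition_matrix(list(p_hhf = 0, p_cv_death = 0, p_noncv_death = 0))
  expect_equal(matrix(P0, 4, 4),
               rbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
                     c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_error(
    build_transition_matrix(list(p_hhf = 0.6, p_cv_death = 0.5,
                                 p_noncv_death = 0), arm = "badarm"),
    "badarm")
  expect_error(build_transition_matrix(list(p_hhf = -0.1, p_cv_death = 0,
                                            p_noncv_death = 0)), "\\[0, 1\\]")
})

test_that("cohort trace equals manual matrix powers on a hand matrix", {
  P <- build_transition_matrix(list(p_hhf = 0.2, p_cv_death = 0.1,
                                    p_noncv_death = 0.05))
  tr <- run_cohort(P, sim_settings(horizon_cycles = 2, cohort_size = 1))
  start <- c(1, 0, 0, 0)
  expect_equal(unname(tr$occupancy[2, ]), unname(as.vector(start %*% P)))
  expect_equal(unname(tr$occupancy[3, ]), unname(as.vector(start %*% P %*% P)))
  # flows by hand: cycle 1 inflow to event = 0.2; cycle 2 = (0.65 + 0.2) * 0.2
  expect_equal(tr$hhf_flow, c(0.2, 0.85 * 0.2))
  expect_equal(unname(tr$death_flow[1, ]), c(0.1, 0.05))
})

test_that("occupancy is conserved and death states are monotone absorbing", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(3, 0, 0.2)
    P <- build_transition_matrix(list(p_hhf = p[1], p_cv_death = p[2],
                                      p_noncv_death = p[3]))
    tr <- run_cohort(P, sim_settings(horizon_cycles = 60))
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    dead <- tr$occupancy[, "CVDeath"] + tr$occupancy[, "NonCVDeath"]
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-15 & tr$occupancy <= 1 + 1e-15))
  }
})

test_that("a cohort starting all-dead never moves", {
  P <- build_transition_matrix(table1_sc)
  tr <- run_cohort(P, sim_settings(horizon_cycles = 12), start = c(0, 0, 1, 0))
  expect_true(all(tr$occupancy[, "CVDeath"] == 1))
  expect_equal(sum(tr$hhf_flow), 0)
})

test_that("microsimulation is reproducible and vanishes without hazards", {
  P <- build_transition_matrix(table1_sc)
  s <- sim_settings(horizon_cycles = 24)
  m1 <- microsimulate_cohort(P, s, n_individuals = 2000, seed = 5)
  m2 <- microsimulate_cohort(P, s, n_individuals = 2000, seed = 5)
  expect_identical(m1$occupancy, m2$occupancy)
  P0 <- build_transition_matrix(list(p_hhf = 0, p_cv_death = 0, p_noncv_death = 0))
  m0 <- microsimulate_cohort(P0, s, n_individuals = 500, seed = 1)
  expect_equal(sum(m0$hhf_flow), 0)
  expect_equal(m0$cumulative_mortality, 0)
})

test_that("single-cycle accumulation matches the closed form", {
  tr <- run_cohort(build_transition_matrix(list(p_hhf = 0, p_cv_death = 0,
                                                p_noncv_death = 0)),
                   sim_settings(horizon_cycles = 1, annual_discount = 0))
  costs <- list(drug_monthly = 0, stable_monthly = 0, event_month = 0,
                death_month_cv = 0, death_month_noncv = 0)
  utils_ <- list(stable_hf = 0.77, aging_decrement_per_year = 0,
                 hhf_decrement = 0)
  out <- accumulate_outcomes(tr, costs, utils_)
  expect_equal(out$qaly_discounted, 0.77 / 12)
  expect_equal(out$cost_discounted, 0)
  expect_equal(out$ly_undiscounted, 1 / 12)
})

test_that("zero discounting equalizes discounted and undiscounted totals", {
  cfg <- taiwan_base_config()
  cfg$settings$annual_discount <- 0
  res <- run_model(cfg)
  for (o in list(res$comparator, res$intervention)) {
    expect_equal(o$cost_discounted, o$cost_undiscounted)
    expect_equal(o$qaly_discounted, o$qaly_undiscounted)
    expect_equal(o$ly_discounted, o$ly_undiscounted)
  }
})

test_that("discounted totals never exceed undiscounted ones", {
  res <- run_model(taiwan_base_config())
  for (o in list(res$comparator, res$intervention)) {
    expect_lte(o$cost_discounted, o$cost_undiscounted)
    expect_lte(o$qaly_discounted, o$qaly_undiscounted)
    expect_lte(o$ly_discounted, o$ly_undiscounted)
    expect_lte(o$ly_undiscounted, o$settings$horizon_cycles / 12)
  }
})

test_that("the intervention arm has lower mortality and fewer acute events", {
  res <- run_model(taiwan_base_config())
  expect_lt(res$intervention$cumulative_mortality,
            res$comparator$cumulative_mortality)
  expect_lt(res$intervention$hhf_events_expected,
            res$comparator$hhf_events_expected)
})

test_that("trace exports as a tidy cycle-by-state table", {
  P <- build_transition_matrix(table1_sc)
  tr <- run_cohort(P, sim_settings(horizon_cycles = 10))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 11 * 4)
  expect_named(df, c("cycle", "state", "occupancy", "flow"))
  expect_equal(sum(df$flow[df$state == "AcuteHFEvent"]), sum(tr$hhf_flow))
})
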