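test_that("ICER divides unrounded increments", {
  a <- make_outcome(cost = 11304, qaly = 0.94, ly = 1.25, arm = "add_on")
  b <- make_outcome(cost = 0, qaly = 0, ly = 0, arm = "soc")
  r <- icer(a, b)
  expect_equal(r$icer_per_qaly, 11304 / 0.94)   # 12025.53
  expect_equal(r$icer_per_ly, 11304 / 1.25)
  expect_equal(r$delta_cost, 11304)
})

test_that("dominance labels follow the quadrant convention", {
  base <- make_outcome(0, 0, 0)
  expect_equal(icer(make_outcome(-1, 0.1, 0.1), base)$icer_per_qaly, "dominant")
  expect_equal(icer(make_outcome(1, 0, 0), base)$icer_per_qaly, "dominated")
  expect_equal(icer(make_outcome(1, -0.2, 0), base)$icer_per_qaly, "dominated")
})

test_that("mismatched settings are rejected", {
  a <- make_outcome(1, 1, 1, settings = sim_settings(horizon_cycles = 180))
  b <- make_outcome(1, 1, 1, settings = sim_settings(horizon_cycles = 18))
  expect_error(icer(a, b), "different simulation settings")
})

test_that("net monetary benefit is the standard linear transform", {
  r <- list(delta_cost = 11304, delta_qaly = 0.94)
  expect_equal(net_monetary_benefit(r, 25000), 25000 * 0.94 - 11304)  # 12196
  expect_equal(net_monetary_benefit(r, 0), -11304)
  expect_equal(net_monetary_benefit(list(delta_cost = 500, delta_qaly = 0), 1e9),
               -500)
})

test_that("NMB sign agrees with the ICER decision over a grid", {
  lambdas <- c(1000, 25000, 75000, 2e5)
  for (dc in c(100, 5000, 50000)) {
    for (dq in c(0.01, 0.5, 2)) {
      for (l in lambdas) {
        nmb <- net_monetary_benefit(list(delta_cost = dc, delta_qaly = dq), l)
        expect_equal(nmb > 0, dc / dq < l)
      }
    }
  }
})

test_that("willingness-to-pay tiers classify ICERs", {
  res <- function(icer_q, dq = 1) {
    dc <- if (is.character(icer_q)) NA_real_ else icer_q * dq
    structure(list(delta_cost = dc, delta_qaly = dq,
                   icer_per_qaly = icer_q), class = "incremental_result")
  }
  expect_equal(ce_decision(res(12035)), "very cost-effective")
  expect_equal(ce_decision(res(44670)), "cost-effective")
  expect_equal(ce_decision(res(80000)), "not cost-effective")
  expect_equal(ce_decision(res("dominant")), "very cost-effective")
  expect_equal(ce_decision(res("dominated")), "not cost-effective")
})

test_that("the decision is monotone in the thresholds", {
  res <- structure(list(delta_cost = 40000, delta_qaly = 1,
                        icer_per_qaly = 40000), class = "incremental_result")
  ranks <- c("not cost-effective" = 0, "cost-effective" = 1,
             "very cost-effective" = 2)
  dec <- vapply(c(10000, 39999, 40000, 60000),
                function(l) ranks[[ce_decision(res, c(l, 3 * l))]], numeric(1))
  expect_true(all(diff(dec) >= 0))
})

test_that("ICER is invariant to cohort size", {
  cfg1 <- taiwan_base_config()
  cfg2 <- cfg1
  cfg2$settings$cohort_size <- 250
  r1 <- run_model(cfg1)$incremental
  r2 <- run_model(cfg2)$incremental
  expect_equal(r1$icer_per_qaly, r2$icer_per_qaly)
})
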