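test_that("beta moments match the closed form and the sampled distribution", {
  p <- beta_from_moments(0.77, 0.016)
  nu <- 0.77 * 0.23 / 0.016^2 - 1
  expect_equal(p$shape1, 0.77 * nu)   # ~531.9
  expect_equal(p$shape2, 0.23 * nu)   # ~158.9
  expect_equal(p$shape1, 531.9, tolerance = 1e-3)
  set.seed(3)
  x <- rbeta(1e5, p$shape1, p$shape2)
  expect_lt(abs(mean(x) - 0.77), 3 * 0.016 / sqrt(1e5))
  expect_equal(sd(x), 0.016, tolerance = 0.02)
})

test_that("beta parameterization errors are raised", {
  expect_error(beta_from_moments(0.5, 0), "point mass")
  expect_error(beta_from_moments(0.5, 0.5), "variance")
  expect_error(beta_from_moments(1.2, 0.1), "\\(0, 1\\)")
})

test_that("gamma moments match the closed form", {
  g <- gamma_from_moments(450, 225)
  expect_equal(g$shape, 4)
  expect_equal(g$rate, 1 / 112.5)
  g2 <- gamma_from_moments(28.6, 14.3)
  expect_equal(g2$shape, 4)
  expect_equal(g2$rate, 0.13986014, tolerance = 1e-7)
  set.seed(4)
  x <- rgamma(1e5, shape = g$shape, rate = g$rate)
  expect_lt(abs(mean(x) - 450), 3 * 225 / sqrt(1e5))
  expect_error(gamma_from_moments(-1, 1), "> 0")
})

test_that("one-way DSA spans match direct reruns and collapse at zero width", {
  cfg <- taiwan_base_config()
  bounds <- data.frame(parameter = "stable_monthly", low = 400, high = 500)
  td <- one_way_dsa(cfg, bounds)
  lo <- run_model(set_param_public(cfg, "stable_monthly", 400))
  hi <- run_model(set_param_public(cfg, "stable_monthly", 500))
  expect_equal(td$icer_at_low, lo$incremental$icer_per_qaly)
  expect_equal(td$icer_at_high, hi$incremental$icer_per_qaly)
  expect_equal(td$span, abs(hi$incremental$icer_per_qaly -
                              lo$incremental$icer_per_qaly))

  base <- 450
  zero <- one_way_dsa(cfg, data.frame(parameter = "stable_monthly",
                                      low = base, high = base))
  expect_equal(zero$span, 0)
})

test_that("DSA rejects bounds that do not bracket the base value", {
  cfg <- taiwan_base_config()
  expect_error(one_way_dsa(cfg, data.frame(parameter = "stable_monthly",
                                           low = 500, high = 600)),
               "bracket")
})

test_that("degenerate distributions make every PSA draw the base case", {
  cfg <- taiwan_base_config()
  for (nm in names(cfg$distributions)) cfg$distributions[[nm]]$sd <- 0
  base <- run_model(cfg)$incremental
  for (mode in c("paired", "independent")) {
    psa <- run_psa(cfg, iterations = 3, seed = 9, sampling = mode)
    expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 3))
    expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 3))
  }
})

test_that("PSA is reproducible given the seed", {
  cfg <- taiwan_base_config()
  p1 <- run_psa(cfg, iterations = 25, seed = 17)
  p2 <- run_psa(cfg, iterations = 25, seed = 17)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, iterations = 25, seed = 18)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("PSA draws reproduce the configured means within 3 SE", {
  cfg <- taiwan_base_config()
  n <- 4000
  set.seed(31)
  for (nm in c("stable_monthly", "utility_stable", "standard_care.p_hhf")) {
    spec <- cfg$distributions[[nm]]
    x <- hfcea:::sample_spec(spec, n)
    expect_lt(abs(mean(x) - spec$mean), 3 * spec$sd / sqrt(n))
  }
})

test_that("CEAC probabilities are exact empirical fractions", {
  draws <- data.frame(delta_cost = c(100, -50, 300),
                      delta_qaly = c(0.01, 0.01, -0.01))
  # by hand: NMB at lambda = 20000: 100, 250, -500 -> 2/3
  #          NMB at lambda =  5000: -50, 100, -350 -> 1/3
  curve <- ceac(draws, c(5000, 20000))
  expect_equal(curve$probability, c(1 / 3, 2 / 3))
  # lambda = 0: fraction of cost-saving draws
  expect_equal(ceac(draws, 0)$probability, 1 / 3)
  # lambda far above any draw ICER with positive effect, negative-effect draw excluded
  pos <- draws[draws$delta_qaly > 0, ]
  expect_equal(ceac(pos, 1e9)$probability, 1)
  expect_error(ceac(draws, numeric(0)), "non-empty")
})

test_that("CEAC is non-decreasing in lambda for effect-positive draws", {
  cfg <- taiwan_base_config()
  psa <- run_psa(cfg, iterations = 60, seed = 2)
  grid <- seq(0, 80000, by = 10000)
  curve <- ceac(psa, grid)
  expect_equal(nrow(curve), length(grid))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})
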