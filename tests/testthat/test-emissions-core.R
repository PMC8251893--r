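test_that("area decays exponentially and matches a fine Euler integration", {
  expect_equal(area_remaining(1000, d = 0, t = 50), 1000)
  expect_equal(area_remaining(0, d = 0.2, t = 10), 0)
  expect_equal(area_remaining(911223, d = 0.0055, t = 90),
               911223 * exp(-0.495))
  # forward Euler on dA/dt = -A d, step 1e-3 yr (frozen from the oracle run)
  euler_90yr <- 555454.274744
  expect_lt(abs(area_remaining(911223, 0.0055, 90) - euler_90yr) / euler_90yr,
            1e-3)
  expect_error(area_remaining(-1, 0.1, 1), "non-negative")
})

test_that("effective carbon is the share/factor-weighted stock with addends", {
  simplex <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  expect_equal(effective_carbon(600, factors = rep(1, 5), shares = simplex)$total,
               600)
  one <- effective_carbon(600, factors = c(0.5, 1, 1, 1, 1),
                          shares = c(1, 0, 0, 0, 0))
  expect_equal(one$total, 300)
  f <- c(0.8, 0.6, 0.5, 0.3, 0.9)
  p <- c(0.6, 0.2, 0.1, 0.05, 0.05)
  ec <- effective_carbon(747.9, f, p)
  expect_equal(unname(ec$addends), 747.9 * f * p)
  expect_equal(ec$total, sum(747.9 * f * p))
  expect_error(effective_carbon(600, f, c(0.5, 0.1, 0.1, 0.1, 0.1)), "sum to 1")
  expect_error(effective_carbon(600, c(1.2, f[-1]), p), "\\[0, 1\\]")
})

test_that("cumulative emissions: trivial limits and the frozen quadrature value", {
  expect_equal(cumulative_emissions(1e5, d = 0, c = 500, r = 0.07, T = 90), 0)
  # conservation limit: everything eventually deforested emits its stock
  expect_equal(cumulative_emissions(1e5, d = 0.01, c = 500, r = 0.07, T = 1e5),
               1e5 * 500, tolerance = 1e-9)
  # frozen from adaptive quadrature of the cohort integrand (rel.tol 1e-12)
  expect_equal(cumulative_emissions(1, d = 0.01, c = 1, r = log(2) / 10, T = 90),
               0.52521514039, tolerance = 1e-10)
  expect_error(cumulative_emissions(1, 0.01, 1, r = 0, T = 90), "positive")
})

test_that("closed form matches adaptive quadrature to 1e-8 including r near d", {
  draws <- random_cohort_params(40, seed = 101)
  for (i in seq_len(nrow(draws))) {
    p <- draws[i, ]
    expect_equal(cumulative_emissions(p$A1, p$d, p$c, p$r, p$T),
                 quad_emissions(p$A1, p$d, p$c, p$r, p$T),
                 tolerance = 1e-8)
  }
  # stress the r = d degeneracy and its neighbourhood
  for (eps in c(0, 1e-12, 1e-9, 1e-7, 1e-4)) {
    d <- 0.02
    expect_equal(cumulative_emissions(1e4, d, 300, d * (1 + eps), 90),
                 quad_emissions(1e4, d, 300, d * (1 + eps), 90),
                 tolerance = 1e-8)
  }
})

test_that("emissions are linear in area and stock, monotone in T, d, r", {
  E <- function(A1 = 1e4, d = 0.003, c = 400, r = log(2) / 10, T = 90) {
    cumulative_emissions(A1, d, c, r, T)
  }
  expect_equal(E(A1 = 2e4), 2 * E())
  expect_equal(E(c = 800), 2 * E())
  expect_true(all(diff(E(T = c(10, 30, 60, 90, 150))) > 0))
  expect_true(all(diff(E(d = c(0.001, 0.003, 0.01, 0.03))) > 0))
  expect_true(all(diff(E(r = c(0.01, 0.05, 0.1, 0.5))) > 0))
  # bounded by the total at-risk stock at every horizon
  expect_true(all(E(T = c(1, 10, 100, 1000)) <= 1e4 * 400))
})

test_that("foregone sequestration matches its closed form and trapezoid oracle", {
  expect_equal(foregone_sequestration(1e4, d = 0, s = 1.5, T = 90), 0)
  expect_equal(foregone_sequestration(1e4, d = 0.01, s = 1.5, T = 0), 0)
  # frozen from trapezoid integration of s*A1*(1 - e^{-dt}) on a 1e-3 grid
  expect_equal(foregone_sequestration(1, d = 0.01, s = 1.5, T = 90),
               45.98544896, tolerance = 1e-8)
  set.seed(77)
  for (i in 1:8) {
    A1 <- runif(1, 1e3, 1e6); d <- runif(1, 1e-4, 0.01); s <- runif(1, 0.5, 3)
    expect_equal(foregone_sequestration(A1, d, s, 90),
                 trapezoid_foregone(A1, d, s, 90), tolerance = 1e-6)
  }
  # monotone in T, d and s
  expect_true(all(diff(foregone_sequestration(1e4, 0.005, 1.5,
                                              c(10, 50, 90, 200))) > 0))
  expect_true(all(diff(foregone_sequestration(1e4, c(1e-4, 1e-3, 1e-2),
                                              1.5, 90)) > 0))
})

test_that("CO2-equivalent conversion is plain stoichiometry", {
  expect_equal(to_co2eq(12), 44e-6)
  expect_equal(to_co2eq(0), 0)
  expect_equal(to_co2eq(1e6), 44 / 12, tolerance = 1e-12)
  expect_equal(to_co2eq(100, co2_per_c = 3), 3e-4)
})

test_that("trajectories end exactly at the closed-form horizon values", {
  provs <- generate_provinces(n = 4, seed = 21)
  cfg <- model_config()
  traj <- project_trajectory(provs, cfg)
  for (i in seq_len(nrow(provs))) {
    row <- provs[i, ]
    tr <- traj[traj$province_id == row$province_id, ]
    expect_equal(tr$time_yr[1], 0)
    expect_equal(tr$cum_emitted_c_mg[1], 0)
    expect_equal(tr$area_ha[1], row$area_ha)
    # area non-increasing, cumulative series non-decreasing
    expect_true(all(diff(tr$area_ha) <= 0))
    expect_true(all(diff(tr$cum_emitted_c_mg) >= 0))
    expect_true(all(diff(tr$cum_co2eq_tg) >= 0))
    # closed-form horizon totals, evaluated outside the grid machinery
    soc <- row$soc2m_mgc_ha
    addends <- (soc + row$abc_mgc_ha) *
      unlist(row[paste0("ef_", mangrove_drivers())]) *
      unlist(row[paste0("share_", mangrove_drivers())])
    expected <- sum(cumulative_emissions(row$area_ha, row$deforestation_rate,
                                         addends, cfg$emission_release_rate,
                                         cfg$horizon_years))
    expect_equal(tr$cum_emitted_c_mg[nrow(tr)], expected)
  }
})

test_that("a province with no deforestation has a flat, emission-free trajectory", {
  provs <- generate_provinces(n = 1, seed = 3)
  provs$deforestation_rate <- 0
  traj <- project_trajectory(provs, model_config())
  expect_true(all(traj$area_ha == provs$area_ha))
  expect_true(all(traj$cum_emitted_c_mg == 0))
  expect_true(all(traj$cum_foregone_seq_c_mg == 0))
})

test_that("model_config validates its inputs", {
  expect_error(model_config(horizon_years = -1), "positive")
  expect_error(model_config(emission_release_rate = c(0.1, 0.2)), "length 1 or 5")
  expect_error(model_config(emission_release_rate = 0), "positive")
  cfg <- model_config(emission_release_rate = c(
    settlement = 0.1, commodities = 0.2, erosion = 0.3, clearing = 0.4,
    climatic = 0.5))
  # named vectors are reordered into canonical driver order
  expect_equal(cfg$emission_release_rate[["commodities"]], 0.2)
  expect_equal(names(cfg$emission_release_rate), mangrove_drivers())
})
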