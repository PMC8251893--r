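test_that("the identity scenario reproduces the base projection", {
  provs <- generate_provinces(n = 10, seed = 51)
  grid <- run_scenarios(provs, model_config(),
                        list(scenario_spec("identity")))
  base <- grid$summary[grid$summary$label == "base", ]
  ident <- grid$summary[grid$summary$label == "identity", ]
  expect_equal(ident$global_emissions_tg, base$global_emissions_tg)
  expect_equal(ident$topk_overlap_with_base, min(6, 10))
})

test_that("halving the erosion emission factor halves an erosion-only province", {
  provs <- generate_provinces(n = 1, seed = 52)
  provs[paste0("share_", mangrove_drivers())] <- 0
  provs$share_erosion <- 1
  cfg <- model_config(include_sequestration = FALSE)
  grid <- run_scenarios(provs, cfg,
                        list(scenario_spec("half", erosion_ef_multiplier = 0.5)))
  base <- grid$summary$global_emissions_tg[grid$summary$label == "base"]
  half <- grid$summary$global_emissions_tg[grid$summary$label == "half"]
  expect_equal(half, base / 2)
})

test_that("scenarios naming a missing input variant fail with its name", {
  provs <- generate_provinces(n = 4, seed = 53)
  expect_error(
    run_scenarios(provs, model_config(),
                  list(scenario_spec("alt", rate_col = "rate_goldberg"))),
    "rate_goldberg")
})

test_that("top-k overlap between scenario rankings matches hand enumeration", {
  provs <- generate_provinces(n = 8, seed = 54)
  # variant rates reshuffle the ranking deterministically
  provs$rate_alt <- rev(provs$deforestation_rate)
  cfg <- model_config()
  grid <- run_scenarios(provs, cfg,
                        list(scenario_spec("alt", rate_col = "rate_alt")),
                        k = 3)
  base_proj <- grid$projections$base
  alt_proj <- grid$projections$alt
  by_hand <- length(intersect(base_proj$provinces$province_id[1:3],
                              alt_proj$provinces$province_id[1:3]))
  expect_equal(grid$summary$topk_overlap_with_base[grid$summary$label == "alt"],
               by_hand)
  expect_equal(rank_overlap(alt_proj, base_proj, 3), by_hand)
  expect_equal(rank_overlap(base_proj, base_proj, 8), 8)
})

test_that("the SOC-depth scenario uses the 1 m stock", {
  provs <- generate_provinces(n = 5, seed = 55)
  grid <- run_scenarios(provs, model_config(include_sequestration = FALSE),
                        list(scenario_spec("soc1m", soc_depth = "1m")))
  base <- grid$summary$global_emissions_tg[grid$summary$label == "base"]
  shallow <- grid$summary$global_emissions_tg[grid$summary$label == "soc1m"]
  expect_lt(shallow, base)
})

test_that("linear parameters get exact analytic derivatives", {
  provs <- generate_provinces(n = 3, seed = 56)
  cfg <- model_config()
  rep <- sensitivity_derivative(provs, cfg,
                                parameters = c("A1", "c_max", "s",
                                               "f_commodities"))
  proj <- project_provinces(provs, cfg)
  for (i in seq_len(nrow(provs))) {
    id <- provs$province_id[i]
    prow <- proj$provinces[proj$provinces$province_id == id, ]
    L <- prow$total_tg
    a1 <- rep[rep$province_id == id & rep$parameter == "A1", ]
    expect_equal(a1$derivative_tg_per_unit, L / provs$area_ha[i])
    expect_equal(a1$elasticity, 1)
    cmax <- rep[rep$province_id == id & rep$parameter == "c_max", ]
    expect_equal(cmax$derivative_tg_per_unit,
                 prow$emissions_tg / (provs$soc2m_mgc_ha[i] + provs$abc_mgc_ha[i]))
    s <- rep[rep$province_id == id & rep$parameter == "s", ]
    expect_equal(s$derivative_tg_per_unit, prow$foregone_seq_tg / 1.5)
    expect_true(all(rep$method[rep$province_id == id] == "analytic"))
  }
})

test_that("finite-difference d-derivative matches the symbolic closed form", {
  provs <- generate_provinces(n = 5, seed = 57)
  cfg <- model_config()
  rep <- sensitivity_derivative(provs, cfg, parameters = "d")
  for (i in seq_len(nrow(provs))) {
    row <- provs[i, ]
    if (row$deforestation_rate == 0) next
    addends <- (row$soc2m_mgc_ha + row$abc_mgc_ha) *
      unlist(row[paste0("ef_", mangrove_drivers())]) *
      unlist(row[paste0("share_", mangrove_drivers())])
    sym <- sum(vapply(seq_along(addends), function(j) {
      demissions_dd(row$area_ha, row$deforestation_rate, addends[j],
                    cfg$emission_release_rate[j], cfg$horizon_years)
    }, numeric(1))) +
      dforegone_dd(row$area_ha, row$deforestation_rate,
                   row$seq_rate_mgc_ha_yr, cfg$horizon_years)
    sym_tg <- sym * cfg$co2_per_c / 1e6
    got <- rep$derivative_tg_per_unit[rep$province_id == row$province_id]
    expect_equal(got, sym_tg, tolerance = 1e-6)
    expect_equal(rep$method[rep$province_id == row$province_id],
                 "finite_difference")
  }
})

test_that("emissions increase with deforestation rate for admissible parameters", {
  draws <- random_cohort_params(25, seed = 58)
  for (i in seq_len(nrow(draws))) {
    p <- draws[i, ]
    expect_gt(demissions_dd(p$A1, p$d, p$c, p$r, p$T), 0)
    h <- 1e-5
    fd <- (cumulative_emissions(p$A1, p$d * (1 + h), p$c, p$r, p$T) -
             cumulative_emissions(p$A1, p$d * (1 - h), p$c, p$r, p$T))
    expect_gt(fd, 0)
  }
})

test_that("the release rate only matters in the short term", {
  # dL/dr peaks on the deforestation timescale 1/d, then decays to zero:
  # once everything deforested has emitted, the release speed is irrelevant
  provs <- generate_provinces(n = 1, seed = 59)
  provs$deforestation_rate <- 0.01
  dLdr <- vapply(c(90, 300, 1000, 5000), function(T) {
    cfg <- model_config(horizon_years = T)
    rep <- sensitivity_derivative(provs, cfg, parameters = "r")
    rep$derivative_tg_per_unit
  }, numeric(1))
  expect_true(all(dLdr >= 0))
  expect_true(all(diff(dLdr) < 0))
  expect_lt(dLdr[4], dLdr[1] / 100)
})

test_that("elasticity is flagged undefined for a zero-emission province", {
  provs <- generate_provinces(n = 1, seed = 60)
  provs$deforestation_rate <- 0
  provs[paste0("share_", mangrove_drivers())] <- 0
  rep <- sensitivity_derivative(provs, model_config(),
                                parameters = c("A1", "c_max"))
  expect_true(all(is.na(rep$elasticity)))
  expect_true(all(!rep$elasticity_defined))
  expect_error(sensitivity_derivative(provs, model_config(), parameters = "d"),
               "positive deforestation rate")
})

test_that("scenario and derivative CSV reports are written", {
  provs <- generate_provinces(n = 4, seed = 61)
  grid <- run_scenarios(provs, model_config(), standard_scenarios())
  rep <- sensitivity_derivative(provs, model_config())
  dir <- withr::local_tempdir()
  paths <- write_sensitivity_csv(grid, rep, dir)
  expect_true(all(file.exists(paths)))
  totals <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_setequal(totals$label, c("base", "soc_1m", "erosion_ef_50",
                                  "no_climatic"))
})
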