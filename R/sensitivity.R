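#' Define one scenario of the sensitivity grid
#'
#' A scenario names which input variant and model switches to use:
#' alternative area or deforestation-rate columns of the province table
#' (e.g. rates derived from a different loss dataset), the SOC depth, the
#' erosion emission-factor multiplier (0.5 for the low-erosion case), and
#' whether loss from extreme climatic events is counted.
#'
#' @param label Unique scenario label.
#' @param area_col,rate_col Columns of the province table supplying area
#'   (ha) and deforestation rate (yr^-1); defaults are the base columns.
#' @param soc_depth `"2m"` or `"1m"`.
#' @param erosion_ef_multiplier Multiplier on the erosion emission factor.
#' @param include_climatic Include the climatic-event driver?
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(label,
                          area_col = "area_ha",
                          rate_col = "deforestation_rate",
                          soc_depth = "2m",
                          erosion_ef_multiplier = 1,
                          include_climatic = TRUE) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  structure(
    list(label = label, area_col = area_col, rate_col = rate_col,
         soc_depth = soc_depth,
         erosion_ef_multiplier = erosion_ef_multiplier,
         include_climatic = include_climatic),
    class = "scenario_spec"
  )
}

#' Run a grid of scenarios
#'
#' Re-projects every province under each scenario and summarises how stable
#' the hotspot ranking is: for each scenario, the number of its top-k
#' provinces that are also in the base projection's top-k set.
#'
#' @param data Validated province table.
#' @param base_config Base [model_config()]; each scenario overrides its
#'   switches.
#' @param scenarios List of [scenario_spec()]s with unique labels.
#' @param k Top-k set size for the rank-stability summary (default 6).
#' @return A `sensitivity_grid`: `summary` tibble (one row per scenario,
#'   including the base run, with global totals and `topk_overlap_with_base`)
#'   and the named list of `global_projection`s.
#' @export
run_scenarios <- function(data, base_config = model_config(), scenarios,
                          k = 6) {
  data <- validate_province_table(data)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("scenario labels must be unique", call. = FALSE)
  }
  base_proj <- project_provinces(data, base_config)
  k <- min(k, nrow(base_proj$provinces))

  run_one <- function(sc) {
    for (col in c(sc$area_col, sc$rate_col)) {
      if (!col %in% names(data)) {
        stop(sprintf("scenario '%s' references missing input variant column `%s`",
                     sc$label, col), call. = FALSE)
      }
    }
    d2 <- data
    d2$area_ha <- data[[sc$area_col]]
    d2$deforestation_rate <- data[[sc$rate_col]]
    cfg <- model_config(
      horizon_years = base_config$horizon_years,
      baseline_year = base_config$baseline_year,
      emission_release_rate = base_config$emission_release_rate,
      co2_per_c = base_config$co2_per_c,
      include_sequestration = base_config$include_sequestration,
      erosion_ef_multiplier = sc$erosion_ef_multiplier,
      include_climatic_driver = sc$include_climatic,
      soc_depth = sc$soc_depth
    )
    project_provinces(d2, cfg)
  }

  projections <- c(list(base = base_proj),
                   stats::setNames(lapply(scenarios, run_one), labels))
  summary <- purrr::map_dfr(names(projections), function(lab) {
    p <- projections[[lab]]
    tibble::tibble(
      label = lab,
      global_emissions_tg = p$global_emissions_tg,
      global_total_tg = p$global_total_tg,
      topk_overlap_with_base = rank_overlap(p, base_proj, k)
    )
  })
  structure(list(summary = summary, projections = projections, k = k),
            class = "sensitivity_grid")
}

#' Overlap of the top-k hotspot sets of two projections
#'
#' @param proj_a,proj_b `global_projection`s over comparable provinces.
#' @param k Set size.
#' @return Integer: size of the intersection of the two top-k province sets.
#' @export
rank_overlap <- function(proj_a, proj_b, k) {
  stopifnot(inherits(proj_a, "global_projection"),
            inherits(proj_b, "global_projection"))
  top <- function(p) utils::head(p$provinces$province_id, k)
  length(intersect(top(proj_a), top(proj_b)))
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d scenario(s), rank stability on top-%d\n",
              nrow(x$summary) - 1, x$k))
  print(x$summary)
  invisible(x)
}

# Province total (Tg CO2eq, emissions + foregone sequestration when the
# config includes it) with optional multiplicative overrides, used by the
# finite-difference derivatives.
province_total_tg <- function(row, config, d_scale = 1, r_scale = 1) {
  row$deforestation_rate <- row$deforestation_rate * d_scale
  cfg <- config
  cfg$emission_release_rate <- config$emission_release_rate * r_scale
  totals <- province_totals_c(row, cfg)
  to_co2eq(totals$emitted + totals$foregone, config$co2_per_c)
}

#' Parameter derivatives of cumulative emissions
#'
#' Sensitivity of one province's projected total (Tg CO2eq at the horizon,
#' including foregone sequestration when configured) to each model
#' parameter. Parameters in which the model is linear (`A1`, `c_max`, the
#' emission factors `f_i`, `s`) get exact analytic derivatives
#' (`dL/dtheta = L_component/theta`); the deforestation rate `d` and the
#' release rate `r` use a central finite difference with a relative step of
#' 1e-4, which handles the orders-of-magnitude spread in parameter scales.
#' Elasticities `theta * dL/dtheta / L` are dimensionless; they are
#' undefined (NA, flagged) when the total is zero.
#'
#' For `r`, when all five per-driver release rates are equal the derivative
#' is with respect to that common scalar rate; otherwise it is with respect
#' to a common multiplier applied to all five rates.
#'
#' @param data Validated province table.
#' @param config A [model_config()].
#' @param parameters Which parameters to differentiate; default all of
#'   `A1`, `c_max`, `d`, `r`, `s` and the five `f_<driver>`s.
#' @return A `sensitivity_report` tibble: `province_id`, `parameter`,
#'   `value`, `derivative_tg_per_unit`, `elasticity`, `method`,
#'   `elasticity_defined`.
#' @export
sensitivity_derivative <- function(data, config = model_config(),
                                   parameters = c("A1", "c_max", "d", "r", "s",
                                                  paste0("f_", mangrove_drivers()))) {
  data <- validate_province_table(data)
  drivers <- mangrove_drivers()
  allowed <- c("A1", "c_max", "d", "r", "s", paste0("f_", drivers))
  bad <- setdiff(parameters, allowed)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  h <- 1e-4

  one_province <- function(row) {
    totals <- province_totals_c(row, config)
    L_em <- to_co2eq(totals$emitted, config$co2_per_c)
    L_seq <- to_co2eq(totals$foregone, config$co2_per_c)
    L <- L_em + L_seq
    L_by_driver <- to_co2eq(totals$emitted_by_driver, config$co2_per_c)
    soc <- if (config$soc_depth == "2m") row$soc2m_mgc_ha else row$soc1m_mgc_ha
    c_max <- soc + row$abc_mgc_ha
    r <- config$emission_release_rate
    r_equal <- diff(range(r)) < 1e-12

    one <- function(par) {
      if (par == "A1") {
        theta <- row$area_ha
        deriv <- if (theta > 0) L / theta else 0
        method <- "analytic"
      } else if (par == "c_max") {
        theta <- c_max
        deriv <- if (theta > 0) L_em / theta else 0
        method <- "analytic"
      } else if (par == "s") {
        theta <- row$seq_rate_mgc_ha_yr
        deriv <- if (config$include_sequestration) {
          if (theta > 0) L_seq / theta else {
            to_co2eq(foregone_sequestration(row$area_ha, row$deforestation_rate,
                                            1, config$horizon_years),
                     config$co2_per_c)
          }
        } else 0
        method <- "analytic"
      } else if (startsWith(par, "f_")) {
        dr <- sub("^f_", "", par)
        theta <- unname(unlist(row[[paste0("ef_", dr)]]))
        if (dr == "erosion") theta <- min(1, theta * config$erosion_ef_multiplier)
        deriv <- if (theta > 0) {
          L_by_driver[dr] / theta
        } else {
          share <- unname(unlist(row[[paste0("share_", dr)]]))
          if (dr == "climatic" && !config$include_climatic_driver) share <- 0
          to_co2eq(cumulative_emissions(row$area_ha, row$deforestation_rate,
                                        c_max * share, r[dr],
                                        config$horizon_years),
                   config$co2_per_c)
        }
        deriv <- unname(deriv)
        method <- "analytic"
      } else if (par == "d") {
        theta <- row$deforestation_rate
        if (theta <= 0) {
          stop("derivative with respect to `d` requires a positive deforestation rate",
               call. = FALSE)
        }
        deriv <- (province_total_tg(row, config, d_scale = 1 + h) -
                    province_total_tg(row, config, d_scale = 1 - h)) /
          (2 * h * theta)
        method <- "finite_difference"
      } else { # r
        theta <- if (r_equal) unname(r[1]) else 1
        deriv <- (province_total_tg(row, config, r_scale = 1 + h) -
                    province_total_tg(row, config, r_scale = 1 - h)) /
          (2 * h * theta)
        method <- "finite_difference"
      }
      defined <- L > 0
      tibble::tibble(
        province_id = row$province_id,
        parameter = par,
        value = theta,
        derivative_tg_per_unit = deriv,
        elasticity = if (defined) theta * deriv / L else NA_real_,
        method = method,
        elasticity_defined = defined
      )
    }
    purrr::map_dfr(parameters, one)
  }

  out <- purrr::map_dfr(seq_len(nrow(data)), function(i) one_province(data[i, ]))
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Write per-scenario totals and the derivative table
#'
#' @param grid A `sensitivity_grid` from [run_scenarios()].
#' @param report A `sensitivity_report` from [sensitivity_derivative()], or
#'   `NULL` to skip.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_sensitivity_csv <- function(grid, report = NULL, dir) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "scenario_totals.csv")
  summary <- dplyr::mutate(grid$summary,
                           dplyr::across(dplyr::ends_with("_tg"), \(x) round(x, 1)))
  readr::write_csv(summary, paths)
  if (!is.null(report)) {
    p2 <- file.path(dir, "derivatives.csv")
    readr::write_csv(tibble::as_tibble(report), p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
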