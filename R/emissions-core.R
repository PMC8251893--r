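#' Model configuration
#'
#' Bundles every tunable of the emission projection: the horizon, the
#' per-driver emission release rates, the CO2:C mass ratio, and the scenario
#' switches used in the sensitivity grid.
#'
#' Defaults encode the business-as-usual projection: a 2010 baseline run for
#' 90 years (to 2100), carbon from each deforested cohort released
#' exponentially with a 10-year half-life (`r = log(2)/10` per year for every
#' driver), CO2:C fixed at the molecular-mass ratio 44/12, foregone soil
#' sequestration included, and all five loss drivers active.
#'
#' @param horizon_years Projection horizon in years (> 0).
#' @param baseline_year Calendar year of the initial extent.
#' @param emission_release_rate Release rate r (yr^-1) of carbon from
#'   deforested area; a single value or a named 5-vector, one per driver.
#' @param co2_per_c Mass of CO2 per mass of C (default 44/12).
#' @param include_sequestration Include foregone soil-carbon sequestration
#'   in province totals?
#' @param erosion_ef_multiplier Multiplier on the erosion emission factor
#'   (0.5 gives the low-erosion scenario).
#' @param include_climatic_driver If `FALSE`, loss from extreme climatic
#'   events is removed (its share is zeroed without renormalising the other
#'   drivers' shares).
#' @param soc_depth Soil depth used for the carbon stock: `"2m"` (default)
#'   or `"1m"`.
#' @return A `model_config` list.
#' @examples
#' model_config()
#' model_config(erosion_ef_multiplier = 0.5, include_climatic_driver = FALSE)
#' @export
model_config <- function(horizon_years = 90,
                         baseline_year = 2010,
                         emission_release_rate = log(2) / 10,
                         co2_per_c = 44 / 12,
                         include_sequestration = TRUE,
                         erosion_ef_multiplier = 1,
                         include_climatic_driver = TRUE,
                         soc_depth = c("2m", "1m")) {
  soc_depth <- match.arg(soc_depth)
  r <- per_driver(emission_release_rate, "emission_release_rate")
  stopifnot(
    "`horizon_years` must be a single positive number" =
      length(horizon_years) == 1 && is.finite(horizon_years) && horizon_years > 0,
    "`emission_release_rate` must be positive" = all(r > 0),
    "`co2_per_c` must be a single positive number" =
      length(co2_per_c) == 1 && is.finite(co2_per_c) && co2_per_c > 0,
    "`erosion_ef_multiplier` must be a single non-negative number" =
      length(erosion_ef_multiplier) == 1 && is.finite(erosion_ef_multiplier) &&
        erosion_ef_multiplier >= 0
  )
  structure(
    list(
      horizon_years = horizon_years,
      baseline_year = baseline_year,
      emission_release_rate = r,
      co2_per_c = co2_per_c,
      include_sequestration = isTRUE(include_sequestration),
      erosion_ef_multiplier = erosion_ef_multiplier,
      include_climatic_driver = isTRUE(include_climatic_driver),
      soc_depth = soc_depth
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("Mangrove emission model configuration\n")
  cat(sprintf("  horizon: %g yr from %d; CO2:C = %.4f; SOC depth %s\n",
              x$horizon_years, x$baseline_year, x$co2_per_c, x$soc_depth))
  cat(sprintf("  release rates r (yr^-1): %s\n",
              paste(sprintf("%s=%.4g", names(x$emission_release_rate),
                            x$emission_release_rate), collapse = ", ")))
  cat(sprintf("  sequestration %s; erosion EF x %g; climatic driver %s\n",
              if (x$include_sequestration) "on" else "off",
              x$erosion_ef_multiplier,
              if (x$include_climatic_driver) "on" else "off"))
  invisible(x)
}

#' Remaining mangrove area under constant proportional loss
#'
#' Solves dA/dt = -A d: area decays exponentially from the initial extent,
#' `A(t) = A1 exp(-d t)`.
#'
#' @param A1 Initial area (ha).
#' @param d Deforestation rate (fraction yr^-1).
#' @param t Time since baseline (yr). All arguments vectorised.
#' @return Remaining area (ha).
#' @export
area_remaining <- function(A1, d, t) {
  if (any(A1 < 0) || any(d < 0) || any(t < 0)) {
    stop("`A1`, `d` and `t` must be non-negative", call. = FALSE)
  }
  A1 * exp(-d * t)
}

#' Driver-weighted effective carbon stock
#'
#' The carbon actually at risk per hectare once the mix of land uses and
#' their emission factors is accounted for:
#' `c = c_max * sum_i f_i p_i`, with per-driver addends
#' `c_i = c_max f_i p_i` retained for attribution.
#'
#' @param c_max Maximum labile carbon per hectare (TECS, Mg C ha^-1).
#' @param factors 5-vector of emission factors in [0, 1], canonical driver
#'   order.
#' @param shares 5-vector of proportional driver loss shares; must sum to 1
#'   (or be all zero for a province with no loss).
#' @return List with `total` (Mg C ha^-1) and the named per-driver
#'   `addends`.
#' @export
effective_carbon <- function(c_max, factors, shares) {
  factors <- per_driver(factors, "factors")
  shares <- per_driver(shares, "shares")
  if (any(factors < 0 | factors > 1)) {
    stop("`factors` must lie in [0, 1]", call. = FALSE)
  }
  ssum <- sum(shares)
  if (any(shares < 0) || (abs(ssum - 1) > 1e-9 && ssum != 0)) {
    stop("`shares` must be non-negative and sum to 1 (or all be zero)",
         call. = FALSE)
  }
  addends <- c_max * factors * shares
  list(total = sum(addends), addends = addends)
}

# Emitted fraction of the at-risk stock by time T for one cohort stream:
# K(d, r, T) = integral_0^T d e^{-d y} (1 - e^{-r (T - y)}) dy
#            = (1 - e^{-dT}) - d (e^{-dT} - e^{-rT}) / (r - d),
# with the analytic limit (1 - e^{-dT}) - d T e^{-dT} when r ~ d and a
# short-circuit 0 when d = 0. Vectorised over all three arguments.
emitted_fraction <- function(d, r, T) {
  n <- max(length(d), length(r), length(T))
  d <- rep_len(d, n); r <- rep_len(r, n); T <- rep_len(T, n)
  out <- numeric(n)
  pos <- d > 0
  near <- pos & abs(r - d) < 1e-9 * pmax(r, d)
  gen <- pos & !near
  if (any(gen)) {
    out[gen] <- -expm1(-d[gen] * T[gen]) -
      d[gen] * (exp(-d[gen] * T[gen]) - exp(-r[gen] * T[gen])) / (r[gen] - d[gen])
  }
  if (any(near)) {
    out[near] <- -expm1(-d[near] * T[near]) -
      d[near] * T[near] * exp(-d[near] * T[near])
  }
  out
}

#' Cumulative carbon emissions from deforestation cohorts
#'
#' Each year's deforested cohort (flux `A1 d e^{-d y}` at year y) carries
#' labile carbon `c` per hectare and releases it exponentially at rate `r`
#' thereafter, so cumulative emissions by the horizon T are the convolution
#' \deqn{E(T) = \int_0^T A_1 d e^{-d y} c \,(1 - e^{-r (T - y)})\, dy,}
#' evaluated in closed form (with an analytic branch at the r = d
#' degeneracy and a zero short-circuit when d = 0). As T grows, E
#' approaches `A1 * c`: everything eventually deforested emits its labile
#' stock.
#'
#' @param A1 Initial area (ha).
#' @param d Deforestation rate (yr^-1).
#' @param c Labile carbon emitted per hectare (Mg C ha^-1).
#' @param r Emission release rate after loss (yr^-1, > 0).
#' @param T Horizon (yr). All arguments vectorised.
#' @return Cumulative emitted carbon by time T (Mg C).
#' @examples
#' cumulative_emissions(1, d = 0.01, c = 1, r = log(2) / 10, T = 90)
#' @export
cumulative_emissions <- function(A1, d, c, r, T) {
  if (any(A1 < 0) || any(d < 0) || any(c < 0) || any(T < 0)) {
    stop("`A1`, `d`, `c` and `T` must be non-negative", call. = FALSE)
  }
  if (any(r <= 0)) {
    stop("`r` must be positive: released carbon must eventually be emitted",
         call. = FALSE)
  }
  A1 * c * emitted_fraction(d, r, T)
}

#' Foregone soil-carbon sequestration
#'
#' Carbon the deforested area would have sequestered under the no-loss
#' counterfactual: the intact extent sequesters `s A1` per year, the
#' deforested run only `s A(t)`, so the foregone amount by T is
#' \deqn{S(T) = s A_1 T - s A_1 (1 - e^{-d T})/d,}
#' which tends to 0 as d tends to 0 (the counterfactual equals the actual
#' trajectory when nothing is lost).
#'
#' @param A1 Initial area (ha).
#' @param d Deforestation rate (yr^-1).
#' @param s Soil sequestration rate (Mg C ha^-1 yr^-1); global mean 1.5.
#' @param T Horizon (yr). All arguments vectorised.
#' @return Foregone sequestered carbon by time T (Mg C).
#' @export
foregone_sequestration <- function(A1, d, s, T) {
  if (any(A1 < 0) || any(d < 0) || any(s < 0) || any(T < 0)) {
    stop("all arguments must be non-negative", call. = FALSE)
  }
  n <- max(length(A1), length(d), length(s), length(T))
  A1 <- rep_len(A1, n); d <- rep_len(d, n)
  s <- rep_len(s, n); T <- rep_len(T, n)
  out <- numeric(n)
  pos <- d > 0
  # -expm1(-dT)/d is the exact lost-area-years integral; stable for small d
  out[pos] <- s[pos] * A1[pos] * (T[pos] + expm1(-d[pos] * T[pos]) / d[pos])
  pmax(out, 0)
}

#' Convert a carbon mass to CO2 equivalents in teragrams
#'
#' @param mass_c Carbon mass (Mg C), non-negative.
#' @param co2_per_c CO2:C mass ratio (default 44/12).
#' @return CO2 equivalents (Tg).
#' @export
to_co2eq <- function(mass_c, co2_per_c = 44 / 12) {
  if (any(mass_c < 0)) stop("`mass_c` must be non-negative", call. = FALSE)
  mass_c * co2_per_c / 1e6
}

# Per-driver effective carbon addends (Mg C / ha) for one province row,
# after applying the scenario switches: the erosion emission factor is
# scaled by the configured multiplier and the climatic share is zeroed
# (without renormalising) when that driver is excluded.
effective_addends <- function(row, config) {
  drivers <- mangrove_drivers()
  shares <- unlist(row[paste0("share_", drivers)], use.names = FALSE)
  factors <- unlist(row[paste0("ef_", drivers)], use.names = FALSE)
  names(shares) <- names(factors) <- drivers
  factors["erosion"] <- min(1, factors["erosion"] * config$erosion_ef_multiplier)
  if (!config$include_climatic_driver) shares["climatic"] <- 0
  soc <- if (config$soc_depth == "2m") row$soc2m_mgc_ha else row$soc1m_mgc_ha
  c_max <- soc + row$abc_mgc_ha
  c_max * factors * shares
}

# Province-level closed-form totals (Mg C) at horizon T under a config.
# Returns emitted carbon per driver, their sum, and foregone sequestration.
province_totals_c <- function(row, config) {
  addends <- effective_addends(row, config)
  r <- config$emission_release_rate
  T <- config$horizon_years
  emitted <- cumulative_emissions(row$area_ha, row$deforestation_rate,
                                  addends, r, T)
  seq_c <- if (config$include_sequestration) {
    foregone_sequestration(row$area_ha, row$deforestation_rate,
                           row$seq_rate_mgc_ha_yr, T)
  } else 0
  list(emitted_by_driver = emitted, emitted = sum(emitted), foregone = seq_c)
}

#' Emission trajectory for each province
#'
#' Evaluates the closed forms on a uniform time grid: remaining area,
#' cumulative emitted carbon (summed over the five drivers, each with its
#' own release rate and effective-carbon addend), cumulative foregone
#' sequestration, and their CO2-equivalent total.
#'
#' @param data Validated province table.
#' @param config A [model_config()].
#' @param n_steps Number of grid intervals (default: one per year).
#' @return A `mangrove_trajectory` tibble with columns `province_id`,
#'   `time_yr`, `year`, `area_ha`, `cum_emitted_c_mg`,
#'   `cum_foregone_seq_c_mg`, `cum_co2eq_tg`. Cumulative series start at 0
#'   and are non-decreasing; the final grid point equals the closed-form
#'   horizon values.
#' @export
project_trajectory <- function(data, config = model_config(), n_steps = NULL) {
  data <- validate_province_table(data)
  if (is.null(n_steps)) n_steps <- as.integer(ceiling(config$horizon_years))
  stopifnot("`n_steps` must be a positive whole number" =
              length(n_steps) == 1 && n_steps >= 1)
  times <- seq(0, config$horizon_years, length.out = n_steps + 1)
  out <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    addends <- effective_addends(row, config)
    emitted <- rowSums(vapply(
      mangrove_drivers(),
      function(dr) cumulative_emissions(row$area_ha, row$deforestation_rate,
                                        addends[dr],
                                        config$emission_release_rate[dr],
                                        times),
      numeric(length(times))
    ))
    seq_c <- if (config$include_sequestration) {
      foregone_sequestration(row$area_ha, row$deforestation_rate,
                             row$seq_rate_mgc_ha_yr, times)
    } else rep(0, length(times))
    tibble::tibble(
      province_id = row$province_id,
      time_yr = times,
      year = config$baseline_year + times,
      area_ha = area_remaining(row$area_ha, row$deforestation_rate, times),
      cum_emitted_c_mg = emitted,
      cum_foregone_seq_c_mg = seq_c,
      cum_co2eq_tg = to_co2eq(emitted + seq_c, config$co2_per_c)
    )
  })
  class(out) <- c("mangrove_trajectory", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.mangrove_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("area_ha", "cum_co2eq_tg"),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(long$series, c("area_ha", "cum_co2eq_tg"),
                        c("Remaining area (ha)",
                          "Cumulative emissions (Tg CO2eq)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                     colour = .data$province_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Year", y = NULL, colour = "Province")
}
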