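#' Decompose projected emissions by proximate driver
#'
#' Attributes each province's projected emissions to the five proximate
#' drivers of loss. Future deforestation from each driver is assumed
#' proportional to its historical share, so the per-driver effective-carbon
#' addend `c_i = c_max f_i p_i` feeds the cohort closed form directly, and
#' per-driver emissions sum exactly to the aggregate run (the model is
#' linear in c).
#'
#' @param data Validated province table.
#' @param config A [model_config()].
#' @return A `driver_decomposition` tibble, one row per province x driver:
#'   `annual_loss_ha_yr` (the present-day loss flux `A1 d p_i`),
#'   `co2eq_tg` (cumulative emissions at the horizon attributed to the
#'   driver), and the province's `total_co2eq_tg`.
#' @examples
#' fx <- fixture_table1()
#' decompose_drivers(fx$provinces)
#' @export
decompose_drivers <- function(data, config = model_config()) {
  data <- validate_province_table(data)
  drivers <- mangrove_drivers()
  out <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    shares <- unlist(row[paste0("share_", drivers)], use.names = FALSE)
    names(shares) <- drivers
    if (!config$include_climatic_driver) shares["climatic"] <- 0
    totals <- province_totals_c(row, config)
    co2 <- to_co2eq(totals$emitted_by_driver, config$co2_per_c)
    tibble::tibble(
      province_id = row$province_id,
      name = row$name,
      driver = drivers,
      annual_loss_ha_yr = unname(row$area_ha * row$deforestation_rate * shares),
      co2eq_tg = unname(co2),
      total_co2eq_tg = sum(co2)
    )
  })
  class(out) <- c("driver_decomposition", class(out))
  out
}

#' Per-driver share of a province's emissions
#'
#' @param decomp A `driver_decomposition` from [decompose_drivers()].
#' @param driver Optional driver identifier to filter to.
#' @return Tibble with `province_id`, `driver` and `share_pct`, the driver's
#'   percentage of the province total rounded to the nearest integer.
#'   Provinces with zero total emissions have no defined shares and raise an
#'   error.
#' @examples
#' fx <- fixture_table1()
#' driver_share(decompose_drivers(fx$provinces), "erosion")
#' @export
driver_share <- function(decomp, driver = NULL) {
  stopifnot(inherits(decomp, "driver_decomposition"))
  zero <- unique(decomp$province_id[decomp$total_co2eq_tg <= 0])
  if (length(zero) > 0) {
    stop("driver shares are undefined for province(s) with zero total emissions: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::transmute(
    tibble::as_tibble(decomp),
    province_id = .data$province_id,
    driver = .data$driver,
    share_pct = round(100 * .data$co2eq_tg / .data$total_co2eq_tg)
  )
  if (!is.null(driver)) {
    stopifnot(driver %in% mangrove_drivers())
    out <- out[out$driver == driver, ]
  }
  out
}

#' Wide per-province decomposition report
#'
#' One row per province with paired annual-loss (ha yr^-1) and cumulative
#' emission (Tg CO2eq) columns per driver, emissions rounded to 1 decimal
#' and annual losses to whole hectares — the precision used in reports.
#'
#' @param decomp A `driver_decomposition`.
#' @return A wide tibble.
#' @export
decomposition_table <- function(decomp) {
  stopifnot(inherits(decomp, "driver_decomposition"))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(decomp),
    id_cols = c("province_id", "name", "total_co2eq_tg"),
    names_from = "driver",
    values_from = c("annual_loss_ha_yr", "co2eq_tg"),
    names_glue = "{driver}_{.value}"
  )
  num <- setdiff(names(wide), c("province_id", "name"))
  loss_cols <- grep("annual_loss", num, value = TRUE)
  tg_cols <- setdiff(num, loss_cols)
  wide[loss_cols] <- lapply(wide[loss_cols], round)
  wide[tg_cols] <- lapply(wide[tg_cols], round, digits = 1)
  dplyr::relocate(wide, "total_co2eq_tg", .after = dplyr::last_col())
}

#' Write the decomposition report CSV
#'
#' @param decomp A `driver_decomposition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decomposition_csv <- function(decomp, path) {
  readr::write_csv(decomposition_table(decomp), path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.driver_decomposition <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$driver <- factor(d$driver, mangrove_drivers(),
                     unname(driver_labels()))
  d$name <- stats::reorder(d$name, -d$total_co2eq_tg)
  ggplot2::ggplot(d, ggplot2::aes(.data$name, .data$co2eq_tg,
                                  fill = .data$driver)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Cumulative emissions (Tg CO2eq)",
                  fill = "Driver") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
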