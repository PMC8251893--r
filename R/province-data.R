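#' @importFrom rlang .data
NULL

# Column contract for a province table. Rates are decimal fractions
# (0.0055, not 0.55%); stocks in Mg C per hectare; areas in hectares.
province_columns <- function() {
  drivers <- mangrove_drivers()
  c(
    "province_id", "name", "area_ha", "deforestation_rate",
    "soc1m_mgc_ha", "soc2m_mgc_ha", "abc_mgc_ha",
    paste0("share_", drivers),
    paste0("ef_", drivers),
    paste0("efconf_", drivers),
    "seq_rate_mgc_ha_yr"
  )
}

#' Convert aboveground biomass to aboveground carbon
#'
#' Applies the standard biomass-to-carbon conversion factor of 0.48 used for
#' mangrove aboveground pools.
#'
#' @param biomass Aboveground biomass (Mg ha^-1); vectorised, must be
#'   non-negative.
#' @return Aboveground carbon (Mg C ha^-1).
#' @examples
#' abc_from_biomass(210.8) # ~101.2 Mg C / ha
#' @export
abc_from_biomass <- function(biomass) {
  if (!is.numeric(biomass) || anyNA(biomass)) {
    stop("`biomass` must be numeric with no missing values", call. = FALSE)
  }
  if (any(biomass < 0)) {
    stop("`biomass` must be non-negative", call. = FALSE)
  }
  biomass * 0.48
}

#' Total ecosystem carbon stock per province
#'
#' Adds a `tecs_mgc_ha` column: soil organic carbon at the requested depth
#' plus aboveground carbon. The default depth is 2 m; the 1 m option exists
#' for the sensitivity grid. Requesting 2 m when `soc2m_mgc_ha` is missing is
#' an error — there is no silent fallback to the 1 m stock.
#'
#' @param data Province table (data frame with at least the SOC/ABC columns).
#' @param soc_depth Soil depth for the SOC term, `"2m"` (default) or `"1m"`.
#' @return `data` as a tibble with a `tecs_mgc_ha` column.
#' @examples
#' compute_tecs(tibble::tibble(soc1m_mgc_ha = 331.3, soc2m_mgc_ha = 646.7,
#'                             abc_mgc_ha = 101.2))
#' @export
compute_tecs <- function(data, soc_depth = c("2m", "1m")) {
  soc_depth <- match.arg(soc_depth)
  soc_col <- if (soc_depth == "2m") "soc2m_mgc_ha" else "soc1m_mgc_ha"
  for (col in c(soc_col, "abc_mgc_ha")) {
    if (!col %in% names(data)) {
      stop(sprintf("column `%s` is required for TECS at %s", col, soc_depth),
           call. = FALSE)
    }
  }
  soc <- data[[soc_col]]
  if (anyNA(soc)) {
    stop(sprintf("`%s` has missing values; cannot compute TECS at %s depth",
                 soc_col, soc_depth), call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                tecs_mgc_ha = soc + .data$abc_mgc_ha)
}

#' Validate modelled carbon stocks against field measurements
#'
#' Ordinary least-squares regression of field-measured total ecosystem carbon
#' stocks on model-derived stocks, the standard accuracy check before the
#' modelled stocks are used in a projection. Field stocks are the response
#' and modelled stocks the predictor, so the fit answers "how well does the
#' model predict the truth".
#'
#' @param data Data frame holding both stock columns.
#' @param modelled,field Column names (tidy-eval) of modelled and field
#'   stocks (Mg C ha^-1). Pairs must be complete and there must be at least
#'   two of them.
#' @return A `stock_validation` object with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying [stats::lm] fit. Has
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
validate_stocks <- function(data, modelled = "tecs_mgc_ha",
                            field = "tecs_field_mgc_ha") {
  modelled <- rlang::as_name(rlang::enquo(modelled))
  field <- rlang::as_name(rlang::enquo(field))
  for (col in c(modelled, field)) {
    if (!col %in% names(data)) {
      stop(sprintf("column `%s` not found in `data`", col), call. = FALSE)
    }
  }
  x <- data[[modelled]]
  y <- data[[field]]
  if (anyNA(x) || anyNA(y)) {
    stop("modelled/field stock pairs must be complete (no missing values)",
         call. = FALSE)
  }
  if (length(x) < 2) {
    stop("at least two modelled/field pairs are required", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      n = length(x),
      fit = fit,
      data = tibble::tibble(modelled = x, field = y)
    ),
    class = "stock_validation"
  )
}

#' @export
print.stock_validation <- function(x, ...) {
  cat("Field vs. modelled carbon stock regression\n")
  cat(sprintf("  n = %d, field = %.3f * modelled + %.2f, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.stock_validation <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @exportS3Method generics::glance
glance.stock_validation <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 slope = x$slope, intercept = x$intercept)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.stock_validation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$modelled, .data$field)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Modelled TECS (Mg C / ha)", y = "Field TECS (Mg C / ha)",
      title = sprintf("Field = %.2f x Modelled %+.1f  (R² = %.2f, n = %d)",
                      object$slope, object$intercept, object$r_squared,
                      object$n)
    )
}

#' Validate a province table
#'
#' Checks every record invariant: complete columns, non-negative finite
#' rates and stocks, `soc2m >= soc1m >= 0`, driver shares on the unit
#' simplex (or all zero when the deforestation rate is zero), emission
#' factors in [0, 1] with confidence levels in {1, 2, 3}. Errors name the
#' offending row(s) and province(s).
#'
#' @param data Province table.
#' @return `data` as a tibble, invisibly unchanged, for piping.
#' @export
validate_province_table <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(province_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("province table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) return(data)

  fail <- function(rows, msg) {
    ids <- data$province_id[rows]
    stop(sprintf("invalid province table: %s [row %s: %s]", msg,
                 paste(rows, collapse = ", "),
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  drivers <- mangrove_drivers()
  num_cols <- setdiff(province_columns(), c("province_id", "name"))
  for (col in num_cols) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0) fail(bad, sprintf("`%s` must be finite", col))
  }
  nonneg <- c("area_ha", "deforestation_rate", "soc1m_mgc_ha", "soc2m_mgc_ha",
              "abc_mgc_ha", "seq_rate_mgc_ha_yr")
  for (col in nonneg) {
    bad <- which(data[[col]] < 0)
    if (length(bad) > 0) fail(bad, sprintf("`%s` must be non-negative", col))
  }
  bad <- which(data$soc2m_mgc_ha < data$soc1m_mgc_ha)
  if (length(bad) > 0) fail(bad, "soil carbon to 2 m must be >= soil carbon to 1 m")

  shares <- as.matrix(data[paste0("share_", drivers)])
  bad <- which(shares < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) fail(unique(bad[, 1]), "driver shares must be non-negative")
  ssum <- rowSums(shares)
  ok <- abs(ssum - 1) <= 1e-9 | (ssum == 0 & data$deforestation_rate == 0)
  if (any(!ok)) {
    fail(which(!ok),
         "driver shares must sum to 1 (or all be zero when the deforestation rate is zero)")
  }
  efs <- as.matrix(data[paste0("ef_", drivers)])
  bad <- which(efs < 0 | efs > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) fail(unique(bad[, 1]), "emission factors must lie in [0, 1]")
  conf <- as.matrix(data[paste0("efconf_", drivers)])
  bad <- which(!conf %in% c(1, 2, 3), arr.ind = TRUE)
  if (length(bad) > 0) {
    fail(unique(arrayInd(bad, dim(conf))[, 1]),
         "emission-factor confidence levels must be 1, 2 or 3")
  }
  data
}

#' Read a province table from CSV
#'
#' Reads the package's province CSV dialect (UTF-8, rates as decimal
#' fractions) and validates every record; validation errors carry row
#' numbers and province identifiers.
#'
#' @param path Path to the CSV file.
#' @return A validated province tibble.
#' @seealso [write_province_table()], [validate_province_table()]
#' @export
read_province_table <- function(path) {
  cols <- readr::cols(
    province_id = readr::col_character(),
    name = readr::col_character(),
    .default = readr::col_double()
  )
  data <- readr::read_csv(path, col_types = cols, progress = FALSE)
  unknown <- setdiff(names(data), province_columns())
  if (length(unknown) > 0) {
    stop("unknown column(s) in province table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  validate_province_table(data)
}

#' Write a province table to CSV
#'
#' Writes in the same dialect [read_province_table()] reads, so a
#' write/read cycle round-trips records exactly (numbers are serialised at
#' full double precision).
#'
#' @param data Province table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_province_table <- function(data, path) {
  data <- validate_province_table(data)
  readr::write_csv(data[province_columns()], path)
  invisible(path)
}
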