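#' Project all provinces to the horizon and rank hotspots
#'
#' Runs the closed-form model for every province, aggregates the global
#' totals (always both with and without foregone sequestration), and ranks
#' provinces by their emissions. Ties are broken by province identifier so
#' the ranking is reproducible.
#'
#' @param data Validated province table with at least one row.
#' @param config A [model_config()].
#' @return A `global_projection` object: `provinces` (ranked tibble with
#'   `emissions_tg`, `foregone_seq_tg`, `total_tg`, `rank`),
#'   `global_emissions_tg`, `global_foregone_seq_tg`, `global_total_tg`
#'   and the config. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @examples
#' provs <- generate_provinces(n = 10, seed = 42)
#' project_provinces(provs)
#' @export
project_provinces <- function(data, config = model_config()) {
  data <- validate_province_table(data)
  if (nrow(data) == 0) {
    stop("at least one province is required", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    totals <- province_totals_c(row, config)
    tibble::tibble(
      province_id = row$province_id,
      name = row$name,
      area_ha = row$area_ha,
      deforestation_rate = row$deforestation_rate,
      emissions_tg = to_co2eq(totals$emitted, config$co2_per_c),
      foregone_seq_tg = to_co2eq(totals$foregone, config$co2_per_c)
    )
  })
  rows$total_tg <- rows$emissions_tg + rows$foregone_seq_tg
  rows <- dplyr::arrange(rows, dplyr::desc(.data$emissions_tg),
                         .data$province_id)
  rows$rank <- seq_len(nrow(rows))
  structure(
    list(
      provinces = rows,
      global_emissions_tg = sum(rows$emissions_tg),
      global_foregone_seq_tg = sum(rows$foregone_seq_tg),
      global_total_tg = sum(rows$total_tg),
      config = config
    ),
    class = "global_projection"
  )
}

#' @export
print.global_projection <- function(x, ...) {
  cat(sprintf(
    "Global mangrove emission projection (%d provinces, %g-yr horizon)\n",
    nrow(x$provinces), x$config$horizon_years))
  cat(sprintf("  emissions:            %8.1f Tg CO2eq\n", x$global_emissions_tg))
  cat(sprintf("  foregone seq.:        %8.1f Tg CO2eq\n", x$global_foregone_seq_tg))
  cat(sprintf("  emissions + foregone: %8.1f Tg CO2eq\n", x$global_total_tg))
  top <- utils::head(x$provinces, 6)
  cat("  top provinces (Tg CO2eq emissions):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("   %2d. %-28s %8.1f\n", top$rank[i], top$name[i],
                top$emissions_tg[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.global_projection <- function(x, ...) {
  x$provinces
}

#' @exportS3Method generics::glance
glance.global_projection <- function(x, ...) {
  tibble::tibble(
    n_provinces = nrow(x$provinces),
    global_emissions_tg = x$global_emissions_tg,
    global_foregone_seq_tg = x$global_foregone_seq_tg,
    global_total_tg = x$global_total_tg,
    horizon_years = x$config$horizon_years
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.global_projection <- function(object, k = 10, ...) {
  top <- utils::head(object$provinces, k)
  top$name <- stats::reorder(top$name, top$emissions_tg)
  ggplot2::ggplot(top, ggplot2::aes(.data$emissions_tg, .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Cumulative emissions by horizon (Tg CO2eq)", y = NULL)
}

#' Emission concentration in the top-k provinces
#'
#' Share of global emissions contributed by the k highest-emitting
#' provinces, as a percentage rounded to the nearest integer. By default the
#' denominator is the projection's own global total; an externally reported
#' global total (covering provinces not in `projection`) can be supplied
#' instead.
#'
#' @param projection A `global_projection`.
#' @param k Number of top provinces, `1 <= k <= n`.
#' @param global_total_tg Optional global emissions denominator (Tg CO2eq).
#' @return Integer percentage.
#' @export
hotspot_share <- function(projection, k, global_total_tg = NULL) {
  stopifnot(inherits(projection, "global_projection"))
  n <- nrow(projection$provinces)
  if (!(length(k) == 1 && k >= 1 && k <= n)) {
    stop(sprintf("`k` must be between 1 and the number of provinces (%d)", n),
         call. = FALSE)
  }
  denom <- if (is.null(global_total_tg)) {
    projection$global_emissions_tg
  } else {
    global_total_tg
  }
  if (denom <= 0) stop("global total must be positive", call. = FALSE)
  round(100 * sum(utils::head(projection$provinces$emissions_tg, k)) / denom)
}

#' Write the ranked projection and summary report
#'
#' Writes the ranked per-province CSV and a plain-text summary block with
#' the global totals and the top-k concentration share. Numeric rounding
#' follows the reporting conventions (Tg to 1 decimal, shares to integer
#' percent).
#'
#' @param projection A `global_projection`.
#' @param dir Output directory (created if needed).
#' @param k Top-k used in the summary's concentration share.
#' @return Named character vector of the files written, invisibly.
#' @export
write_projection_report <- function(projection, dir, k = 6) {
  stopifnot(inherits(projection, "global_projection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranked <- dplyr::mutate(projection$provinces,
                          dplyr::across(dplyr::ends_with("_tg"), \(x) round(x, 1)))
  ranked_path <- file.path(dir, "projection_ranked.csv")
  readr::write_csv(ranked, ranked_path)
  k <- min(k, nrow(projection$provinces))
  summary_path <- file.path(dir, "summary.txt")
  writeLines(c(
    sprintf("provinces: %d", nrow(projection$provinces)),
    sprintf("horizon_years: %g", projection$config$horizon_years),
    sprintf("global_emissions_tg: %.1f", projection$global_emissions_tg),
    sprintf("global_foregone_seq_tg: %.1f", projection$global_foregone_seq_tg),
    sprintf("global_total_tg: %.1f", projection$global_total_tg),
    sprintf("top%d_share_pct: %d", k, hotspot_share(projection, k)),
    sprintf("top%d_provinces: %s", k,
            paste(utils::head(projection$provinces$province_id, k),
                  collapse = ", "))
  ), summary_path)
  invisible(c(ranked = ranked_path, summary = summary_path))
}
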