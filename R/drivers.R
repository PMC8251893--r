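#' Proximate drivers of mangrove loss
#'
#' The five proximate drivers of mangrove deforestation used throughout the
#' package, in their fixed canonical order: conversion to commodities
#' (agriculture/aquaculture), coastal erosion, clearing, extreme climatic
#' events, and conversion to human settlements. Every 5-vector keyed by
#' driver (loss shares, emission factors, release rates) uses this order.
#'
#' @return A character vector of the five driver identifiers.
#' @examples
#' mangrove_drivers()
#' @export
mangrove_drivers <- function() {
  c("commodities", "erosion", "clearing", "climatic", "settlement")
}

#' Human-readable driver labels
#'
#' @return Named character vector mapping driver identifiers to display labels.
#' @export
driver_labels <- function() {
  c(
    commodities = "Agri/aquaculture",
    erosion     = "Erosion",
    clearing    = "Clearing",
    climatic    = "Extreme climatic events",
    settlement  = "Human settlements"
  )
}

# Expand a scalar or length-5 vector to a named per-driver vector.
# Used for emission release rates and similar per-driver parameters.
per_driver <- function(x, what = "value") {
  drivers <- mangrove_drivers()
  if (length(x) == 1) x <- rep(x, 5)
  if (length(x) != 5) {
    stop(sprintf("`%s` must have length 1 or 5 (one per driver)", what),
         call. = FALSE)
  }
  if (is.null(names(x))) {
    names(x) <- drivers
  } else if (!setequal(names(x), drivers)) {
    stop(sprintf("`%s` names must be the five driver identifiers", what),
         call. = FALSE)
  } else {
    x <- x[drivers]
  }
  x
}
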