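# Power-law action costs with diminishing returns.

#' Power-law cost model
#'
#' The annual cost of managing all threats to a species across an area `R`
#' is `q * R^z`. With `z < 1` the marginal cost per km^2 declines as the
#' managed area grows (economies of scale in threat abatement); typical
#' exponents are 0.2-0.4. `q` converts area to cost and carries the currency
#' units; all costs in the package are unit-agnostic ("cost units/yr").
#'
#' @param q positive multiplier, cost units per km^(2z) per year.
#' @param z exponent in (0, 1].
#' @return A list of class `cost_model`.
#' @export
cost_model <- function(q, z) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0) {
    umb_config_error("q must be a single positive number")
  }
  if (!is.numeric(z) || length(z) != 1L || z <= 0 || z > 1) {
    umb_config_error("z must lie in (0, 1]")
  }
  structure(list(q = as.numeric(q), z = as.numeric(z)), class = "cost_model")
}

#' Annual cost of managing one species' threats across its range
#'
#' @param range_area numeric vector of managed areas in km^2 (the species'
#'   full ranges; partial-range management is not costed).
#' @param model a [cost_model()].
#' @return `q * range_area^z`; 0 where `range_area` is 0.
#' @export
action_cost <- function(range_area, model) {
  if (any(range_area < 0)) umb_config_error("range_area must be >= 0")
  model$q * range_area^model$z
}

#' Total cost of managing a list of species
#'
#' Sums [action_cost()] over the listed species. Running this on a reference
#' priority list yields the assumed budget that constrains an optimized run
#' (see [efficiency_comparison()]).
#'
#' @param ids character vector of species ids.
#' @param records a [species_table()].
#' @param model a [cost_model()].
#' @return Total cost units per year.
#' @export
portfolio_cost <- function(ids, records, model) {
  idx <- match(ids, records$species_id)
  if (anyNA(idx)) {
    umb_lookup_error(sprintf("unknown species id: %s",
                             paste(ids[is.na(idx)], collapse = ", ")))
  }
  sum(action_cost(records$range_area[idx], model))
}
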