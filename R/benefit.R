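# Benefit functions and the accrual ledger.
#
# Two accountings coexist and are deliberately kept apart:
#
# * gross benefit -- each managed species passes its full overlap fraction to
#   every overlapping species sharing a threat, actions credited
#   independently (this is the accounting behind the published three-species
#   worked example, where the koala accumulates 0.15 + 0.15 + 1.00 = 1.30);
# * net (marginal) benefit -- per-(recipient, threat) managed coverage is
#   tracked in a ledger and capped at the recipient's full range, so an area
#   already managed for a threat yields no further benefit. The greedy
#   optimizer scores candidates with this marginal form.
#
# The two differ whenever several managed species cover the same
# (recipient, threat) area; the methods vignette discusses the discrepancy.

sp_index <- function(x, ids) {
  if (is.character(x)) {
    i <- match(x, ids)
    if (anyNA(i)) umb_lookup_error(sprintf("unknown species id: %s",
                                           paste(x[is.na(i)], collapse = ", ")))
    i
  } else as.integer(x)
}

default_weights <- function(records) {
  stats::setNames(rep(1, nrow(records)), records$species_id)
}

resolve_weights <- function(W, records) {
  if (is.null(W)) return(default_weights(records))
  W <- as.numeric(W)
  if (length(W) != nrow(records) || any(!is.finite(W)) || any(W < 0)) {
    umb_validation_error("weights must be nonnegative, finite, one per species")
  }
  stats::setNames(W, records$species_id)
}

#' Shared-threat ratio between two species
#'
#' The fraction of threats shared between a managed (umbrella) species `i`
#' and a recipient species `j`: the number of threats affecting both,
#' divided by the umbrella's threat count (`denominator = "umbrella"`) or
#' the recipient's (`denominator = "recipient"`). Equals 1 when `i == j`.
#'
#' @param i,j species index or id.
#' @param threats binary threat matrix from [threat_matrix()].
#' @param denominator `"umbrella"` or `"recipient"`.
#' @return A number in \[0, 1\].
#' @export
threat_ratio <- function(i, j, threats, denominator = c("umbrella", "recipient")) {
  denominator <- match.arg(denominator)
  ids <- rownames(threats)
  i <- sp_index(i, ids); j <- sp_index(j, ids)
  ni <- sum(threats[i, ]); nj <- sum(threats[j, ])
  if (ni == 0 || nj == 0) {
    umb_validation_error(sprintf(
      "threat ratio undefined: species '%s' has no threats",
      ids[if (ni == 0) i else j]))
  }
  shared <- sum(threats[i, ] * threats[j, ])
  shared / if (denominator == "umbrella") ni else nj
}

#' Gross pairwise benefit of managing one species for another
#'
#' The benefit species `j` receives when all threats to species `i` are
#' managed across `i`'s entire range, with no prior management:
#' `O[i, j] * W[i] * threat_ratio(i, j)`. The self term (`i == j`) equals
#' `W[i]`.
#'
#' @param i managed (umbrella) species index or id.
#' @param j recipient species index or id.
#' @param overlap overlap matrix (`O[i, j]` = fraction of j's range covered
#'   by i's range).
#' @param threats binary threat matrix.
#' @param weights optional per-species weights (default all 1).
#' @param config a [run_config()]; supplies the denominator mode.
#' @return A nonnegative number.
#' @export
pairwise_benefit <- function(i, j, overlap, threats, weights = NULL, config) {
  ids <- rownames(threats)
  i <- sp_index(i, ids); j <- sp_index(j, ids)
  W <- if (is.null(weights)) rep(1, nrow(threats)) else as.numeric(weights)
  overlap[i, j] * W[i] * threat_ratio(i, j, threats, config$benefit_denominator)
}

#' Gross accumulated benefit of a managed set
#'
#' Sums the static pairwise benefit of every managed species toward every
#' recipient, crediting each management action independently (no coverage
#' cap across actions). This is the accounting of the published worked
#' example in which a recipient's accumulated benefit may exceed 1.
#'
#' @param selected character vector of managed species ids.
#' @param overlap,threats,weights,config as in [pairwise_benefit()].
#' @return Named numeric vector of per-recipient accumulated benefit.
#' @export
accumulated_benefit <- function(selected, overlap, threats, weights = NULL, config) {
  ids <- rownames(threats)
  sel <- sp_index(selected, ids)
  W <- if (is.null(weights)) rep(1, nrow(threats)) else as.numeric(weights)
  denom_mode <- config$benefit_denominator
  ni <- rowSums(threats)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (i in sel) {
    if (ni[i] == 0) next
    shared <- as.numeric(threats %*% threats[i, ])   # per recipient j
    D <- if (denom_mode == "umbrella") rep(ni[i], length(ids)) else ni
    contrib <- ifelse(ni > 0, overlap[i, ] * W[i] * shared / pmax(D, 1), 0)
    out <- out + contrib
  }
  out
}

# Accrual ledger -------------------------------------------------------------

#' Create an empty benefit-accrual ledger
#'
#' The ledger tracks, for every (recipient species, threat) pair, the
#' fraction of the recipient's range over which that threat is currently
#' managed. It enforces the rule that a species benefits from a
#' threat-specific action only once per area: marginal benefits are computed
#' from capped coverage increments. In `"matrix"` mode multi-species
#' coverage is the capped sum of overlap fractions, `min(1, sum(O))`; in
#' `"geometry"` mode it is the exact union of managed grid cells within the
#' recipient's range (requires geometry on every species).
#'
#' @param records a [species_table()].
#' @param threats binary threat matrix (after [manageable_threats()] if
#'   unmanageable threats are configured).
#' @param mode `"matrix"` or `"geometry"`.
#' @return An `accrual_ledger` object.
#' @export
accrual_ledger <- function(records, threats, mode = c("matrix", "geometry")) {
  mode <- match.arg(mode)
  n <- nrow(records); m <- ncol(threats)
  ids <- records$species_id
  cells <- NULL
  if (mode == "geometry") {
    if (any(vapply(records$geometry, is.null, TRUE))) {
      umb_validation_error("geometry mode requires geometry on every species")
    }
    cells <- records$geometry
    names(cells) <- ids
  }
  structure(list(
    coverage = matrix(0, n, m, dimnames = dimnames(threats)),
    contrib = matrix(0, n, n, dimnames = list(ids, ids)),
    selected = character(0),
    mode = mode,
    cells = cells,
    managed = if (mode == "geometry") {
      stats::setNames(rep(list(stats::setNames(
        rep(list(integer(0)), m), colnames(threats))), n), ids)
    } else NULL
  ), class = "accrual_ledger")
}

# Coverage increments for candidate umbrella i: an n x m matrix of
# per-(recipient, threat) deltas under the ledger's mode.
coverage_delta <- function(i, ledger, overlap, threats) {
  m <- ncol(threats); n <- nrow(threats)
  ti <- threats[i, ] == 1L
  delta <- matrix(0, n, m, dimnames = dimnames(threats))
  if (!any(ti)) return(delta)
  if (ledger$mode == "matrix") {
    add <- outer(overlap[i, ], as.numeric(ti)) * threats
    newcov <- pmin(ledger$coverage + add, 1)
    delta <- newcov - ledger$coverage
  } else {
    gi <- ledger$cells[[i]]
    for (j in seq_len(n)) {
      inter <- intersect(gi, ledger$cells[[j]])
      if (length(inter) == 0L) next
      nj <- length(ledger$cells[[j]])
      for (k in which(ti & threats[j, ] == 1L)) {
        old <- ledger$managed[[j]][[k]]
        newlen <- length(union(old, inter))
        delta[j, k] <- (newlen - length(old)) / nj
      }
    }
  }
  delta
}

benefit_from_delta <- function(i, delta, threats, W, config) {
  n <- nrow(threats)
  nthreats <- rowSums(threats)
  per_recipient <- stats::setNames(numeric(n), rownames(threats))
  if (config$scenario == "baseline") {
    D <- if (config$benefit_denominator == "umbrella") {
      rep(sum(threats[i, ]), n)
    } else nthreats
    V <- W[i] * delta / pmax(D, 1)
    per_recipient <- rowSums(V)
    pp <- which(V > 0, arr.ind = TRUE)
    per_pair <- data.frame(
      recipient = rownames(threats)[pp[, 1]],
      threat = colnames(threats)[pp[, 2]],
      value = V[pp], stringsAsFactors = FALSE)
  } else if (config$scenario == "optimistic") {
    old <- apply(attr(delta, "oldcov"), 1, max)
    new <- apply(attr(delta, "oldcov") + delta, 1, max)
    per_recipient <- stats::setNames(W[i] * (new - old), rownames(threats))
    per_pair <- data.frame(recipient = character(0), threat = character(0),
                           value = numeric(0), stringsAsFactors = FALSE)
  } else { # pessimistic
    oldcov <- attr(delta, "oldcov")
    newcov <- oldcov + delta
    full <- function(cov) {
      vapply(seq_len(n), function(j) {
        tk <- threats[j, ] == 1L
        if (!any(tk)) return(0)
        as.numeric(all(cov[j, tk] >= 1 - 1e-12))
      }, 1)
    }
    per_recipient <- stats::setNames(W[i] * (full(newcov) - full(oldcov)),
                                     rownames(threats))
    per_pair <- data.frame(recipient = character(0), threat = character(0),
                           value = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(total = sum(per_recipient), per_recipient = per_recipient,
                 per_pair = per_pair), class = "benefit_breakdown")
}

#' Marginal (net) benefit of managing a species given prior accrual
#'
#' For each recipient `j` and each threat `k` affecting both species, the
#' newly managed coverage is the capped increment
#' `min(1, coverage + O[i, j]) - coverage` (matrix mode) or the exact new
#' union fraction (geometry mode); each increment is weighted by
#' `W[i] / D`, with `D` the umbrella's or recipient's threat count
#' depending on `config$benefit_denominator`. Re-evaluating a species whose
#' effects are already fully accrued returns a total of 0.
#'
#' @param i candidate umbrella species index or id.
#' @param ledger an [accrual_ledger()] reflecting previously managed species.
#' @param overlap,threats,weights,config as in [pairwise_benefit()].
#' @return A `benefit_breakdown`: list with `total`, `per_recipient`, and
#'   (baseline scenario) nonzero `per_pair` rows.
#' @export
marginal_benefit <- function(i, ledger, overlap, threats, weights = NULL, config) {
  ids <- rownames(threats)
  i <- sp_index(i, ids)
  if (sum(threats[i, ]) == 0) {
    umb_validation_error(sprintf(
      "species '%s' has no (manageable) threats: benefit undefined", ids[i]))
  }
  W <- if (is.null(weights)) rep(1, nrow(threats)) else as.numeric(weights)
  delta <- coverage_delta(i, ledger, overlap, threats)
  attr(delta, "oldcov") <- ledger$coverage
  benefit_from_delta(i, delta, threats, W, config)
}

#' Scenario-dependent marginal benefit
#'
#' Dispatches on `config$scenario`: `"baseline"` is [marginal_benefit()]
#' (benefit proportional to newly managed overlap); `"optimistic"` credits a
#' recipient with the increment of its *best single-threat* coverage (one
#' managed shared threat suffices); `"pessimistic"` credits a recipient only
#' when every one of its threats becomes managed across its entire range.
#'
#' @inheritParams marginal_benefit
#' @return A `benefit_breakdown`.
#' @export
scenario_benefit <- function(i, ledger, overlap, threats, weights = NULL, config) {
  if (!config$scenario %in% c("baseline", "optimistic", "pessimistic")) {
    umb_config_error(sprintf("unknown scenario '%s'", config$scenario))
  }
  marginal_benefit(i, ledger, overlap, threats, weights, config)
}

#' Accrue a managed species into the ledger
#'
#' Updates per-(recipient, threat) coverage by the capped-increment rule and
#' records the managed species' scenario contributions to every recipient.
#' A species can be accrued only once ("once a species is managed, it cannot
#' be managed again").
#'
#' @inheritParams marginal_benefit
#' @return The updated `accrual_ledger`.
#' @export
accrue <- function(i, ledger, overlap, threats, weights = NULL, config) {
  ids <- rownames(threats)
  idx <- sp_index(i, ids)
  id <- ids[idx]
  if (id %in% ledger$selected) {
    umb_validation_error(sprintf("species '%s' has already been accrued", id))
  }
  W <- if (is.null(weights)) rep(1, nrow(threats)) else as.numeric(weights)
  delta <- coverage_delta(idx, ledger, overlap, threats)
  attr(delta, "oldcov") <- ledger$coverage
  bb <- benefit_from_delta(idx, delta, threats, W, config)
  ledger$coverage <- pmin(ledger$coverage + delta, 1)
  if (ledger$mode == "geometry") {
    gi <- ledger$cells[[idx]]
    ti <- which(threats[idx, ] == 1L)
    for (j in seq_len(nrow(threats))) {
      inter <- intersect(gi, ledger$cells[[j]])
      if (length(inter) == 0L) next
      for (k in intersect(ti, which(threats[j, ] == 1L))) {
        ledger$managed[[j]][[k]] <- union(ledger$managed[[j]][[k]], inter)
      }
    }
  }
  ledger$contrib[idx, ] <- ledger$contrib[idx, ] + bb$per_recipient
  ledger$selected <- c(ledger$selected, id)
  ledger
}

#' Categorize species after a run
#'
#' Selected species whose accrued contribution to at least one *other*
#' species exceeds the benefit threshold are umbrella species; selected
#' species with no such contribution are additional species (they benefit
#' only themselves); unselected species whose accrued benefit exceeds the
#' threshold are benefitting species. `total_benefitting` counts every
#' species (selected or not) with accrued benefit above the threshold.
#'
#' @param ledger final [accrual_ledger()] of a run.
#' @param config a [run_config()]; supplies `benefit_threshold`.
#' @param selected character vector of managed species ids.
#' @return List with integer components `umbrella`, `benefitting`,
#'   `additional`, `total_benefitting`.
#' @export
count_benefitting <- function(ledger, config, selected) {
  thr <- config$benefit_threshold
  ids <- rownames(ledger$contrib)
  received <- colSums(ledger$contrib)
  is_sel <- ids %in% selected
  other <- ledger$contrib
  diag(other) <- 0
  helps_other <- rowSums(other > thr) > 0
  list(
    umbrella = sum(is_sel & helps_other),
    benefitting = sum(!is_sel & received > thr),
    additional = sum(is_sel & !helps_other),
    total_benefitting = sum(received > thr)
  )
}
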