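# The maximum-gains greedy solver, an exhaustive oracle for small
# instances, and the surrounding analyses (sensitivity, efficiency
# comparison).

accrue_with_benefit <- function(i, ledger, overlap, threats, W, config) {
  bb <- marginal_benefit(i, ledger, overlap, threats, W, config)
  ledger <- accrue(i, ledger, overlap, threats, W, config)
  list(ledger = ledger, breakdown = bb)
}

# Tie-break: maximize score; ties (1e-9 relative) by lower cost, then
# lexicographic species id. `cand` are integer indices into `ids`.
pick_best <- function(cand, score, cost, ids) {
  best <- max(score)
  tied <- cand[score >= best - 1e-9 * max(abs(best), 1)]
  tied <- tied[cost[tied] <= min(cost[tied]) + 1e-12]
  tied[order(ids[tied])][1L]
}

#' Greedy maximum-gains prioritization under a budget
#'
#' Iteratively selects the unselected species with the highest
#' cost-effectiveness `E_i` = (scenario marginal benefit) / (action cost),
#' accrues its management into the ledger, and repeats until the budget is
#' exhausted. Marginal benefits are recomputed every iteration against the
#' current ledger, so each pick reflects what prior selections have already
#' managed. Only species with positive marginal benefit are ranked by
#' `E_i`; when every remaining species has zero marginal benefit (their
#' ranges and threats are fully covered), species continue to be added in
#' order of `1 / cost` until the budget is met. Under the
#' `"skip_and_continue"` budget rule, unaffordable candidates are skipped
#' and cheaper ones may still be chosen; under `"stop_at_first"` the run
#' ends at the first unaffordable best candidate. Ties in `E_i` are broken
#' by lower cost, then lexicographic species id.
#'
#' @param records a [species_table()].
#' @param overlap overlap matrix aligned to `records`.
#' @param threats binary threat matrix aligned to `records`.
#' @param weights optional per-species weights (default all 1).
#' @param config a [run_config()].
#' @param ledger_mode `"matrix"` (capped-sum coverage) or `"geometry"`
#'   (exact cell unions; requires geometry).
#' @return A `priority_list`: list with `steps` (data.frame of rank,
#'   species_id, category, marginal_benefit, ratio, cost, cumulative_spend,
#'   n_species_newly_benefitting), `budget`, `config`, and the final
#'   `ledger`. An infeasible or fully covered instance yields zero rows,
#'   not an error.
#' @export
greedy_prioritize <- function(records, overlap, threats, weights = NULL, config,
                              ledger_mode = c("matrix", "geometry")) {
  ledger_mode <- match.arg(ledger_mode)
  threats <- manageable_threats(threats, config)
  W <- resolve_weights(weights, records)
  model <- cost_model(config$cost_q, config$cost_z)
  cost <- action_cost(records$range_area, model)
  ids <- records$species_id
  n <- length(ids)
  eligible <- rowSums(threats) > 0
  ledger <- accrual_ledger(records, threats, mode = ledger_mode)
  thr <- config$benefit_threshold
  spend <- 0
  selected <- logical(n)
  steps <- vector("list", n)
  nstep <- 0L
  benefitting_now <- 0L
  repeat {
    cand <- which(eligible & !selected)
    if (!length(cand)) break
    remaining <- config$budget - spend
    if (config$greedy_budget_rule == "skip_and_continue") {
      cand <- cand[cost[cand] <= remaining + 1e-9]
      if (!length(cand)) break
    }
    mb <- vapply(cand, function(i) {
      scenario_benefit(i, ledger, overlap, threats, W, config)$total
    }, numeric(1))
    pos <- mb > 1e-12
    if (any(pos)) {
      pool <- cand[pos]
      pool_mb <- mb[pos]
      score <- pool_mb / cost[pool]
    } else {
      pool <- cand                     # zero-benefit fallback: cheapest first
      pool_mb <- mb
      score <- 1 / cost[pool]
    }
    choice <- pick_best(pool, score, cost, ids)
    if (cost[choice] > remaining + 1e-9) break   # stop_at_first
    res <- accrue_with_benefit(choice, ledger, overlap, threats, W, config)
    ledger <- res$ledger
    benefit <- res$breakdown$total
    spend <- spend + cost[choice]
    selected[choice] <- TRUE
    benefitting_before <- benefitting_now
    benefitting_now <- sum(colSums(ledger$contrib) > thr)
    nstep <- nstep + 1L
    steps[[nstep]] <- data.frame(
      rank = nstep, species_id = ids[choice],
      marginal_benefit = benefit, ratio = benefit / cost[choice],
      cost = cost[choice], cumulative_spend = spend,
      n_species_newly_benefitting = benefitting_now - benefitting_before,
      stringsAsFactors = FALSE)
    umb_log("iteration=%d selected=%s E=%.6g spend=%.6g",
            nstep, ids[choice], benefit / cost[choice], spend)
  }
  steps <- if (nstep) do.call(rbind, steps[seq_len(nstep)]) else
    data.frame(rank = integer(0), species_id = character(0),
               marginal_benefit = numeric(0), ratio = numeric(0),
               cost = numeric(0), cumulative_spend = numeric(0),
               n_species_newly_benefitting = integer(0),
               stringsAsFactors = FALSE)
  other <- ledger$contrib
  diag(other) <- 0
  helps_other <- rowSums(other > thr) > 0
  steps$category <- ifelse(helps_other[match(steps$species_id, ids)],
                           "umbrella", "additional")
  steps <- steps[, c("rank", "species_id", "category", "marginal_benefit",
                     "ratio", "cost", "cumulative_spend",
                     "n_species_newly_benefitting")]
  structure(list(steps = steps, budget = config$budget, config = config,
                 ledger = ledger), class = "priority_list")
}

#' @export
print.priority_list <- function(x, ...) {
  cat(sprintf("Priority list: %d species selected, spend %.4g of budget %.4g (%s scenario)\n",
              nrow(x$steps),
              if (nrow(x$steps)) max(x$steps$cumulative_spend) else 0,
              x$budget, x$config$scenario))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Exhaustive optimum for small instances
#'
#' Enumerates every subset of species within the budget and returns the one
#' maximizing total accrued benefit under the same ledger semantics as the
#' greedy solver. Each subset is accrued in descending benefit-rate order
#' (weight over denominator threat count for the baseline umbrella
#' denominator, weight otherwise; ties by species id); by a
#' fractional-knapsack exchange argument this order maximizes the capped
#' total for every (recipient, threat) pair simultaneously, so the returned
#' optimum upper-bounds the benefit achievable by any accrual order --
#' including the greedy path. Intended as a verification oracle, not a
#' production solver: instances larger than `max_n` eligible species are
#' refused.
#'
#' @inheritParams greedy_prioritize
#' @param max_n refuse instances with more eligible species than this
#'   (default 15, i.e. at most 2^15 subsets).
#' @return List with `ids` (optimal subset, sorted), `benefit`, `cost`, and
#'   `n_subsets_evaluated`.
#' @export
brute_force_optimum <- function(records, overlap, threats, weights = NULL,
                                config, max_n = 15, ledger_mode = "matrix") {
  threats <- manageable_threats(threats, config)
  W <- resolve_weights(weights, records)
  model <- cost_model(config$cost_q, config$cost_z)
  cost <- action_cost(records$range_area, model)
  ids <- records$species_id
  eligible <- which(rowSums(threats) > 0)
  if (length(eligible) > max_n) {
    umb_config_error(sprintf(
      "instance has %d eligible species; brute force refuses more than %d (2^n subsets)",
      length(eligible), max_n))
  }
  nthreats <- rowSums(threats)
  rate <- if (config$scenario == "baseline" &&
              config$benefit_denominator == "umbrella") {
    W[eligible] / nthreats[eligible]
  } else W[eligible]
  eligible <- eligible[order(-rate, ids[eligible])]
  ne <- length(eligible)
  empty_ledger <- accrual_ledger(records, threats, mode = ledger_mode)
  best <- list(ids = character(0), benefit = 0, cost = 0)
  best_key <- ""
  n_eval <- 0L
  for (mask in seq_len(2^ne) - 1L) {
    if (mask == 0L) next
    members <- eligible[bitwAnd(bitwShiftR(mask, seq_len(ne) - 1L), 1L) == 1L]
    total_cost <- sum(cost[members])
    if (total_cost > config$budget + 1e-9) next
    ledger <- empty_ledger
    total <- 0
    for (i in members) {
      res <- accrue_with_benefit(i, ledger, overlap, threats, W, config)
      ledger <- res$ledger
      total <- total + res$breakdown$total
    }
    n_eval <- n_eval + 1L
    key <- paste(sort(ids[members]), collapse = "|")
    better <- total > best$benefit + 1e-12 ||
      (total >= best$benefit - 1e-12 &&
         (total_cost < best$cost - 1e-12 ||
            (total_cost <= best$cost + 1e-12 && key < best_key)))
    if (better) {
      best <- list(ids = sort(ids[members]), benefit = total, cost = total_cost)
      best_key <- key
    }
  }
  c(best, list(n_subsets_evaluated = n_eval))
}

#' Membership consistency of two priority lists
#'
#' 100 times the Jaccard similarity of list membership (order ignored);
#' two empty lists are 100% consistent by convention.
#'
#' @param list_a,list_b `priority_list` objects or character vectors of
#'   species ids.
#' @return Percentage in \[0, 100\].
#' @export
consistency <- function(list_a, list_b) {
  members <- function(x) {
    if (inherits(x, "priority_list")) x$steps$species_id else as.character(x)
  }
  a <- unique(members(list_a)); b <- unique(members(list_b))
  if (length(a) == 0 && length(b) == 0) return(100)
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Sensitivity of the priority list to the cost exponent
#'
#' Reruns the greedy prioritization for each supplied `z` under the same
#' budget and reports all pairwise membership consistencies.
#'
#' @inheritParams greedy_prioritize
#' @param z_values numeric vector of at least two cost exponents in (0, 1].
#' @return A `sensitivity_report`: list with `z_values`, `lists` (one
#'   `priority_list` per z), `consistency` (symmetric percentage matrix) and
#'   `pairs` (long-form data.frame).
#' @export
sensitivity_analysis <- function(records, overlap, threats, weights = NULL,
                                 config, z_values) {
  if (length(z_values) < 2) {
    umb_config_error("sensitivity analysis needs at least two z values")
  }
  lists <- lapply(z_values, function(z) {
    cfg <- config
    cfg$cost_z <- z
    greedy_prioritize(records, overlap, threats, weights, cfg)
  })
  k <- length(z_values)
  cons <- matrix(100, k, k, dimnames = list(z_values, z_values))
  pairs <- list()
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    cons[a, b] <- cons[b, a] <- consistency(lists[[a]], lists[[b]])
    pairs[[length(pairs) + 1L]] <- data.frame(
      z_a = z_values[a], z_b = z_values[b], consistency = cons[a, b])
  }
  structure(list(z_values = z_values, lists = lists, consistency = cons,
                 pairs = do.call(rbind, pairs)), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Priority-list membership consistency (%) across cost exponents z:\n")
  print(round(x$consistency, 1))
  invisible(x)
}

#' Compare a reference priority list with an optimized one
#'
#' Computes (1) the cost of managing every species on the reference list
#' (the assumed budget), (2) how many species benefit when exactly the
#' reference list is managed, and (3) how many benefit under a greedy
#' optimized selection constrained to that same budget, along with the
#' fold-ratio of the two counts.
#'
#' @param reference_ids non-empty character vector of species ids (e.g. a
#'   government priority list).
#' @inheritParams greedy_prioritize
#' @return An `efficiency_comparison`: list with `assumed_budget`,
#'   `reference_counts`, `optimized_counts`, `fold_ratio`, and the optimized
#'   `priority_list`.
#' @export
efficiency_comparison <- function(reference_ids, records, overlap, threats,
                                  weights = NULL, config) {
  if (length(reference_ids) == 0) {
    umb_validation_error("reference list is empty: assumed budget would be zero")
  }
  threats <- manageable_threats(threats, config)
  W <- resolve_weights(weights, records)
  model <- cost_model(config$cost_q, config$cost_z)
  assumed_budget <- portfolio_cost(reference_ids, records, model)
  ledger <- accrual_ledger(records, threats)
  managed <- character(0)
  for (id in reference_ids) {
    if (sum(threats[match(id, records$species_id), ]) == 0) {
      warning(sprintf("reference species '%s' has no manageable threats; skipped", id),
              call. = FALSE)
      next
    }
    ledger <- accrue(id, ledger, overlap, threats, W, config)
    managed <- c(managed, id)
  }
  reference_counts <- count_benefitting(ledger, config, managed)
  cfg <- config
  cfg$budget <- assumed_budget
  opt <- greedy_prioritize(records, overlap, threats, weights, cfg)
  optimized_counts <- count_benefitting(opt$ledger, cfg, opt$steps$species_id)
  structure(list(
    assumed_budget = assumed_budget,
    reference_counts = reference_counts,
    optimized_counts = optimized_counts,
    fold_ratio = optimized_counts$total_benefitting /
      reference_counts$total_benefitting,
    priority = opt
  ), class = "efficiency_comparison")
}

#' @export
print.efficiency_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "Assumed budget (cost of reference list): %.6g/yr\n",
    "Species benefitting under reference list: %d\n",
    "Species benefitting under optimized list: %d\n",
    "Fold-ratio: %.3g\n"),
    x$assumed_budget, x$reference_counts$total_benefitting,
    x$optimized_counts$total_benefitting, x$fold_ratio))
  invisible(x)
}
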