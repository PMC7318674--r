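# Domain types, validation, and file readers/writers.
#
# A species table is a data.frame with one row per species and list-columns
# for threat profiles and (optional) gridded range geometry. Geometry is a
# set of cell indices on a shared rectangular landscape grid; overlap
# fractions derived from it are exact rationals (cell counts), which keeps
# the asymmetric-consistency identity O[i,j]*area_j == O[j,i]*area_i exact.

#' Construct a validated species table
#'
#' @param species_id character vector of unique species identifiers.
#' @param name free-text species names (defaults to `species_id`).
#' @param range_area positive numeric range areas in km^2.
#' @param threats list of character vectors, one per species, naming the
#'   threats affecting that species. A species with zero threats is accepted
#'   but flagged with a warning: its benefit ratio is undefined and it is
#'   excluded from selection and accrual.
#' @param geometry optional list of integer cell-index vectors on a shared
#'   grid, one per species (or `NULL` entries for species without geometry).
#' @param cell_area area of one grid cell in km^2 (default 1). When geometry
#'   is present, `length(geometry) * cell_area` must agree with `range_area`
#'   within 0.5%.
#'
#' @return A `species_table`: a data.frame with columns `species_id`, `name`,
#'   `range_area` and list-columns `threats`, `geometry`, plus a `cell_area`
#'   attribute.
#' @export
species_table <- function(species_id, name = species_id, range_area, threats,
                          geometry = NULL, cell_area = 1) {
  species_id <- as.character(species_id)
  n <- length(species_id)
  if (n == 0L) umb_validation_error("species table is empty")
  dup <- unique(species_id[duplicated(species_id)])
  if (length(dup)) {
    umb_validation_error(sprintf(
      "duplicate species_id: %s", paste(dup, collapse = ", ")))
  }
  range_area <- as.numeric(range_area)
  bad <- which(!is.finite(range_area) | range_area <= 0)
  if (length(bad)) {
    umb_validation_error(sprintf(
      "non-positive range_area for species: %s",
      paste(species_id[bad], collapse = ", ")))
  }
  stopifnot(is.list(threats), length(threats) == n)
  threats <- lapply(threats, function(x) unique(as.character(x[nzchar(x)])))
  none <- species_id[vapply(threats, length, 1L) == 0L]
  if (length(none)) {
    warning(sprintf(
      "species with no listed threats (undefined benefit ratio, excluded from selection): %s",
      paste(none, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(geometry)) {
    stopifnot(is.list(geometry), length(geometry) == n)
    geometry <- lapply(geometry, function(g) {
      if (is.null(g)) NULL else sort(unique(as.integer(g)))
    })
    for (i in seq_len(n)) {
      g <- geometry[[i]]
      if (is.null(g)) next
      implied <- length(g) * cell_area
      if (abs(implied - range_area[i]) > 0.005 * range_area[i]) {
        umb_validation_error(sprintf(
          "geometry of species '%s' implies area %g km^2 but range_area is %g km^2 (> 0.5%% apart)",
          species_id[i], implied, range_area[i]))
      }
    }
  } else {
    geometry <- rep(list(NULL), n)
  }
  out <- data.frame(species_id = species_id, name = as.character(name),
                    range_area = range_area, stringsAsFactors = FALSE)
  out$threats <- threats
  out$geometry <- geometry
  attr(out, "cell_area") <- cell_area
  class(out) <- c("species_table", "data.frame")
  out
}

#' Read a species table from CSV
#'
#' Expects header columns `species_id`, `name`, `range_area_km2`, `threats`
#' (semicolon-delimited threat identifiers) and optionally `geometry_cells`
#' (semicolon-delimited grid-cell indices).
#'
#' @param path path to the CSV file.
#' @param cell_area grid-cell area in km^2 used to check geometry consistency.
#' @return A [species_table()].
#' @export
read_species_table <- function(path, cell_area = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("species_id", "name", "range_area_km2", "threats")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    umb_format_error(sprintf(
      "species CSV is missing required column(s): %s",
      paste(missing, collapse = ", ")))
  }
  split_field <- function(x) {
    lapply(as.character(x), function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  geometry <- NULL
  if ("geometry_cells" %in% names(df)) {
    geometry <- lapply(split_field(df$geometry_cells), function(x) {
      if (length(x) == 0L) NULL else as.integer(x)
    })
  }
  species_table(
    species_id = df$species_id, name = df$name,
    range_area = df$range_area_km2, threats = split_field(df$threats),
    geometry = geometry, cell_area = cell_area
  )
}

#' Write a species table to CSV
#'
#' Inverse of [read_species_table()]: threats and geometry cells are joined
#' with semicolons.
#'
#' @param records a [species_table()].
#' @param path output path.
#' @export
write_species_table <- function(records, path) {
  join <- function(xs) vapply(xs, function(x) paste(x, collapse = ";"), "")
  df <- data.frame(
    species_id = records$species_id, name = records$name,
    range_area_km2 = records$range_area,
    threats = join(records$threats), stringsAsFactors = FALSE)
  if (any(!vapply(records$geometry, is.null, TRUE))) {
    df$geometry_cells <- join(records$geometry)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build the binary species-by-threat matrix
#'
#' The threat vocabulary is the union of all listed threats in encounter
#' order (row by row), fixed thereafter.
#'
#' @param records a [species_table()].
#' @return An n x m 0/1 integer matrix with species ids as rownames and
#'   threat ids as colnames.
#' @export
threat_matrix <- function(records) {
  vocab <- unique(unlist(records$threats, use.names = FALSE))
  m <- matrix(0L, nrow = nrow(records), ncol = length(vocab),
              dimnames = list(records$species_id, vocab))
  for (i in seq_len(nrow(records))) {
    m[i, match(records$threats[[i]], vocab)] <- 1L
  }
  m
}

#' Zero out threats that have no management action
#'
#' Threats listed in `config$unmanageable_threats` contribute no benefit
#' (their matrix columns are zeroed); they do not change range areas or
#' costs.
#'
#' @param threats a binary threat matrix from [threat_matrix()].
#' @param config a [run_config()].
#' @return The threat matrix with unmanageable columns set to 0.
#' @export
manageable_threats <- function(threats, config) {
  drop <- intersect(colnames(threats), config$unmanageable_threats)
  if (length(drop)) threats[, drop] <- 0L
  threats
}

#' Build the pairwise range-overlap matrix from gridded geometry
#'
#' `O[i, j]` is the fraction of species j's range intersected by species i's
#' range: `|cells_i ∩ cells_j| / |cells_j|`. The diagonal is exactly 1 and
#' `O[i, j] * area_j == O[j, i] * area_i` exactly (both equal the
#' intersection cell count times the cell area).
#'
#' @param records a [species_table()] in which every species has geometry.
#' @return An n x n numeric matrix with species ids as dimnames.
#' @export
build_overlap_matrix <- function(records) {
  missing_geom <- records$species_id[vapply(records$geometry, is.null, TRUE)]
  if (length(missing_geom)) {
    umb_validation_error(sprintf(
      "species without geometry (%s): supply a precomputed overlap CSV via read_overlap_matrix() instead",
      paste(missing_geom, collapse = ", ")))
  }
  n <- nrow(records)
  sizes <- vapply(records$geometry, length, 1L)
  O <- matrix(0, n, n, dimnames = list(records$species_id, records$species_id))
  for (i in seq_len(n)) {
    gi <- records$geometry[[i]]
    for (j in seq_len(n)) {
      if (i == j) { O[i, j] <- 1; next }
      O[i, j] <- length(intersect(gi, records$geometry[[j]])) / sizes[j]
    }
  }
  O
}

validate_overlap_matrix <- function(O, areas = NULL, tol = 1e-9) {
  if (nrow(O) != ncol(O)) umb_validation_error("overlap matrix is not square")
  bad <- which(O < -tol | O > 1 + tol, arr.ind = TRUE)
  if (nrow(bad)) {
    umb_validation_error(sprintf(
      "overlap entries outside [0, 1] at (row, col): %s",
      paste(sprintf("(%d,%d)=%g", bad[, 1], bad[, 2], O[bad]), collapse = ", ")))
  }
  dg <- diag(O)
  if (any(abs(dg - 1) > tol)) {
    umb_validation_error(sprintf(
      "overlap diagonal must be 1; offending species: %s",
      paste(rownames(O)[abs(dg - 1) > tol], collapse = ", ")))
  }
  if (!is.null(areas)) {
    lhs <- O * rep(areas, each = nrow(O))      # O[i,j] * area_j
    rhs <- t(O) * areas                        # O[j,i] * area_i
    rel <- abs(lhs - rhs) / pmax(abs(lhs), abs(rhs), 1e-300)
    viol <- which(rel > tol & (lhs > 0 | rhs > 0), arr.ind = TRUE)
    if (nrow(viol)) {
      umb_validation_error(sprintf(
        "overlap inconsistent with areas (O[i,j]*area_j != O[j,i]*area_i) at: %s",
        paste(sprintf("(%d,%d)", viol[, 1], viol[, 2]), collapse = ", ")))
    }
  }
  invisible(O)
}

#' Read a precomputed overlap matrix from CSV
#'
#' The file must be a square matrix with species ids as the header row and
#' the first column. Entries are validated (range, unit diagonal, and --
#' when range areas are supplied -- the asymmetric consistency identity
#' `O[i,j] * area_j == O[j,i] * area_i`).
#'
#' @param path path to the CSV.
#' @param species_order character vector of species ids giving the row/column
#'   order of the returned matrix.
#' @param areas optional numeric range areas named by species id, used for the
#'   consistency check.
#' @return An n x n numeric overlap matrix aligned to `species_order`.
#' @export
read_overlap_matrix <- function(path, species_order, areas = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  O <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(O) <- "double"
  rownames(O) <- ids
  if (!setequal(ids, species_order) || !setequal(colnames(O), species_order)) {
    extra <- setdiff(union(ids, colnames(O)), species_order)
    miss <- setdiff(species_order, intersect(ids, colnames(O)))
    umb_validation_error(sprintf(
      "overlap matrix ids do not match the species table (unexpected: %s; missing: %s)",
      if (length(extra)) paste(extra, collapse = ", ") else "none",
      if (length(miss)) paste(miss, collapse = ", ") else "none"))
  }
  O <- O[species_order, species_order]
  if (!is.null(areas)) areas <- as.numeric(areas[species_order])
  validate_overlap_matrix(O, areas)
  O
}

#' Write an overlap matrix to CSV
#'
#' @param O overlap matrix with species-id dimnames.
#' @param path output path.
#' @export
write_overlap_matrix <- function(O, path) {
  df <- data.frame(species_id = rownames(O),
                   signif(O, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every knob of a prioritization run.
#'
#' @param budget positive total budget, cost units per year.
#' @param scenario benefit scenario: `"baseline"` (benefit proportional to
#'   managed overlap), `"optimistic"` (a species benefits once any one shared
#'   threat is managed over the overlap) or `"pessimistic"` (benefit only on
#'   complete management of every threat across the species' whole range).
#' @param benefit_denominator `"umbrella"` divides the shared-threat count by
#'   the managed (umbrella) species' threat count; `"recipient"` divides by
#'   the recipient's. The umbrella form reproduces the published three-species
#'   worked example; see the methods vignette for the trade-off.
#' @param cost_q positive multiplier of the power-law cost model, cost units
#'   per km^(2z) per year.
#' @param cost_z power-law exponent in (0, 1]; values below 1 give
#'   diminishing per-area costs. Typical values 0.2-0.4.
#' @param greedy_budget_rule `"skip_and_continue"` skips candidates whose cost
#'   exceeds the remaining budget and keeps scanning; `"stop_at_first"` ends
#'   the run at the first unaffordable best candidate.
#' @param benefit_threshold accrued benefit above which a species counts as
#'   benefitting (default 0: any positive benefit counts).
#' @param unmanageable_threats character vector of threat ids with no
#'   management action; they contribute zero benefit.
#' @param seed integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(budget,
                       scenario = c("baseline", "optimistic", "pessimistic"),
                       benefit_denominator = c("umbrella", "recipient"),
                       cost_q = 1, cost_z = 0.3,
                       greedy_budget_rule = c("skip_and_continue", "stop_at_first"),
                       benefit_threshold = 0,
                       unmanageable_threats = character(0),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  benefit_denominator <- match.arg(benefit_denominator)
  greedy_budget_rule <- match.arg(greedy_budget_rule)
  if (!is.numeric(budget) || length(budget) != 1L || !is.finite(budget) || budget <= 0) {
    umb_config_error("budget must be a single positive number")
  }
  if (!is.numeric(cost_q) || cost_q <= 0) umb_config_error("cost_q must be > 0")
  if (!is.numeric(cost_z) || cost_z <= 0 || cost_z > 1) {
    umb_config_error("cost_z must lie in (0, 1]")
  }
  if (!is.numeric(benefit_threshold) || benefit_threshold < 0) {
    umb_config_error("benefit_threshold must be >= 0")
  }
  structure(list(
    budget = as.numeric(budget), scenario = scenario,
    benefit_denominator = benefit_denominator,
    cost_q = as.numeric(cost_q), cost_z = as.numeric(cost_z),
    greedy_budget_rule = greedy_budget_rule,
    benefit_threshold = as.numeric(benefit_threshold),
    unmanageable_threats = as.character(unmanageable_threats),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path path to the YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    umb_config_error(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Write a priority list to CSV
#'
#' Columns: `rank`, `species_id`, `category`, `marginal_benefit`, `cost`,
#' `cumulative_spend`, `n_species_newly_benefitting`. Floats are printed at
#' 6 decimals; the header row is always present (an empty selection yields a
#' header-only file).
#'
#' @param result a `priority_list` from [greedy_prioritize()].
#' @param path output path.
#' @export
write_priority_list <- function(result, path) {
  stopifnot(inherits(result, "priority_list"))
  s <- result$steps
  fmt <- function(x) formatC(x, format = "f", digits = 6)
  df <- data.frame(
    rank = s$rank, species_id = s$species_id, category = s$category,
    marginal_benefit = fmt(s$marginal_benefit), cost = fmt(s$cost),
    cumulative_spend = fmt(s$cumulative_spend),
    n_species_newly_benefitting = s$n_species_newly_benefitting,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run summary to JSON
#'
#' Fields: scenario, denominator mode, category counts, total benefit, spend
#' and budget.
#'
#' @param result a `priority_list` from [greedy_prioritize()].
#' @param path output path.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "priority_list"))
  counts <- count_benefitting(result$ledger, result$config,
                              result$steps$species_id)
  out <- list(
    scenario = result$config$scenario,
    benefit_denominator = result$config$benefit_denominator,
    umbrella = counts$umbrella, benefitting = counts$benefitting,
    additional = counts$additional,
    total_benefitting = counts$total_benefitting,
    total_benefit = sum(result$steps$marginal_benefit),
    spend = if (nrow(result$steps)) max(result$steps$cumulative_spend) else 0,
    budget = result$budget)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
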