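# Shared fixture builders. Everything is constructed in code; geometry uses
# the package's grid-cell convention (cell index = (row-1)*ncol + col).

cells_rect <- function(top, left, h, w, ncol_grid = 200L) {
  rows <- rep(top:(top + h - 1L), each = w)
  cols <- rep(left:(left + w - 1L), times = h)
  (rows - 1L) * ncol_grid + cols
}

# Six-species instance with a hand-derivable greedy trajectory (z = 0.5,
# q = 1, budget 38). spA and spB are equal 16-cell squares sharing half
# their cells; both sit inside spC (81 cells, two threats); spD/spE/spF are
# isolated.
six_species_instance <- function() {
  recs <- species_table(
    species_id = c("spA", "spB", "spC", "spD", "spE", "spF"),
    range_area = c(16, 16, 81, 256, 625, 10000),
    threats = list("t1", "t1", c("t1", "t2"), "t2", "t1", "t2"),
    geometry = list(
      cells_rect(1L, 1L, 4L, 4L), cells_rect(1L, 3L, 4L, 4L),
      cells_rect(1L, 1L, 9L, 9L), cells_rect(30L, 30L, 16L, 16L),
      cells_rect(60L, 60L, 25L, 25L), cells_rect(101L, 101L, 100L, 100L)))
  list(records = recs, overlap = build_overlap_matrix(recs),
       threats = threat_matrix(recs),
       config = run_config(budget = 38, cost_z = 0.5))
}

# Instance on which greedy is provably suboptimal: one expensive umbrella
# spU (covers recipients r1, r2) has the top cost-effectiveness, but the
# two cheap complementary species spP + spQ (each covering its own
# recipient) jointly yield more benefit within the budget.
greedy_trap_instance <- function() {
  recs <- species_table(
    species_id = c("spU", "spP", "spQ", "r1", "r2", "r3", "r4"),
    range_area = c(10000, 4096, 4096, 4096, 4096, 3969, 3969),
    threats = rep(list("t1"), 7),
    geometry = list(
      cells_rect(1L, 1L, 100L, 100L), cells_rect(101L, 1L, 64L, 64L),
      cells_rect(101L, 101L, 64L, 64L), cells_rect(1L, 1L, 64L, 64L),
      cells_rect(21L, 21L, 64L, 64L), cells_rect(101L, 1L, 63L, 63L),
      cells_rect(101L, 101L, 63L, 63L)))
  list(records = recs, overlap = build_overlap_matrix(recs),
       threats = threat_matrix(recs),
       config = run_config(budget = 16, cost_z = 0.25))
}

# Small random instance for oracle-dominance ensembles.
random_instance <- function(seed, n = NULL) {
  cfg <- synthetic_config(
    n_species = if (is.null(n)) 4L + (seed %% 7L) else n,
    n_threats = 4, grid = c(24, 24), range_cells = c(4, 100),
    clustering = 0.4, threat_prevalence = 0.35, seed = seed)
  asm <- generate_assemblage(cfg)
  total <- portfolio_cost(asm$records$species_id, asm$records,
                          cost_model(1, 0.3))
  asm$config <- run_config(budget = 0.5 * total, cost_z = 0.3)
  asm
}

write_species_csv <- function(path, rows) {
  writeLines(c("species_id,name,range_area_km2,threats", rows), path)
}
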