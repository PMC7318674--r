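# Greedy solver, exhaustive oracle, sensitivity, and efficiency comparison.

test_that("greedy reproduces a hand-derived selection sequence", {
  # By hand (z = 0.5, q = 1, costs 4, 4, 9, 16, 25, 100; budget 38):
  # iter 1: E_A = E_B = (1 + 1/2 + 16/81)/4; tie broken by id -> spA.
  # iter 2: spB marginal = (1 - 1/2) + 16/81 (spA already covers half of B
  #         and 16/81 of C for t1) -> E = 0.174; beats C = 1.151/9.
  # iter 3: spC marginal = ((1 - 32/81) + 1)/2 = 65/81 -> E = 0.0892.
  # iter 4: spD self benefit 1, E = 1/16; spE (1/25), spF (1/100) trail.
  # iter 5: remaining spE (cost 25), spF (cost 100) exceed the 5 left.
  inst <- six_species_instance()
  pl <- greedy_prioritize(inst$records, inst$overlap, inst$threats,
                          config = inst$config)
  expect_equal(pl$steps$species_id, c("spA", "spB", "spC", "spD"))
  expect_equal(pl$steps$marginal_benefit,
               c(1 + 0.5 + 16/81, 0.5 + 16/81, 65/81, 1), tolerance = 1e-12)
  expect_equal(pl$steps$cost, c(4, 4, 9, 16))
  expect_equal(pl$steps$cumulative_spend, cumsum(pl$steps$cost))
  # spC is selected only after spA and spB have fully covered its
  # neighbours' shared threat, so at selection time it helps nobody else
  expect_equal(pl$steps$category,
               c("umbrella", "umbrella", "additional", "additional"))
})

test_that("unconstrained budgets select everything useful; infeasible budgets select nothing", {
  inst <- six_species_instance()
  rich <- run_config(budget = 1e6, cost_z = 0.5)
  pl <- greedy_prioritize(inst$records, inst$overlap, inst$threats, config = rich)
  expect_setequal(pl$steps$species_id, inst$records$species_id)
  poor <- run_config(budget = 2, cost_z = 0.5)
  pl0 <- greedy_prioritize(inst$records, inst$overlap, inst$threats, config = poor)
  expect_equal(nrow(pl0$steps), 0L)
})

test_that("budget rules differ: skip_and_continue keeps scanning, stop_at_first halts", {
  # Three disjoint species, costs 10 / 9 / 2 (z = 0.5), weights 2 / 1 / 0.05,
  # budget 12. Greedy picks spX (E = 0.2). With 2 left, the best remaining
  # candidate spY (E = 1/9) is unaffordable; spZ (E = 0.025) still fits.
  recs <- species_table(c("spX", "spY", "spZ"),
                        range_area = c(100, 81, 4),
                        threats = rep(list("t"), 3))
  O <- diag(3); dimnames(O) <- list(recs$species_id, recs$species_id)
  T <- threat_matrix(recs)
  W <- c(2, 1, 0.05)
  skip <- greedy_prioritize(recs, O, T, W,
                            run_config(budget = 12, cost_z = 0.5))
  halt <- greedy_prioritize(recs, O, T, W,
                            run_config(budget = 12, cost_z = 0.5,
                                       greedy_budget_rule = "stop_at_first"))
  expect_equal(skip$steps$species_id, c("spX", "spZ"))
  expect_equal(halt$steps$species_id, "spX")
})

test_that("every selected species has zero marginal benefit afterwards (anti-redundancy)", {
  inst <- six_species_instance()
  pl <- greedy_prioritize(inst$records, inst$overlap, inst$threats,
                          config = inst$config)
  for (id in pl$steps$species_id) {
    mb <- marginal_benefit(id, pl$ledger, inst$overlap, inst$threats,
                           config = inst$config)
    expect_equal(mb$total, 0)
  }
  expect_false(any(duplicated(pl$steps$species_id)))
})

test_that("greedy rechecks: each step's E is maximal among candidates at that step", {
  inst <- six_species_instance()
  cfg <- inst$config
  pl <- greedy_prioritize(inst$records, inst$overlap, inst$threats, config = cfg)
  led <- accrual_ledger(inst$records, inst$threats)
  model <- cost_model(cfg$cost_q, cfg$cost_z)
  costs <- setNames(action_cost(inst$records$range_area, model),
                    inst$records$species_id)
  chosen <- character(0)
  for (s in seq_len(nrow(pl$steps))) {
    id <- pl$steps$species_id[s]
    remaining <- cfg$budget - if (s == 1) 0 else pl$steps$cumulative_spend[s - 1]
    cand <- setdiff(inst$records$species_id, chosen)
    cand <- cand[costs[cand] <= remaining + 1e-9]
    E <- vapply(cand, function(j) {
      marginal_benefit(j, led, inst$overlap, inst$threats, config = cfg)$total /
        costs[[j]]
    }, numeric(1))
    expect_equal(max(E), pl$steps$ratio[s], tolerance = 1e-9)
    led <- accrue(id, led, inst$overlap, inst$threats, config = cfg)
    chosen <- c(chosen, id)
  }
})

test_that("the exhaustive oracle beats greedy on a constructed complementarity trap", {
  trap <- greedy_trap_instance()
  g <- greedy_prioritize(trap$records, trap$overlap, trap$threats,
                         config = trap$config)
  expect_equal(g$steps$species_id, "spU")
  expect_equal(sum(g$steps$marginal_benefit), 3)
  bf <- brute_force_optimum(trap$records, trap$overlap, trap$threats,
                            config = trap$config)
  expect_equal(bf$ids, c("spP", "spQ"))
  expect_equal(bf$benefit, 4)
  expect_true(bf$benefit > sum(g$steps$marginal_benefit))
})

test_that("the oracle handles singletons and refuses oversized instances", {
  one <- species_table("solo", range_area = 4, threats = list("t"),
                       geometry = list(cells_rect(1L, 1L, 2L, 2L)))
  O <- build_overlap_matrix(one); T <- threat_matrix(one)
  bf <- brute_force_optimum(one, O, T, config = run_config(budget = 10))
  expect_equal(bf$ids, "solo")
  expect_equal(bf$benefit, 1)
  asm <- generate_assemblage(synthetic_config(n_species = 12, grid = c(20, 20),
                                              range_cells = c(4, 50), seed = 2))
  expect_error(
    brute_force_optimum(asm$records, asm$overlap, asm$threats,
                        config = run_config(budget = 10), max_n = 10),
    "refuses", class = "umb_config_error")
})

test_that("greedy never beats the oracle and is budget-feasible on random instances", {
  ratios <- numeric(0)
  for (seed in 1:40) {
    asm <- random_instance(seed)
    g <- greedy_prioritize(asm$records, asm$overlap, asm$threats,
                           config = asm$config)
    if (nrow(g$steps)) {
      expect_lte(max(g$steps$cumulative_spend), asm$config$budget + 1e-9)
    }
    bf <- brute_force_optimum(asm$records, asm$overlap, asm$threats,
                              config = asm$config)
    gtot <- sum(g$steps$marginal_benefit)
    expect_lte(gtot, bf$benefit + 1e-9)
    if (bf$benefit > 0) ratios <- c(ratios, gtot / bf$benefit)
  }
  expect_true(all(ratios >= 0 & ratios <= 1 + 1e-9))
})

test_that("list consistency is Jaccard membership in percent", {
  expect_equal(consistency(c("a", "b", "c"), c("a", "b", "c")), 100)
  expect_equal(consistency(c("a", "b"), c("c", "d")), 0)
  expect_equal(consistency(c("a", "b", "c"), c("a", "b", "d")), 50)
  expect_equal(consistency(character(0), character(0)), 100)
})

test_that("sensitivity analysis reruns greedy per z and reports pairwise consistencies", {
  inst <- six_species_instance()
  rep3 <- sensitivity_analysis(inst$records, inst$overlap, inst$threats,
                               config = inst$config, z_values = c(0.2, 0.3, 0.4))
  expect_equal(nrow(rep3$pairs), 3L)
  expect_true(all(rep3$pairs$consistency >= 0 & rep3$pairs$consistency <= 100))
  expect_equal(unname(diag(rep3$consistency)), rep(100, 3))
  dup <- sensitivity_analysis(inst$records, inst$overlap, inst$threats,
                              config = inst$config, z_values = c(0.3, 0.3))
  expect_equal(dup$pairs$consistency, 100)
  expect_error(sensitivity_analysis(inst$records, inst$overlap, inst$threats,
                                    config = inst$config, z_values = 0.3),
               class = "umb_config_error")
})

test_that("equal-area universes give z-invariant lists once the budget is rescaled", {
  # all ranges equal -> all costs equal q * A^z; scaling the budget by the
  # same factor leaves the selection order untouched.
  recs <- species_table(
    sprintf("s%d", 1:5), range_area = rep(64, 5),
    threats = list("t1", "t1", "t2", c("t1", "t2"), "t2"),
    geometry = list(cells_rect(1L, 1L, 8L, 8L), cells_rect(1L, 5L, 8L, 8L),
                    cells_rect(5L, 1L, 8L, 8L), cells_rect(5L, 5L, 8L, 8L),
                    cells_rect(40L, 40L, 8L, 8L)))
  O <- build_overlap_matrix(recs); T <- threat_matrix(recs)
  sel <- lapply(c(0.2, 0.4), function(z) {
    cfg <- run_config(budget = 3 * 64^z, cost_q = 1, cost_z = z)
    greedy_prioritize(recs, O, T, config = cfg)$steps$species_id
  })
  expect_equal(sel[[1]], sel[[2]])
})

test_that("efficiency comparison benchmarks a reference list against greedy", {
  tl <- make_two_list_fixture()
  cfg <- run_config(budget = 1, cost_z = 0.3)   # budget replaced internally
  ec <- efficiency_comparison(tl$reference_ids, tl$records, tl$overlap,
                              tl$threats, config = cfg)
  expect_equal(ec$assumed_budget,
               portfolio_cost(tl$reference_ids, tl$records, cost_model(1, 0.3)))
  expect_equal(ec$reference_counts$total_benefitting, 8L)
  expect_gte(ec$reference_counts$total_benefitting, length(tl$reference_ids))
  expect_true(ec$fold_ratio > 1)
  # self-comparison: the optimized list benchmarked against itself is 1
  own <- efficiency_comparison(ec$priority$steps$species_id, tl$records,
                               tl$overlap, tl$threats, config = cfg)
  expect_equal(own$fold_ratio, 1)
  expect_error(efficiency_comparison(character(0), tl$records, tl$overlap,
                                     tl$threats, config = cfg),
               class = "umb_validation_error")
})

test_that("identical inputs produce byte-identical priority CSV and summary JSON", {
  tl <- make_two_list_fixture()
  cfg <- run_config(budget = 30, cost_z = 0.3, seed = 42L)
  out <- replicate(2, {
    pl <- greedy_prioritize(tl$records, tl$overlap, tl$threats, config = cfg)
    csv <- withr::local_tempfile(fileext = ".csv")
    js <- withr::local_tempfile(fileext = ".json")
    write_priority_list(pl, csv)
    write_summary(pl, js)
    c(paste(readLines(csv), collapse = "\n"), paste(readLines(js), collapse = "\n"))
  })
  expect_identical(out[1, 1], out[1, 2])
  expect_identical(out[2, 1], out[2, 2])
})
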