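---
title: "Choosing umbrella species by cost-effectiveness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing umbrella species by cost-effectiveness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(umbrellar)
```

## The problem

Given a set of threatened species — each with a geographic range, a profile
of threats (fire, invasive predators, grazing, …), and a cost of managing
all of those threats across its full range — and a fixed annual budget,
which species should be managed so that the largest number of species
benefits? Managing one species can benefit others, but only where two
conditions hold simultaneously: the ranges overlap, *and* the managed
threat also affects the other species. `umbrellar` formalizes this as a
budget-constrained maximum-gains problem and solves it greedily.

## Benefit model

Let $O_{ij}$ be the fraction of species $j$'s range intersected by species
$i$'s range (asymmetric: $O_{ij} A_j = O_{ji} A_i$ = the intersection
area), $T_{ik} \in \{0,1\}$ the species × threat matrix, and $W_i$ a
species weight (1 by default). The baseline benefit of managing all
threats to species $i$ is

$$B_i = \sum_j O_{ij}\, W_i\, \frac{\sum_k T_{ik} T_{jk}}{\sum_k T_{ik}},$$

i.e. each overlapping species gains the overlap fraction scaled by the
proportion of shared threats. Two points in this formula were genuinely
open and are worth being explicit about.

**The denominator.** Written as above, the shared-threat count is divided
by the *managed* (umbrella) species' threat count, so a single-threat
umbrella passes its full overlap to every recipient sharing that threat.
The alternative reading divides by the *recipient's* threat count (a
recipient plagued by ten threats gains little from one being managed).
Only the umbrella-side denominator reproduces the classic three-species
worked example (below), so it is the default; both are available through
`run_config(benefit_denominator =)`. With the recipient-side denominator
the total benefit any species can accrue over a run is bounded by its
weight — a conservation property the test suite checks.

**Gross versus net accounting.** The package computes benefits two ways,
and they are deliberately not reconciled:

* `accumulated_benefit()` is the *gross* accounting: every management
  action is credited with its full overlap fraction, independently of any
  other action. In the three-species example — a koala threatened by foxes
  and fire, a bilby (foxes) overlapping 15% of the koala's range, an
  orchid (fire) overlapping a disjoint 15% — the koala accumulates
  $0.15 + 0.15 + 1.0 = 1.30$ with all three managed. Gross benefit can
  exceed 1 per species.
* `marginal_benefit()` / `accrue()` implement the *net* accounting used by
  the optimizer: a ledger tracks the managed fraction of each (recipient,
  threat) pair, capped at the recipient's full range, and a candidate is
  credited only with the coverage it *adds*. Under this accounting the same
  example yields at most 1.15 for the koala (the koala's own fox
  management re-covers the bilby strip, and that increment is capped),
  whatever the order of management. The discrepancy is intrinsic: the
  gross figure double-counts fox abatement over the 15% strip. We keep the
  gross form because it is the published illustration's arithmetic and a
  useful descriptive summary; the optimizer never uses it.

The net accounting is what makes the greedy selection complementarity-
aware: re-evaluating an already-selected species returns exactly zero, and
a species whose range and threats are fully covered by earlier picks
contributes nothing and is passed over.

**Scenarios.** Besides the proportional baseline, two bracketing scenarios
are provided, reconstructed from their one-sentence descriptions and
isolated in one code path each so they are easy to revise: *optimistic* —
a recipient benefits once any one shared threat is managed over the
overlap (the increment of its best single-threat coverage); *pessimistic*
— benefit is counted only when every threat to the recipient is managed
across its entire range (a 0/1 completion indicator). For any fixed
selection the benefitting counts are ordered optimistic ≥ baseline ≥
pessimistic, which the acceptance tests verify on every fixture.

**Ledger modes.** With only the pairwise overlap matrix available, the
coverage contributed to a recipient by several umbrellas is approximated
by the capped sum $\min(1, \sum_i O_{ij})$ (`mode = "matrix"`), which
over-counts where umbrella ranges mutually intersect inside the recipient;
triple intersections are not recoverable from $O$ alone. When gridded
geometry is available, `mode = "geometry"` computes exact cell unions.
Matrix-mode coverage is always ≥ geometry-mode coverage, with equality for
pairwise-disjoint managed areas; both modes are order-invariant in the
final coverage.

## Cost model

$C_i = q R_i^z$, with $R_i$ the species' full range area (partial-range
management is not costed — the method assumes all threats are managed
across the entire range), $q > 0$ a fitted area-to-cost conversion
supplied by the user (the synthetic generator emits $q = 1$; costs are
unit-agnostic), and $0 < z \le 1$ the diminishing-returns exponent.
Realistic $z$ lies around 0.2–0.4; `sensitivity_analysis()` reruns the
prioritization across a set of exponents and reports pairwise
priority-list consistency as a Jaccard membership percentage (the metric
is an interpretation — "consistency" has no canonical definition — and is
documented as such). Threats with no feasible management action can be
listed in `run_config(unmanageable_threats =)`; they contribute zero
benefit but do not change areas or costs. Cost depends on area only, not
on how many threats a species has.

## The greedy solver

Each iteration recomputes, for every unselected species with at least one
manageable threat, the scenario marginal benefit against the current
ledger, and selects the candidate maximizing $E_i = B_i / C_i$ among those
with positive marginal benefit. Two budget rules are exposed:
`skip_and_continue` (default; unaffordable candidates are skipped and the
scan continues — standard greedy-knapsack practice) and `stop_at_first`
(the run ends at the first unaffordable best candidate). Ties in $E_i$
(within $10^{-9}$ relative) are broken by lower cost, then lexicographic
species id, making runs deterministic: identical inputs produce
byte-identical priority CSVs and summary JSON. When every remaining
species has zero marginal benefit — fully covered by earlier picks —
species continue to be added cheapest-first until the budget is met,
mirroring the notion of "additional" species appended in
cost-effectiveness order; this fallback is an interpretation and is
confined to one branch of the selection loop.

After the run, selected species are categorized from the ledger's
contribution matrix: *umbrella* if they contributed benefit above the
threshold (default 0) to at least one other species at the time they were
accrued, *additional* otherwise; unselected species with accrued benefit
are *benefitting*. Note a subtlety the six-species regression test pins
down: a species selected late may be categorized *additional* even though
it would have helped others had it been selected first — categories
describe the realized run, not potential.

## The exhaustive oracle

`brute_force_optimum()` enumerates all affordable subsets (refusing more
than `max_n = 15` eligible species) and evaluates each with the same
ledger semantics as the greedy solver. Because the capped increments make
the total depend on accrual order when umbrellas with different
benefit-per-threat rates compete for the same capped (recipient, threat)
capacity, each subset is evaluated in descending benefit-rate order
($W_i / \sum_k T_{ik}$ under the baseline umbrella denominator, $W_i$
otherwise; ties by id). By the fractional-knapsack exchange argument this
order fills every capped capacity with the highest-rate contributions
first and therefore upper-bounds the total achievable by *any* order —
including the greedy path — so oracle dominance (greedy ≤ optimum) holds
structurally as well as empirically. The test ensemble also includes a
constructed instance where two cheap complementary species jointly beat
the single most cost-effective umbrella, confirming the greedy heuristic's
known suboptimality.

## Efficiency comparison and assumed budgets

`efficiency_comparison()` reproduces the reference-list benchmark design:
the cost of managing every species on a reference list becomes the
*assumed budget*; the number of species benefitting when exactly that list
is managed is compared with the number benefitting under a greedy
optimized selection constrained to the same budget, and the fold-ratio of
the two counts is reported.

## Synthetic assemblages

No real distribution/threat/cost data ship with the package, so
`generate_assemblage()` creates controllable stand-ins: rectangular
contiguous ranges on a shared grid (default 256 × 256 cells of 1 km²),
log-uniform range sizes, placement that interpolates between uniform
(clustering 0) and hotspot-concentrated (clustering 1, three Gaussian
kernels with sd 5% of the grid side), and independent per-threat Bernoulli
profiles (default 10 threats, prevalence 0.2, at least one threat per
species — matching the premise that every threatened species has a listed
threat). Rectangles make every overlap fraction an exact rational and the
consistency identity $O_{ij}A_j = O_{ji}A_i$ exact, at the price of
realism: real range maps are fragmented and anisotropic, threats co-occur
non-independently, and range size correlates with threat type. Passing
tests on these assemblages validates the *bookkeeping and optimization*,
not ecological realism of any particular prioritization.

Two named fixtures are first-class: `make_figure1_fixture()` (the
three-species example, with the two managed strips on provably disjoint
cells) and `make_two_list_fixture()` (40 species: 8 isolated
reference-list species and 4 clusters of 8 overlapping, threat-sharing
species, constructed so optimization under the reference budget benefits
strictly more species).

## Numerical choices and problem sizes

Positive-benefit screening uses a $10^{-12}$ floor; budget feasibility
allows $10^{-9}$ slack so exact-cost portfolios (subset cost equal to the
budget) are admitted; tie detection is $10^{-9}$ relative. Zero-threat
species are accepted at read time with a warning and excluded from
selection and accrual. Geometry is validated against declared areas at
0.5% relative tolerance; overlap matrices read from CSV are validated for
range, unit diagonal, and area consistency at $10^{-9}$ relative
tolerance.

The test suite's ensembles are sized for routine desk runs: the
oracle-dominance ensemble uses 200 seeded instances of 4–10 species and 4
threats on a 24 × 24 grid with the budget set to half the universe's total
portfolio cost; Monte-Carlo placement checks use 500 replicates of 4
species against the closed-form expected rectangle intersection;
prevalence recovery uses 1000 species. These sizes keep the full suite
under a few minutes while leaving the statistical checks well-powered.

## Known limitations

* Benefit is static: no persistence probabilities, management feasibility,
  time lags, or threat severity — benefit is range-and-threat geometry
  only.
* Matrix-mode coverage over-counts mutually overlapping umbrellas (see
  above); supply geometry where exactness matters.
* The greedy solver carries no approximation guarantee; use the oracle to
  audit small instances.
* Gross accumulated benefit intentionally double-counts co-located actions
  and must not be summed as if it were net benefit.
* The synthetic generator does not emulate real biogeography; conclusions
  about real assemblages require real range, threat, and cost data.
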