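---
title: "Designing a post-disaster blood supply chain: model, methods, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a post-disaster blood supply chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodnet)
```

## The planning problem

After a major disaster, transfusion demand spikes while the blood supply
chain itself is disrupted. Blood cannot be stockpiled in advance at scale —
it perishes — so the response network has to be designed for throughput:
where to station mobile (temporary) collection units, which candidate
permanent facilities and blood centers to activate, whether to erect field
hospitals, and how to route collected blood so that as much transfusion
demand as possible is met at acceptable cost.

`bloodnet` formulates this as a mixed-integer linear program over a
three-layer network — collection sites feed blood centers, blood centers
feed treatment nodes — repeated over a small number of response periods and,
in the stochastic variant, over discrete severity scenarios.

### Structure and assumptions

* **Facility roles.** Temporary sites only collect. Permanent facilities
  (hospitals/clinics) both collect and treat. Blood centers test, process
  and store; they are the only inventory-holding layer. Field hospitals are
  candidate treatment nodes erected for the emergency. Standing treatment
  centers are always open. Existing facilities of any class are treated as
  open and are never charged a setup cost.
* **Flows and losses.** A fraction `beta` of collected units survives
  testing/processing at the blood center (default 0.8); the survivors enter
  a single-pool inventory with no further aging or spoilage within the
  planning horizon. Blood is a single commodity: no blood groups, no product
  fractions.
* **Demand.** Demand is given in injured persons per period; transfusion
  demand in units is `alpha * units_per_patient * demand` (`alpha` = 0.8 by
  default, one unit per patient). Unmet units accumulate as per-period
  shortage `IB_t`; the service-level constraint requires delivered units to
  cover at least a fraction `lambda` (default 0.7) of each period's
  transfusion demand. Because delivered + shortage equals demand exactly,
  the service level is algebraically an upper bound on the shortage, and the
  solver implements it that way.
* **Periods.** The default horizon is four periods of 24, 48, 72 and 168
  hours — the hyperacute day, the remainder of the first 72 hours, the rest
  of the first week's response, and the following week. Period lengths are
  metadata: the model is period-indexed, and capacities and demands are
  per-period quantities.
* **Objectives.** Cost = setup of newly opened candidates + transport
  (currency per unit-km on every arc, default 5000) + testing (currency per
  raw unit entering a center, default 5000). Shortage is reported both as
  total units and as the sum over periods of shortage/demand ratios. The
  unit count is the default optimization metric — shortages of thousands of
  units are what headline results are stated in — while the ratio sum, the
  literal "minimize the ratio of shortage to demand in every period"
  reading, is always evaluated and can be optimized instead
  (`objective = "shortage_ratio"`). Zero-demand periods contribute zero to
  the ratio by convention.
* **Scenario probabilities.** The three default severity scenarios carry
  probabilities 0.15, 0.35 and 0.5, read as fractions (they must sum to 1;
  a percent reading would not be a probability distribution).

### What is deliberately out of scope

Waiting-time and completion-time costs are named as a motivation in the
problem setting but have no formula or data to implement, so they are not
part of the cost objective. There is no blood-group compartmentalization, no
perishability beyond the single inventory pool, no routing (arc distances
are given, not derived from a road network), and no exact bi-objective
branch-and-bound — the multi-objective layer is scalarization-based
(weighted sums and epsilon-constraints), which is what the solution
procedure this package follows actually uses.

## Solving

### The built-in MIP solver

The models are solved by a branch-and-bound over a dense two-phase primal
simplex written for this package (`src/simplex.cpp`). That is an unusual
choice for an R package, and a deliberate one: the model sizes here
(hundreds of rows and columns; about 430 x 900 for the full three-scenario
default instance) are comfortably within dense-simplex territory, and
carrying the solver means the package has no external solver dependency and
its results are reproducible bit-for-bit.

Numerical safeguards, each of which was added because a test caught the
failure mode it prevents:

* **Geometric-mean row equilibration.** Rows are scaled by the geometric
  mean of their extreme coefficient magnitudes, so a row mixing unit and
  big-M coefficients keeps both ends representable above the pivot
  tolerance.
* **Harris-style two-pass ratio test.** The tightest ratio is computed with
  a small tolerance, then the pivot is taken on the largest eligible
  element among near-ties. Tiny pivots are what corrupt a long-running
  tableau; before this rule, degenerate instances could oscillate for 10^5
  iterations.
* **Clamped ratios.** Round-off can leave a basic value at -1e-9; a ratio
  computed from it must be treated as zero or the pivot steps the basis
  infeasible.
* **Sticky Bland's rule.** After 400 consecutive degenerate pivots the
  pricing switches to Bland's rule and stays there for the rest of the
  phase; switching back after escaping one degenerate vertex can re-enter
  the same cycle.
* **Trusted incumbents only.** In branch and bound, a relaxation solution
  whose binaries merely look integral is never accepted directly: the node
  is re-solved with the binaries hard-fixed at their rounded values. Under
  a large big-M, a binary at 1e-8 passes any integrality tolerance while
  still enabling real flow; the re-solve eliminates exactly this class of
  wrong answer.
* **Big-M tightening.** The solver's default ("tight") assembly folds each
  linkage into its capacity row (`sum_z QT_izt <= capa_it * X_i`), which is
  both the strongest LP relaxation and the best-conditioned matrix. The
  literal row-per-linkage assembly (`formulation = "bigM"`) clamps a
  user-supplied M per row to the tightest valid bound — a
  coefficient-tightening presolve that leaves the mixed-integer optimum
  unchanged. The test suite solves both formulations on random tiny
  instances and requires equal optima.

Branch and bound is depth-first with most-fractional branching, the
round-nearest child explored first, an initial incumbent from rounding the
root relaxation up (opening more facilities never removes feasibility), and
pruning at a relative gap of `mip_gap` (default 1e-6). All tie-breaks are
deterministic (lowest index), so identical inputs yield identical solutions.

### Infeasibility diagnosis

The only structural infeasibility is a service level that cannot be met. On
an infeasible solve the package re-solves with every candidate open and a
violation variable on each service-level row, minimizing total violation;
the periods (and scenarios) with positive violation are reported as the
irreducible cause.

### Multi-objective drivers

Individual optima first (`ideal_points()`); the weighted method normalizes
each objective by its ideal value floored at 1 — raw cost (~10^9) and raw
shortage (~10^2-10^4) are incommensurable and the source procedure states no
normalization, so ideal-point normalization is the package's choice. The
"weighted method with the cost objective as a constraint" is implemented
literally: scalarization plus an optional hard cost bound, independently
available. The epsilon-constraint front sweeps cost bounds equally spaced
between the cost optimum and the cost of the shortage-anchored solution; at
each bound the solver minimizes shortage and then, lexicographically,
re-minimizes cost at that shortage level so every reported point is extreme.
Objective-bound rows carry a relative slack of 1e-7 so that re-optimizing at
an attained optimum is never cut off by round-off. The result is filtered to
its non-dominated subset.

### The scenario model

Open decisions are first-stage and shared; flows, inventory and shortage are
recourse. Scenario multipliers apply to demand, to temporary-facility setup
costs (harsher conditions add excavation/shipping surcharges to mobile
units), and to capacities; other parameters are scenario-invariant. The
service level binds per scenario — the stricter reading of an ambiguous
choice, preferred because an expectation-only service level would let a
planner trade a catastrophic scenario against a mild one. "Robustness" is
realized two ways: the expectation model with a per-unit shortage fine
(which is what the fine-sweep analysis exercises, with 1,450,000 in the
default grid as the reference balance point), and an optional min-max mode
minimizing the worst scenario's cost-plus-penalty, implemented with a single
epigraph variable. No uncertainty sets are invented beyond the discrete
scenarios.

## The synthetic generator

The case study that motivates the default network shape published its data
only as figures, so no numeric dataset exists to load. The generator
therefore emulates the *shape* of that case: 8 temporary sites, 5 permanent
facilities (2 existing), 3 blood centers (1 existing) at 10^9 setup each,
5 candidate field hospitals, 4 periods, 3 scenarios with probabilities
0.15/0.35/0.5.

Where the case publishes a number, the profile pins it (alpha, beta, lambda,
vehicle capacity, unit costs, blood-center setup). Where it does not, the
profile fixes a realistic regime once:

* demand of 3000-4500 injured in the first day, decaying over periods as
  (1, 0.8, 0.6, 0.4) — front-loaded, matching the emergency framing;
* scenario multipliers growing with severity: demand x (1, 1.4, 1.8), setup
  x (1, 1.15, 1.3), capacity x (1, 1.1, 1.2);
* per-period capacities of 400-700 (temporary), 600-1100 (permanent),
  2000-3000 (center intake) and 1000-1600 (treatment) units, and distances
  of 1-30 km (urban scale).

These ranges were chosen so that the qualitative regime of the published
results is reproduced — in severe scenarios demand exceeds processing
throughput (shortages of hundreds of units, concentrated in period 1), the
service level remains attainable, blood centers are the expensive lever and
field hospitals are usually not worth their setup cost — and they are not
tuned further. What the generator does **not** emulate: road-network
distances (draws are uniform, not map-derived), spatial correlation between
capacity and demand, and the actual case demand counts. Tests passing on
synthetic instances therefore validate the *method* (optimality,
feasibility, monotonicity, reproducibility), not any claim about the real
case values.

`generate_tiny()` is the second generator: instances with at most 3 sites
per class, 2 periods, 2 scenarios, integer capacities and demands, small
enough that every facility configuration (at most 2^12) can be enumerated.

## Verification

Two independent routes establish ground truth, sharing no code with the
model assembly:

* **A residual checker** (`check_solution()`) that re-evaluates all 18
  constraint families plus nonnegativity and binarity directly from the
  instance data. Linkage families use the symbolic big-M semantics: any
  positive flow through a closed facility is a violation. The acceptance
  suite applies 18 single-family mutations to hand-built feasible solutions
  and requires each to be flagged in its own family.
* **Flow oracles** on tiny instances: for every facility configuration, the
  maximum deliverable volume is an augmenting-path max-flow on a
  time-expanded network (source, collection sites per period, center intake
  and pool nodes with pool-to-pool inventory arcs, treatment nodes, one
  demand node per period). The uniform testing loss `beta` is handled by
  unit rescaling: the whole network is measured in raw collected units,
  downstream capacities and demands are divided by `beta`, and delivered
  units are `beta` times the raw flow into the sink. This is exact because
  `beta` is a single multiplier applied at one layer — a gain-flow
  formulation is unnecessary. Service-level feasibility is a max-flow
  saturation check at sink capacities `lambda * alpha * demand`; because an
  augmenting path can traverse at most one sink arc forwards and none
  backwards, continuing to augment after the saturation check preserves the
  met lower bounds. The cost oracle solves each configuration's transport
  problem by successive-shortest-path min-cost flow delivering exactly the
  service-level requirement (costs are nonnegative, so delivering more
  never costs less).

The acceptance suite cross-validates the MILP against both oracles on 50
seeded tiny instances (exact equality for shortage units on integer data,
1e-6 relative for cost, agreement on infeasibility verdicts).

## Problem sizes and defaults used by the test suite

Unit and acceptance tests run on tiny instances (50 seeds for the oracle
cross-validation, 20 for the scenario-collapse identity) plus one full-scale
default-profile instance (21 sites, 4 periods, 3 scenarios; about 430 rows x
900 columns after assembly), which solves to optimality in seconds. The
epsilon-constraint front uses 4-5 grid points; the fine sweep uses the
8-point default grid. These sizes were chosen as the smallest that exercise
every code path meaningfully.

## Known limitations

* The dense simplex is not meant for instances orders of magnitude larger
  than the default profile; a sparse revised simplex would be the next step.
* `integral_vehicles` affects cost *evaluation* only (whole truck trips via
  `ceiling(flow / vehicle_capacity)`); the MILP always prices transport per
  unit-km. Optimizing with integer trip variables is not implemented.
* The flow oracles require tiny instances by design; at full scale the only
  verification is the residual checker (which is complete for feasibility,
  but optimality rests on the branch-and-bound).
* One printed linkage constraint in the source formulation carries an
  internally inconsistent quantifier; it is implemented as
  delivery-requires-open-destination, the only reading consistent with its
  companions, and not given any more specific meaning.
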