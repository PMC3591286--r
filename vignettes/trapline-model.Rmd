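---
title: "The traplining heuristic: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The traplining heuristic: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Trapline foraging — the development of stable, near-shortest circuits over a
fixed set of replenishing nectar sources — is the behavioural analogue of
the travelling salesman problem. `traplinesim` implements a minimal
iterative-improvement learning model of this process and the measurement
apparatus around it. This vignette is the package's own account of the
model: what is assumed, which readings of the verbal model were adopted
where more than one was possible, what the synthetic data do and do not
emulate, and where the numerical edges are.

## The model

A bee forages over a nest and $n$ flowers at fixed 2-D coordinates
(metres). Its state is a row-stochastic transition table over all $n + 1$
locations. The model's moving parts are:

1. **Prior.** The initial probability of the directed transition
   $i \to j$ is proportional to $1 / d(i,j)^{\,\alpha}$ with $\alpha = 2$
   (`distance_exponent`), normalised per origin row. The nest is an
   ordinary origin and target. The prior is invariant under rescaling all
   coordinates, so behaviour depends only on the array's *shape*; spatial
   scale enters the model exclusively through the enhancement factor.
2. **Bouts.** A bout starts at the nest and repeatedly samples the current
   row. Arriving at an unvisited flower empties it (one crop unit);
   revisits to emptied flowers are allowed, recorded and yield nothing.
   The bout ends when `crop_capacity` distinct flowers have been emptied
   (the bee then flies straight home), or as soon as the nest vector is
   sampled — an *early return* with an unfilled crop, the model's
   expression of incomplete early-learning bouts. A generous safety cap
   (`20 n` transitions) guards against degenerate tables; capped bouts are
   counted and reported so pathologies are visible.
3. **Route memory.** The remembered route of a bout is its *trapline
   skeleton*: the nest-to-nest circuit over the flowers in first-visit
   order. Revisit detours inflate the flight, not the remembered route;
   the route's **net length** is the skeleton circuit length. This is the
   quantity compared across bouts and the set of vectors that is
   reinforced. The alternative reading — comparing raw travelled length
   and reinforcing every sampled transition — is retained as
   `route_memory = "traversed"` in `run_bee()`; under it reinforcement
   spreads over revisit noise, bees lock onto wandering walks, and route
   quality stagnates far above the optimum, which is why the skeleton
   reading is the default.
4. **Reinforcement.** After a bout that filled the crop, if its net route
   length is **no longer than** the shortest net route experienced so far
   (ties reinforce — repeating the best route strengthens it), every
   directed transition of that route, including the return leg, is
   multiplied by the enhancement factor $f \ge 1$ and the affected rows
   are renormalised. With $f = 1$ the update is exactly the identity.
   Reinforcement is directional: traplines acquire a habitual direction.

Learning is thus a ratchet: the best-so-far route can only shorten, and
each repetition of it tilts the table further toward it, trading
exploration against consolidation through the single parameter $f$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `enhancement_factor` | 2 | — | reinforcement strength; "motivation to optimise". Around 1.1 reproduces hesitant metre-scale optimisation, 1.5–4 decisive field-scale optimisation. |
| `n_bouts` | 65 | bouts | one foraging day; 130 models two days without overnight memory loss. |
| `crop_capacity` | all flowers | flowers | distinct rewarding visits that fill the crop; smaller values induce flower-subset selection. |
| `distance_exponent` | 2 | — | steepness of the distance prior. |
| `reward_priority_boost` | 1 | — | multiplier on the initial nest-to-high-reward-flower entries; models prioritisation of a known rich site. |
| `max_transitions_per_bout` | `20 n` | moves | pathology guard only. |

## Optimality, stability, and the oracles

A bout is **optimal** when its flower visitation is revisit-free and its
skeleton circuit is as short as the exact optimum from the oracle module
(equality within a $10^{-9}$ relative tolerance, which also absorbs exact
geometric ties such as symmetric arrays; a circuit and its reversal have
identical length, so direction is ignored here). **Stability** is reached
at the third of three consecutive bouts with *identical* optimal
visitation orders — direction is deliberately not merged there, since an
established trapline is flown in a habitual direction.

The oracle side is exact: Held–Karp dynamic programming over visited
subsets (up to 15 flowers), verified against brute-force permutation
enumeration (up to 9), with deterministic lexicographic tie-breaking;
best-subset circuits enumerate $\binom{n}{k}$ subsets (up to $n = 12$).
For 20-flower instances no exact optimum is attempted; the all-pairs
transposition test — can exchanging two positions in the visitation order
strictly shorten the circuit? — serves as the upper-bound diagnostic. An
optimal route is never transposition-improvable, but the converse fails:
the test suite carries a frozen 6-flower instance whose transposition-
stable route is strictly longer than the optimum, which is why the
statistic bounds rather than certifies optimality.

## Adopted statistical conventions

Three published statistics are used whose exact formulas were not
available; each implementation is a documented convention with a pluggable
alternative:

* **Similarity index.** $SI(a, b)$ = (ordered flower-to-flower
  transitions shared between the two sequences, counted with
  multiplicity) / (the larger of the two transition counts). This is
  symmetric, lies in $[0, 1]$, scores disjoint sequences 0 and identical
  sequences 1, and accounts for both order and length. One caveat is
  inherent to any transition-multiset formula: distinct cyclic rotations
  of the same circuit share all transitions and also score 1. An
  alternative transition extractor can be supplied via the `transitions`
  argument.
* **Asymmetry index.** For each unordered flower pair with
  $N = n_{ij} + n_{ji} \ge 6$ recorded transitions, the two-tailed
  binomial probability $P = \min(1,\, 2\Pr(X \ge \max(n_{ij}, n_{ji})))$,
  $X \sim \mathrm{Bin}(N, 1/2)$, scored as $-\ln P$; the index is the mean
  score over tested pairs (so duplicating pairs changes nothing), and
  *undefined* — not zero — when no pair reaches the observation floor.
* **Empirical p-values.** $p$ = fraction of null-model values at least as
  poor as the observation, ties counting one half, clamped to
  $[0.5/m, 1]$ for $m$ null runs. An observation at the 70th-percentile-
  quickest position of the null scores exactly 0.3; drawing observations
  from the null itself yields a uniform $p$.

## The loop-search model

Search flights for a flower at (learned) distance $R$ are modelled as
out-and-back loops: uniform random bearing, exponential outward leg with
mean $\lambda$, continuous perception within radius $r$ along the outward
leg (closest-approach test; the retraced inbound leg cannot reveal
anything new), full retracing on failure. Requiring the longest loop to
reach the target about once — $m \Pr(\ell > R) \approx 1$ for $m$ loops —
gives $m = e^{R/\lambda}$ and a mean search path
$\langle L \rangle = 2\lambda e^{R/\lambda}$, minimised at
$\lambda^* = R$: loops much shorter than the flower distance almost never
arrive, loops much longer overshoot. The closed form is an extreme-value
estimate, so simulations are compared with it only up to the geometric
factor set by $r$ (the per-loop hit probability oracle in the tests) and
the optimum's robustness is checked, not its exact location, when the leg
family is swapped (gamma legs: simulated optimum within a factor two of
$\lambda = R$).

## Synthetic data: what it emulates, what it does not

All inputs are generated: polygon arrays (flight-room style regular
arrangements), uniform-random flowers in a square (the TSP cohorts),
clustered patch grids, a duplicated-coordinate flower pair standing in
for one doubly rewarding site, and three hand-authored 10-flower
geometries spanning the qualitative linkage types between proximity and
circuit structure (ring / jittered ring / interleaved double ring, nest
1.4 m away). The linkage fixtures are *synthetic approximations* — the
experimental coordinates they evoke were never published — and are used
only for ordering comparisons, never for quantitative reproduction.

Design choices worth knowing about:

* **Co-located pairs.** The zero-length within-pair hop receives the
  transition weight of the closest distinct pair of locations: likely, but
  not absorbing, and the inverse-square prior stays finite. Forbidding the
  hop instead (probability 0) makes the double site worthless to the
  model, because collecting both rewards would then require a paid detour.
* **Reward prioritisation.** The shipped `reward_priority` recipe uses
  `reward_priority_boost = 10`, strong enough that the rich site is the
  modal first stop. The prioritisation trade-off is then visible: the
  rewarding site's share of all flower visits falls steadily as the crop
  requires more flowers (from roughly 0.6 at a crop of 2 towards the
  uniform share as the crop approaches the array size). With weak boosts
  there is effectively no prioritisation and the trend dissolves into
  noise.
* **Patch grids.** Four patches of four flowers on the corners of a 4 m
  square (radius 0.6 m, nest 3 m outside) keep the within:between distance
  ratio mild enough that bees migrate between patches; with much tighter
  patches the inverse-square prior traps the walk inside a patch
  essentially forever. Route order is scored cyclically at both levels
  (perimeter order of patch centres; perimeter order of a patch's flowers),
  so both fractions share a chance level, and distance pressure separates
  them: patch-level order locks in, within-patch order barely does.
* **Pentagon experiments.** The nest sits 7 m below the pentagon's
  centroid. With the nest at the centroid every flower is equidistant from
  home, early returns dominate and stabilisation is suppressed; an
  external nest matches how such arrays are actually laid out.

Passing tests on these generators show that the *mechanism* — prior +
selective reinforcement — produces trapline formation, scale-dependent
optimisation, configuration-dependent stability and subset selection. They
do not show that real bees share the model's parameter values, nor do the
fixtures reproduce any particular laboratory array.

## Numerical choices

Optimality tolerance $10^{-9}$ (relative); transposition improvements must
exceed $10^{-9} \cdot \max(1, L)$ to count; oracle tie-breaks are
lexicographic with circuits canonicalised to the smaller of the two
directions; uniform-random arrays resample below a minimum separation of
`patch_side / 1000`. One master seed drives everything: cohorts draw
per-bee seeds once up front, so results are independent of evaluation
order; the compiled and pure-R simulation paths consume the RNG stream
identically (same accumulation order in the categorical draw) and are
asserted bit-identical in the tests. Simulation sizes in the checks are
30 arrangements × 30 bees for cohort statistics and a few hundred bees for
fixture cohorts — large enough that the reported fractions move by at most
a few percent between seeds, small enough to run in seconds.

## Known limitations

* The model has no energetics, handling time, competition, overnight
  memory decay or continuous flight paths; transitions are straight lines
  between point locations.
* Under the adopted tie-reinforced skeleton memory, 10-flower arrays
  essentially never stabilise within 65 bouts at enhancement factors of
  about 1.1 — the linkage-type ordering of stable fractions emerges
  clearly at 1.5 but degenerates to ties at zero at 1.1 (the ordering of
  *finding* the optimum at least once still holds there). A per-bout
  consolidation variant that replays the remembered best route does
  stabilise at 1.1, but it over-commits at factor 2, inverting the
  factor–stability relationship and collapsing subset-selection success;
  it was therefore rejected.
* The greedy nearest-neighbour reference averages about 10% above the
  optimum on 10-flower uniform arrays (the acceptance script's cohorts sit
  a few points above that), not the ~25% excess familiar from large
  instances: at $n = 10$ greedy is simply not that bad, under any nest
  placement we tried.
* Best-found 20-flower routes remain transposition-improvable in
  essentially 100% of runs after both one and two simulated days at the
  shipped cohort sizes: at 20 flowers the model converges towards, but in
  practice never onto, transposition-stable routes.
* The similarity index cannot distinguish cyclic rotations (above), and
  the asymmetry and similarity formulas are conventions, exposed as
  pluggable functions.
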