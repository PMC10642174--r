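---
title: "Decisional-logic models of bio-behavioral networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decisional-logic models of bio-behavioral networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declogic)
```

## The model and its assumptions

`declogic` analyses directed, signed regulatory networks over three kinds
of node — molecular mediators, behavioral constructs, and at most one
exogenous stressor — under a four-level discrete logic. A state assigns
every node a level in `{0, 1, 2, 3}` (Low, Moderate, Severe/High, Very
Severe/Very High). Each edge `e : j -> i` carries a sign (activation or
inhibition), a *perception threshold* `tau_e` (the minimum source level at
which the target perceives the edge) and a positive integer *weight*
`w_e` (its influence). The perceived input of node `i` is the signed
weighted count of its perceptible regulators,

$$u_i(x) \;=\; \sum_{e:\,j\to i} s_e\, w_e\, \mathbf{1}[x_j \ge \tau_e],$$

and on the next iteration `i` moves one level toward the sign of `u_i`,
saturating at 0 and 3. This is a multilevel logical model in the Thomas
tradition; the threshold-and-weight pair per edge is the *decisional
logic* by which a node arbitrates, say, a weak inhibitor perceived at
moderate severity against a strong activator perceived only at high
severity.

Modelling assumptions worth making explicit:

* **Gradual kinetics.** A node moves at most one level per iteration.
  Multi-level jumps are never generated, which rules out some oscillations
  a jump semantics would allow (a consequence explored in the engine test
  suite: a plain two-node negative feedback loop relaxes to a fixed point
  here, and sustained oscillation requires delayed feedback).
* **Additive arbitration.** Competing inputs combine by weighted addition;
  any context-specific arbitration must be expressed through the fitted
  per-edge weights and thresholds, not through extra rules.
* **Synchronous default.** The update scheme is synchronous, which makes
  the dynamics a deterministic total function on the `4^N` state space, so
  predecessors, fixed points and attractors are well defined and the
  constraint-satisfaction fit has clean semantics. Asynchronous updating
  (one uniformly chosen non-quiescent node per step, under the R RNG) is
  retained for fidelity to the formalism but attractor classification is
  only meaningful for the synchronous scheme.
* **Ties.** A balanced input (`u_i = 0`) holds the current level by
  default (`hold`); the `decay` option lets unsupported activation relax
  one level toward baseline. Hold is the default because the motivating
  two-regulator motif (an inhibitor perceived at moderate severity versus
  a heavier activator perceived only at high severity) behaves as intended
  under it; decay is strictly more dissipative and, notably, can hold no
  interior level fixed.

## Parameters, domains, defaults

| parameter | domain / default | rationale |
|---|---|---|
| levels | `{0..3}`, fixed | the qualitative severity scale of the data |
| `tau_e` | `{1, 2, 3}` | all meaningful thresholds on a 4-level scale |
| `w_e` | `{1, 2}` default | the smallest domain that can express "more influence of one regulator over another"; configurable upward |
| tie rule | `hold` | see above |
| update | `synchronous` | see above |
| stressor | clamped pulse: level 3 for 4 steps, then 0 | an acute exogenous insult followed by withdrawal; both knobs configurable |

Polarity is handled at ingest: behavioral function scales (higher =
better) are reversed (`3 - level`) so that inside the engine every node is
severity-like. A consequence worth noting: the idealized control —
minimal severity, maximal function — becomes the all-zero engine state,
which under either tie rule and `tau >= 1` is a fixed point of *every*
logic program. The required "stable resting state" for the control is thus
structural; it anchors the reachability mode below but does not prune the
parameter search.

## Fitting as constraint satisfaction

`fit_program()` searches per-edge `(tau, w)` assignments minimizing the
aggregate Manhattan departure between observed behavioral profiles and
*dynamically consistent* full states (departure is reported as a fraction
of the maximal misalignment, 3 per construct; per-subject denominators
are `3 x 9 = 27` and the group denominator `3 x 9 x 6 = 162` at the
study's dimensions). What "consistent" means is configurable, because a
cross-sectional snapshot underdetermines it:

* `has_predecessor` (default): the full state must be reachable in one
  step from some state — the weakest reading under which a snapshot is
  a legal instant of an ongoing process. Garden-of-eden states are
  excluded.
* `fixed_point`: the full state maps onto itself — the persistence
  reading, used by `persistence_test()` together with an exact-match
  budget (`max_departure = 0`).
* `on_attractor_path`: trivially true under synchronous updating; kept
  for the asynchronous variant.
* `reachable_from_rest`: the state must lie on the stressor pulse-response
  trajectory started at the control fixed point. This is the generative
  reading — it is how the synthetic studies are actually produced — and
  the one used for the headline analysis fits.

The default mode is deliberately the weakest: it makes the fewest claims
about unobserved history. Its cost is degeneracy of the *hidden* states:
because a predecessor's free coordinates can place almost any level on a
molecular node, the departure-optimal completions usually span all four
levels at hidden nodes weakly coupled to the observation. The package is
explicit about this: imputations report every optimal state (up to a cap),
an exact per-node table of attainable levels, and a modal state (ties
resolved toward the lower level). Downstream statistics use the modal
state; recovery experiments additionally score whether the planted level
is *among* the attainable optima. The `reachable_from_rest` mode, by
contrast, pins hidden states to the response trajectory and is the mode
under which differential-marker analysis is scientifically meaningful —
the analysis drivers compare modes side by side on a study small enough
for exact enumeration.

### Search strategies and exactness

Three searches cover the size spectrum. `exhaustive` sweeps the full
program grid (feasible below `exhaustive_cap`, default `2e5` programs) and
returns the exact optimum, all tied optimal programs, and the exact count
of programs within the feasibility budget. `backtracking_propagation`
first prunes per-edge domains by a per-target-node relaxation (only active
in the exact fixed-point setting, where observed levels are pinned), then
sweeps the surviving grid; an empty propagated space is a proof of
infeasibility. `local_search` is seeded multi-restart first-improvement
hill climbing with bounded sideways moves, used above the cap.

Every state-space search is an exact depth-first enumeration with
branch-and-bound on departure, ordered so that observed nodes and their
regulators are assigned first, under a node-expansion budget (default
`1e7`). A search that exhausts its budget returns its incumbent flagged
`exact = FALSE`; results never silently degrade. On 10-node studies
(`4^10` states) all searches are exact in well under a second; exact
predecessor-space imputation does not scale to the 39-node study, which is
why the full-scale fits use the trajectory-based reachability mode (cost
linear in trajectory length) and the mode comparison runs at 10 nodes.

`persistence_test()` adds a sound infeasibility proof that scales to any
size: a source observed at level 3 is perceived under every threshold, so
its edges contribute irreducibly; if for some subject and observed node no
achievable input sum is compatible with holding that node's level —
a subset-sum check over forced versus optional contributions — then no
program in the domain can make every subject persist. When neither the
proof nor an exhaustive sweep is affordable, the budgeted search's verdict
is reported with `proven = FALSE`.

## The synthetic-study generator

`generate_study()` emulates the structure of the text-mined study this
package is organized around, with known ground truth:

* **Topology.** 29 molecular + 9 behavioral nodes + 1 stressor and 273
  distinct directed edges (density `273/1482 ~ 18.4%`). A random spanning
  cycle over the non-stressor nodes guarantees the no-source/no-sink
  closure invariant by construction (rejection sampling would essentially
  never produce it at this density); the stressor gets out-edges only.
  Edge signs are inhibitory with probability 0.3 (a typical curated-network
  proportion; configurable).
* **Evidence.** Citation counts per edge follow
  `max(1, round(exp(N(log 9, 1.8^2))))`: sample median 9, about 15% of
  edges at a single citation (the low-confidence flag), a few percent
  beyond 125 — matching the qualitative evidence profile of large
  text-mined networks.
* **Subjects.** Every subject starts at the resting control fixed point,
  receives the stressor pulse (level 3, 4 steps at full scale; 3 steps in
  the 10-node preset), and evolves under a planted program drawn uniformly
  from the fitting domains. One snapshot time per subject is drawn from
  `snapshot_window` (default steps 2-12, i.e. across the whole active
  response), and the behavioral restriction of that state is observed.
  Observation noise, when enabled, is post-hoc one-level jitter at rate
  `noise_rate` — the planted dynamics stay exact.

Bundles are bit-for-bit reproducible from their seed. What the generator
does *not* emulate: the real network's specific topology and sign pattern,
correlated measurement error, instrument-specific binning of raw scores,
inter-subject heterogeneity in exposure (all subjects share one pulse and
one program), and any molecular ground truth for real subjects. Passing
the recovery suite therefore shows that the pipeline is *internally
correct* — it recovers what it is defined to recover on data generated by
its own model class — not that the model class is adequate for any
particular clinical dataset.

## Numerical and degenerate-case choices

* **Discretization** of instrument scores uses four equal-width bins with
  a floor and a top clamp (`min(3, floor(4 (x - lo)/(hi - lo)))`): the
  simplest range normalization that is monotone and surjective onto the
  four levels. Bin edges are per-instrument configuration, not code.
* **Zero-variance t-tests** are expected with 4-level data (unanimous
  predictions across six subjects). They are handled explicitly: mean
  equal to the reference gives `t = 0, p = 1`; a unanimous difference is
  flagged `degenerate` with `p = 0` plus a warning — a unanimous shift is
  maximal evidence at this resolution, and silently dropping such markers
  would bias the table toward noisier ones. The BH step-up then treats
  them like any other p-value.
* **Modal-state ties** resolve toward the lower level (toward the resting
  baseline), a conservative choice for severity-like quantities.
* **Duplicate edge rows** collapse by summing citation counts (merged
  exports), configurable to `max`; conflicting signs for one ordered pair
  are an error naming the pair rather than a silent resolution, since the
  model admits one mode of action per interaction.
* **Clustering** is computed on the undirected projection by default (the
  convention of the GUI tools typically used for such networks), with a
  directed variant behind a flag; closeness uses the Wasserman-Faust
  reachability correction because directed biological networks are rarely
  strongly connected; betweenness excludes endpoints and normalizes by
  `(N-1)(N-2)`.

## Problem sizes used in validation

The test and acceptance suites run at sizes where independent brute-force
oracles are exact: engine equivalence on 500 random systems of up to 6
nodes against full `4^N` enumeration; fitter equivalence on 50 toy
instances (at most 5 edges, 4 hidden nodes) against naive
program-by-program enumeration; recovery on 20 planted noiseless 10-node
studies with 6 subjects (aggregate departure must be exactly 0, and the
planted hidden level must be among the attainable optima for at least 90%
of hidden node-subject pairs); persistence discrimination on exhaustively
enumerable 6-node/6-edge bundles, attractor-sampled versus
transient-sampled. The analysis drivers state their own sizes: the
full-scale study is fitted under reachability, and the consistency-mode
comparison runs on the 10-node companion study where all modes are exact.

## Known limitations

* Exact predecessor-space imputation is exponential in the number of
  hidden nodes; above the budget the package degrades to flagged
  incumbents rather than refusing, and the trajectory-based mode is the
  practical tool at full scale.
* The persistence verdict at full scale is only as strong as its proof:
  when the balance argument does not fire and the grid is unsweepable, a
  budgeted miss is evidence, not proof, and is labelled so.
* Local search carries no optimality guarantee; it is validated against
  exhaustive sweeps on small instances and used with multiple restarts.
* One shared program is fitted across all subjects (per-subject programs
  would be trivially overparameterized at `n = 6`); heterogeneity between
  subjects is absorbed entirely by snapshot time and hidden states.
* The asynchronous scheme has no attractor theory here; trajectories under
  it are sampled walks.
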