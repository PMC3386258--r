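---
title: "Weighted network prediction of gene function: model, optimizer, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted network prediction of gene function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wnp)
```

## The annotation problem

A probabilistic functional network (PFN) is an undirected graph over gene
products whose edges carry positive log-likelihood scores (LLS): the weight
of edge $(i,j)$ measures the confidence that $i$ and $j$ are functionally
associated. Given such a network and a partial GO-slim annotation — each
*characterized* node carries a non-empty set of function terms, the rest are
*uncharacterized* — direct annotation schemes predict functions for the
uncharacterized nodes from their network context.

## The weighted Potts objective

`wnp` assigns every uncharacterized node $i$ a single label
$\sigma_i$ from the term alphabet and scores the assignment by

$$E(\sigma) \;=\; \sum_{(i,j)\,\in\,E_{uu}} w_{ij}\,\delta(\sigma_i,\sigma_j)
\;+\; \sum_i h_i(\sigma_i),$$

where $E_{uu}$ is the set of edges between uncharacterized nodes (each
unordered pair counted once) and $h_i(f)$ is the summed weight of edges from
$i$ to characterized neighbors annotated with $f$. A multi-label neighbor
contributes its full edge weight to each of its terms. With all weights set
to 1 the objective degenerates to counting same-labelled edges — the
classical binary assignment scheme, kept here as the `sa` baseline with
classical Metropolis annealing, so the WNP/SA comparison isolates exactly
the weighted-objective-plus-schedule difference.

The assumption behind both is guilt by association: functionally linked
gene products tend to share annotations, and heavier (more confident) edges
should count for more. The model keeps $\sigma$ single-valued during
optimization; multi-label *predictions* emerge from the ensemble layer
below, and multi-label *truth* is handled by the evaluation rules, never by
$\delta$.

## Generalized simulated annealing

`gsa_optimize()` maximizes $E$ (equivalently, minimizes $-E$) with the
Tsallis–Stariolo generalized annealing schedule. Schedule time $s$ advances
once per sweep (one proposed move per uncharacterized node) and the visiting
temperature is

$$T_{q_v}(s) = t_0\,\frac{2^{\,q_v-1}-1}{(1+s)^{\,q_v-1}-1},$$

with acceptance temperature $T_a = T_{q_v}(s)/s$. An uphill move of cost
$\Delta C > 0$ is accepted with probability
$[1+(q_a-1)\Delta C/T_a]^{1/(1-q_a)}$ (zero when the base is non-positive);
$q_a \to 1$ recovers the Metropolis rule.

Three adaptations make this continuous-space machinery effective on a
discrete Potts state space:

* **Proposal kernel.** The heavy-tailed visiting distribution has no direct
  discrete analogue. With probability $T_{q_v}(s)/t_0$ (hot phase) the
  proposed label is uniform over the full alphabet — a global move; otherwise
  it is uniform over the node's *candidate set*: terms with positive field
  $h_i$ plus the current labels of its uncharacterized neighbors (full
  alphabet if that set is empty, preserving ergodicity). Only candidate
  moves can change the score, so the cold phase wastes no proposals.
* **Reannealing cycles.** The power-law schedule cools essentially to zero
  within $\sim$100 sweeps; a long chain therefore wraps schedule time every
  `cycle_sweeps` (default 100) sweeps and re-heats from its current state.
  A chain of $10^4$ sweeps is thus a sequence of anneal cycles rather than
  one anneal followed by a long greedy tail.
* **Temperature scale.** With $q_a = -5$ the generalized rule accepts uphill
  moves only up to $\Delta C < T_a/6$, so $t_0$ sets the largest climbable
  barrier. On the LLS scale (weights roughly 0.1–10) single-move barriers of
  several units are routine, and $t_0 = 40$ (hottest barrier $\approx 6.7$)
  makes a single default-length chain match an exhaustive oracle on 100/100
  small random instances, versus 88/100 at $t_0 = 10$. All schedule
  parameters (`q_v = 2.7`, `q_a = -5`, `t0 = 40`, `cycle_sweeps = 100`) are
  exposed in `gsa_config()`.

Chains start from the greedy field signal (each node at the argmax of
$h_i$, ties broken from the seed; `init = "random"` is available), run for
`n_steps` moves (default $10^4 \times$ number of uncharacterized nodes,
capped at $2\times10^5$ — the cap reflects that on the planted-network sizes
used throughout, best scores stop improving well before that), and return
the best state ever visited, not the final state. The best-so-far trajectory
is recorded and is non-decreasing by construction; the reported score is
always recomputable with `weighted_score()`.

`exhaustive_optimize()` enumerates all $|A|^n$ assignments (refusing above a
cap, default $10^6$) with lexicographic tie-breaking; it exists as the
deterministic oracle against which the annealer is tested, never as the
production path.

## Ensemble consensus

`wnp_predict()` runs `n_restarts` (default 20) independent chains with seeds
derived from the master seed and scores each (node, term) by the fraction of
restarts whose best assignment used it. Confidences per node therefore sum
to 1, and near-optimal alternative labellings surface as genuine multi-label
predictions. Frequency voting was chosen over best-run-only or
score-weighted voting: it is the restart analogue of sampling near-optimal
solutions, degrades gracefully (one restart gives exactly one prediction per
node at confidence 1), and yields calibrated-looking thresholds for the
evaluation sweep.

## The comparison algorithms

* `sa` — the unit-weight objective under classical Metropolis annealing with
  geometric cooling (ratio 0.995 per sweep), sharing the restart-consensus
  layer.
* `ff` (FunctionalFlow) — every annotated node is an infinite source of
  per-function flow; each iteration (default 6) flow moves only downhill,
  splits across eligible edges proportionally to weight, and is capped per
  edge by the weight; a node's score is its cumulative inflow. The
  eligible-edges-only denominator is this package's reading of the
  proportional split; the per-function dispensed/received totals are
  returned for audit.
* `chis` — chi-square neighborhood scoring
  $S(f) = (n_f - e_f)^2/e_f$ over the characterized members of the
  `n_hop`-neighborhood (default 1 hop), with $e_f$ from the network-wide
  term frequency among characterized nodes; terms with $e_f = 0$ are
  skipped.
* `wa` — FS-similarity weighted averaging over the 1- and 2-neighborhood,
  with closed neighbor sets, smoothing constant $\lambda$ (default 0)
  exposed, and 2-hop contributions down-weighted by inverse distance.
* `pc` — the weighted-average scheme: the fraction of a node's
  characterized-neighbor edge weight supporting each function. Of the
  readings compatible with its one-line descriptions in the literature this
  package implements the weighted-fraction form; nodes with no
  characterized neighbor receive no predictions.

All six return the same tidy `prediction_set`, so the harness treats them
uniformly.

## Evaluation conventions

**TP/FP rule.** A gene's thresholded prediction set is a true positive iff
*more than half* of the predicted terms are correct (exactly half is a false
positive). TPR and FPR share the denominator "genes to be predicted", so
TPR + FPR is the classified coverage.

**ROC sweep.** `roc_and_auc()` sweeps the threshold over observed scores
from the most confident down to the per-simulation threshold — the largest
value leaving every covered gene at least one prediction
(`select_threshold()`), which is where coverage first reaches its maximum.
Sweeping further only dilutes prediction sets with low-confidence terms
until the majority rule marks *every* gene FP: under that continuation a
random two-function predictor scores $\approx 0.25$ and even strong
propagation methods collapse toward $0.5$, which measures the dilution
artefact rather than ranking quality. Stopping at the coverage point gives
the expected calibration (a perfect single-guess predictor scores 1, a
random one $\approx 0.5$).

Under the majority rule a gene can flip TP→FP as lower-scored wrong terms
enter its set, so the raw sweep need not be monotone in either coordinate;
integration points are sorted by (FPR, TPR). With full coverage the last
point connects to (1, 1); with partial coverage (some genes never receive a
prediction, as happens for `pc`/`chis`) the curve extends horizontally to
FPR = 1 and the area is normalized by the attained coverage
(`mode = "connect"` disables both the normalization and the distinction).

**SR vs FD.** At the per-simulation threshold, predictions are grouped by
the target's functional degree — its number of characterized direct
neighbors *after* masking, i.e. the information actually available — and
each bin reports its success rate. SR is per-prediction by default
(successes / predictions, matching the SR definition); `success_unit =
"gene"` applies the majority rule per gene instead.

**Benchmark.** `run_benchmark()` derives one mask per (fraction, replicate)
from the master seed — every algorithm sees the identical mask — then
derives a separate seed per algorithm for the stochastic ones. Failures
abort a single cell with a warning and an `NA` row, so partial coverage is
explicit. The candidate alphabet is taken from the full (pre-masking)
annotation map: in real use the GO-slim alphabet is known a priori, and
masking should not shrink the label space.

## The synthetic generator

`generate_planted_network()` emulates a PFN plus its annotation table with a
planted partition: within-module pairs connect with probability `p_in` and
weights from a log-normal with median 2.0 (sdlog 0.5), between-module pairs
with probability `p_out` and median 0.5 — positive, right-skewed values on
the LLS scale. Every node carries its module's term, plus one uniformly
random extra term with probability `multi_label_rate` (default 0.2, a
realistic multi-annotation rate for GO-slim tables), so multi-label truth
and annotation noise are both represented. `clear_annotations()` masks
whole genes (all terms at once), exactly `round(fraction × n)` of them with
half-up rounding so replicate counts are platform-stable.

What the generator does *not* emulate: scale-free degree distributions, the
systematic hub/periphery structure of real PFNs, correlated evidence between
edges, ontology structure among terms, or annotation bias toward
well-studied genes. Passing tests on planted modules therefore demonstrates
the machinery's correctness and the algorithms' relative behavior under a
clean block signal — not absolute performance on YeastNet- or AraNet-scale
data, which the I/O layer can load but which ship no fixtures here.

## Problem sizes used by the tests and the acceptance script

The standard benchmark instance is 500 nodes in 5 equal modules with
`p_in = 0.2`, `p_out = 0.02` — dense modules with a strong weight contrast,
where annotation recovery should be (and is) essentially perfect at a 10%
mask. The degradation study intentionally uses a different design: 400
nodes, 8 modules, `p_in = 0.08`, `p_out = 0.01` — mean within-module degree
around 4 — because information loss only bites when characterized anchors
are scarce; on the dense design the pair term alone reconstructs whole
modules even at 90% clearing and the success curve sits at 1.0 everywhere,
expressing nothing. Cross-validation grids run 5–10 replicates per fraction;
means and standard deviations are reported and the monotonicity of the
degradation curve is asserted statistically (multiplicity-adjusted noise
band) rather than pointwise.

## Numerical choices and degenerate inputs

* Duplicate edge rows with identical weight collapse with a warning;
  conflicting weights are an error (silently taking a max or mean would
  corrupt scores). Self-loops and non-positive weights are errors.
* Identifiers are raw case-sensitive strings; no ORF/alias resolution.
* Annotated genes absent from the network are kept in the map but excluded
  from the characterized partition; they cannot influence scoring.
* Isolated uncharacterized nodes carry no signal: the annealer's symmetric
  treatment leaves them with near-uniform consensus confidences, and
  neighborhood-based baselines simply omit them.
* An empty uncharacterized set yields an empty assignment with score 0; an
  empty alphabet is an error.
* Exhaustive enumeration tie-breaks lexicographically by (node, term);
  annealing tie-breaks fall to the seeded RNG.
* All replicate and restart seeds derive from the master seed through a
  counter-based mix, so any single cell of a grid can be re-run in
  isolation.

## Known limitations

Only direct (1-hop) neighbor information enters the objective; level-2/3
extensions and module-assisted (clustering) schemes are out of scope. The
optimizer's defaults are calibrated for LLS-scale weights; networks on very
different weight scales should adjust `t0` accordingly (it absorbs the
scale of climbable barriers). The evaluation harness assumes the held-out
truth is itself complete — in real annotation data, "false positives" may
simply be not-yet-curated truths.
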