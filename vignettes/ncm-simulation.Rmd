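---
title: "Simulating regulatory knowledge maps: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating regulatory knowledge maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmsim)
```

## The model

ncmsim simulates *fuzzy/neutrosophic cognitive maps* (FCM/NCM): qualitative
models of gene-regulatory knowledge in which N concepts (genes, proteins,
miRNAs, phenotypes) are linked by a sparse, signed N×N relationship matrix
W. Cell `W[i, j]` is the causal strength of concept *i* on concept *j*, a
dimensionless value in [−1, +1]; curated relationships are typically ±1
unless a fractional strength is documented. The neutrosophic extension
additionally admits an *indeterminate* relationship, written `I` — a
documented interaction whose direction/strength is unknown. Before
simulation, indeterminate entries are resolved to zero (`to_fuzzy()`): they
contribute no signal, and zero is represented as "no edge".

The system state is a vector x ∈ [−1, 1]^N, one activation per concept. The
dynamics are a synchronous recurrent iteration:

    x_{t+1} = f(Wᵀ x_t),      f(u) = u / (1 + |u|)   (Elliott squashing)

followed by clamping of *locked* nodes to exactly ±1. There is no implicit
self-memory: a node's next value is determined solely by its weighted
inputs, so persistence must be wired as an explicit self-loop. Weights are
never updated — the "learning" is state relaxation toward an attractor, not
weight optimization.

An experiment (a `simulation_protocol`) specifies:

* **on / off nodes** — set to +1/−1 for the *first* iteration only,
  modelling a transient intervention (e.g. transfection of reprogramming
  factors); all subsequent values are determined by system behaviour.
* **locked_on / locked_off nodes** — clamped to +1/−1 at *every* iteration,
  modelling constitutive overexpression or knockout (e.g. MECP2 locked off
  to model Rett syndrome).

Convergence is declared at the first iteration whose mean squared error
(MSE) between successive state vectors — always computed on squashed
states — falls below the tolerance (default 0.001). The converged values are
classified by sign: > 0 expressed/upregulated, < 0 repressed/downregulated
(`classify_state()`), and scored against an expected-outcome panel with an
exact binomial test whose null is the network's own sign bias
(`evaluate_predictions()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tolerance` | 0.001 | MSE threshold declaring a steady state (dimensionless, on squared activation units) |
| `max_iterations` | 1000 | iteration cap; also the horizon of the overtraining check |
| `overtraining_check` | `TRUE` | keep iterating after first convergence and flag any MSE rebound ≥ tolerance |
| `activation` | `"elliott"` | `x/(1+|x|)`; `logistic-symmetric` (`2/(1+e^{-x})−1`) and `hyperbolic-tangent` are selectable but non-default |
| pretest probabilities | computed from the map | fraction of positive/negative determinate edges; override with `pretest = c(0.66, 0.34)` for cross-map comparability |

The Elliott function is the default because its relaxation is fast and its
fixed-point algebra is simple: for a node with unit self-loop and constant
drive c, the steady state solves x = (c + x)/(1 + c + x) in closed form.
The engine exposes this through `generate_planted_attractor_map()`, which
plants drive c = (g−1)²/g so the attractor is exactly (g−1)/g for an
"effective loop gain" g — an analytic oracle for the whole pipeline.

## Statistical validation under a biased null

A naive binomial test at p = 0.5 would overstate significance on a network
biased toward activation. The validation test therefore uses the network's
*pretest probabilities*: with a fraction p₊ of positive edges, a positive
prediction is assumed to occur by chance with probability p₊ (and a negative
one with 1 − p₊). Modes:

* `all_success` (k = n): p₊ⁿ — probability that *every* prediction agrees by
  chance. This applies p₊ uniformly even to expected-down entries, matching
  the convention under which an 11-gene mixed panel has p = 0.66¹¹ ≈ 0.01.
  A stricter per-sign alternative (p₊ for expected-up, p₋ for expected-down,
  an exact Poisson-binomial null) is available via `null = "per_sign"` and is
  always smaller for mixed panels.
* `point_mass` (default for k < n): C(n,k)·p₊ᵏ·(1−p₊)ⁿ⁻ᵏ. This is what a
  16-of-17 agreement at p = 0.0075 corresponds to; the conventional
  `upper_tail` P(K ≥ k) is exposed and recommended for new analyses (it is
  the quantity with the usual frequentist guarantee).

Predictions that converge to exactly 0 (nodes with no inputs and no clamp)
carry no signal; they are excluded from n and reported separately rather
than silently counted either way. All probabilities are computed exactly in
log space; no normal approximation is used anywhere.

## What the synthetic generator emulates — and what it does not

`generate_random_map()` reproduces three shape statistics of a large curated
stem-cell signalling database: node count (3,589), edge count (27,566 —
hence mean in- and out-degree ≈ 7.68), and the 0.66/0.34 positive/negative
sign bias. Edge *placement* is uniform at random: no hubs, no motifs, no
degree correlations, no feedback-loop enrichment. A green test on generated
maps therefore establishes the mechanics (sparse iteration, bookkeeping,
statistics) at realistic scale, not that the dynamics on a real curated
topology would behave comparably — hub-heavy networks can have markedly
different attractor structure. Edge counts are exact by construction
(sampling cells without replacement); sign fractions are binomial draws, so
they concentrate at the target only as the edge count grows (±0.02 at 10⁴
edges).

The toy stem-cell fixture (`toy_stemcell_fixture()`) is openly fictional
wiring over real marker names: a mutually reinforcing 4-factor core (each
pair plus self-loops at +1, settling at 0.75 after transient activation)
drives a 15-marker pluripotency panel; a MECP2 node represses a 9-gene panel
and activates a 2-gene panel, so locking it off reproduces a 9-up/2-down
signature. It demonstrates that the pipeline reproduces the *experiment
designs* and their p-values (0.66¹⁵ ≈ 0.002, 0.66¹¹ ≈ 0.01); it makes no
biological claim, and its files say so in a header comment.

## Numerical choices and degenerate inputs

* **Matrix orientation.** Rows are sources, columns targets — the
  conventional FCM adjacency reading; stated in the CSV format docs since
  the transpose is an easy silent error.
* **Clamp ordering.** Locks are applied after activation, so a locked node
  holds exactly ±1 and feeds exactly ±1 downstream; "locked off" means the
  value cannot move at all.
* **Convergence accounting.** The MSE at iteration t compares x_t with
  x_{t−1}; `iterations_to_converge` is the 1-based index of the first MSE
  below tolerance. A zero-edge map with any transient initialization
  converges at iteration 2 (the first step zeroes everything, the second
  repeats it exactly).
* **`final_state` is the state at loop exit.** With the overtraining check
  on, iteration continues to `max_iterations`, and the reported state is the
  fully relaxed one. This matters: MSE < 0.001 bounds the *step
  displacement*, not the distance to the fixed point — for a slow attractor
  (local contraction factor 1/g² with g = 1.25, i.e. 0.64 per step) the
  state at first tolerance crossing can still be ~0.05–0.1 away from the
  attractor. Reporting the relaxed state makes planted-attractor recovery
  accurate to machine precision instead.
* **Overtraining flag.** Operationalized as: after first convergence, any
  later MSE ≥ tolerance. The canonical failure it catches is *false early
  convergence*: a near-zero start in a locally unstable loop (e.g. a mutual
  +1/−1 pair with unit self-loops and a weak locked driver) produces a tiny
  first step, "converges", then the oscillation grows until squashing
  saturates. A plain mutual +1/−1 pair without self-feedback spirals
  monotonically into its fixed point and — correctly — does not trip the
  flag.
* **Sign antisymmetry.** Because f is odd and the update is linear before
  squashing, negating the initial and clamped values (swapping on/off and
  locked_on/locked_off, W unchanged) negates the whole trajectory *bit
  exactly* in IEEE arithmetic; the test suite asserts this with
  `expect_identical()`. (Negating the weights as well does not negate the
  trajectory — the two sign flips cancel in the first step.)
* **Exact zeros.** A node with no inputs and no clamp is exactly 0 from the
  first iteration onward; the classifier maps exact 0 to `indeterminate`
  rather than guessing a direction.
* **Weights outside [−1, 1] in input files are a hard error**, not clamped:
  silent clamping would mask curation mistakes. Labels are matched
  case-sensitively (gene symbols are case-meaningful); the `I` token is
  case-insensitive and whitespace-trimmed because relationship CSVs are
  hand-edited.
* **Numbers in CSV output** are written with 17 significant digits, so a
  save/load round trip reproduces weights bit-for-bit and reruns are
  byte-identical.

## Known limitations

* The update is synchronous and deterministic; asynchronous or stochastic
  schedules, which can change attractors of signed networks, are out of
  scope (the `seed` protocol field is reserved for such extensions).
* The generator matches mean degree only; no attempt is made to match a
  degree distribution, which is unpublished for the emulating database.
* Partial-agreement p-values default to the point mass for compatibility
  with the published convention; for inference purposes prefer
  `mode = "upper_tail"`.
* No multiple-testing correction is applied across panels.
* The full neutrosophic triple (T, I, F) is reduced to a scalar-or-`I`
  representation; the T and F components are never separately exercised by
  the simulation, so only the scalar form is implemented.

## A worked run

```{r example}
fx <- toy_stemcell_fixture()
res <- run_simulation(fx$map, fx$protocols$rett)
res
report <- evaluate_predictions(classify_state(res$final_state),
                               fx$panels$rett, pretest = c(0.66, 0.34))
report
```
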