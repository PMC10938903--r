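---
title: "Perturbation dynamics of Boolean networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation dynamics of Boolean networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkerbn)
```

## The model

A Boolean network assigns each of N nodes a binary state and an update rule
— a logical expression in AND/OR/NOT over node states.  Two update schemes
are supported.  Under **synchronous** update every node recomputes
simultaneously from the pre-step state, so the dynamics is a deterministic
map on the 2^N states.  Under **asynchronous** update a single node,
selected uniformly at random (no exclusions: sources and constants are
selectable), recomputes per step; one step is one node update, and quantities
compared across schemes at "one network update" use N asynchronous steps per
synchronous step.

Two node types get special treatment throughout.  A **source** node
(rule logically equivalent to the node's own value) models cellular context:
a flip of a source is permanent by construction.  A **constant** node (rule
equivalent to 0 or 1) recovers at its first update.  Classification is
*semantic* — by truth-table equivalence over the rule's referenced inputs,
enumerated up to a fan-in of 20 — because textual conventions vary across
model repositories; `A | !A` is a constant no matter how it is spelled.

## Walker simulation protocol

An ensemble of W independent instances ("walkers") is stored as a W × N
binary matrix and evolved for `T = T_b + T_w` steps.  Time averages are
taken over the last `T_w` steps.  Defaults: total `T = 55N + 6000`, with
`T_w` the largest multiple of 4 not exceeding T/2 and `T_b` the rest.  The
55N + 6000 total is the simulation length the protocol is calibrated to;
the burn-in/window split is a package choice (the stated protocol fixes only
the total), chosen as an even split so that the window is long enough for
1/T_w granularity while the burn-in comfortably covers transients of small
and mid-sized models.  Both are configurable everywhere.

Convergence is diagnosed by splitting the window into four equal quarters
and comparing ensemble-mean node values across them: the diagnostic is the
largest per-node spread (max − min) over the quarters, with default
tolerance 0.0066, the worst case the protocol is calibrated against.  The
package exposes the tolerance and T rather than an adaptive stopping rule,
whose stopping logic is not specified in the protocol we follow.

With W = 2500 walkers the standard error of any mean binary node value is
at most 0.5/√2500 = 0.01, which is why 2500 initial states per perturbation
target is the default sampling plan for the long-term measures (the Derrida
coefficient, needing only one network update, defaults to 100 000 pairs).

### Reproducibility

Every stochastic entry point takes a seed, and asynchronous schedules
require one — there is no silent nondeterminism.  Internally all randomness
derives from the master seed through a fixed integer hash of (seed, stream,
step), kept below 2^31.  Per-step derivation makes the node-choice sequence
a pure function of (seed, t): replaying a schedule is exact, results do not
depend on batching or evaluation order, and a perturbed/unperturbed pair
shares its schedule by construction.  (A counter-based RNG would be the
conventional way to get the same property; R ships none, and the derived-
seed construction achieves the same contract with base R.)

## Paired perturbation experiments

All four response measures are averages over matched trajectory pairs: an
unperturbed walker X(t) and a copy flipped in exactly one node i at t = 0,
updated with the *same* schedule at every step.  Sharing the schedule is
what makes the asynchronous measures well defined — the pair difference then
reflects the perturbation, not schedule noise.

* **Derrida coefficient (δ):** mean Hamming distance after one network
  update.  Estimated from sampled pairs; exact by enumeration.
* **Final Hamming distance (h∞):** window average of the per-step Hamming
  distance.  Phase-shift sensitive.
* **Fragility (φ):** L1 distance between the two members' window-mean
  vectors — time averaging inside the norm, hence phase-insensitive.
* **Quasicoherence (q):** fraction of pairs whose quasiattractor
  signatures agree, where a window mean m classifies a node as fixed-0
  (m ≤ ε), fixed-1 (m ≥ 1 − ε), or oscillating.

h∞, φ and q are computed from one shared simulation pass per target, so the
per-sample triangle inequality φ ≤ h∞ holds sample by sample, not only in
expectation.  Reported dispersion is the standard deviation of per-pair
contributions divided by √(number of pairs), pooled across targets (the
1/N-prefactor average over targets equals the pooled pair mean at equal
pair counts per target; pooling is this package's documented choice for
ensemble averaging).

### Source-handling modes

In mode **p** every node is a flip target.  In mode **f** ("fixed
sources"), source nodes are excluded from the target set and the 1/N
prefactor becomes 1/(number of non-source nodes); sources are still sampled
uniformly at t = 0 and still update as identities, and the Hamming/L1 norms
run over all nodes — source coordinates agree within every pair by
construction, so the norm's support is unaffected.  Constant nodes remain
perturbable in mode f, as do nodes frozen downstream of sources.  On a
source-free network both modes coincide exactly.  Mode f errors when every
node is a source (no perturbable target exists).

### Numerical choices

Window means of binary series are exact multiples of 1/T_w up to
accumulation error, so the signature tolerance defaults to ε = 1e−9 and
must satisfy ε < 1/(2 T_w) to be unambiguous; a larger ε is configurable
for noisy asynchronous windows.

One estimator bias is worth knowing about: φ is a |·| of noisy window
means, so when the exact fragility contribution is 0 *and* a node
oscillates aperiodically (asynchronous update), the finite-window estimate
is biased upward by O(1/√T_w) (≈ 0.01 at the default window).  h∞ and q do
not share this bias (h∞ is linear in per-step indicators; q's signatures
are exact once pairs absorb into fixed points).  The package reports the
estimate as defined; exact values on small networks come from the oracle.

## The exact oracle

For N ≤ 16 the synchronous state-transition graph is enumerated directly.
Attractors are terminal strongly connected components (via igraph); basins
follow the deterministic transient structure.  Exact synchronous measures
iterate each pair onto its joint cycle (periods p₁, p₂; averages over
lcm(p₁, p₂) steps after a 2^N-step burn-in, a safe tail bound) and use
exact cycle means — no tolerances enter.

For N ≤ 6 asynchronous dynamics, the coupled pair chain on 4^N states (both
members update the same uniformly chosen node, probability 1/N each) is
built as a sparse matrix.  Long-run time averages from any start follow
from the chain structure: stationary distributions of the closed
communicating classes (sparse linear solves) combined with exact absorption
probabilities.  δ under asynchronous update applies the one-step pair-chain
operator N times.  Aggregates are clamped to their mathematical ranges to
shed ~1e−16 linear-algebra residue.  The coupled-chain implementation was
validated against an independent hand-coded Monte Carlo simulation of the
mutual-inhibition motif.

Quasiattractors of an attractor set merge attractors sharing fixed-0,
fixed-1, and oscillating node sets; for the three-node rotation
(A\*=B, B\*=C, C\*=A) the four synchronous attractors collapse to three
quasiattractors (000, 111, \*\*\*).

## Network reduction

Two standard reductions are provided, both preserving steady states
projected onto surviving nodes: **source percolation** substitutes fixed
source/constant values and repeatedly fixes any rule that becomes
semantically constant, and **elimination of a self-edge-free node** inlines
its rule into its targets.  Elimination can create new constants (e.g.
substituting B\* = ¬C into A\* = B ∧ C yields the constant 0); only constant
folding is applied syntactically — semantic questions always go through
truth tables.

## Random ensembles

The NK ensemble is the classic Kauffman construction: each node receives K
distinct regulators uniformly from all N (self allowed) and a truth table
uniform over all 2^(2^K) functions.  A node is a source iff self is among
its inputs (probability K/N) and its table is the self-projection
(probability 2^(−2^K)), so the expected number of sources per network is
K·2^(−2^K) — 0.125 at K = 2, independent of N — and the source-free
fraction is ≈ exp(−0.125) ≈ 0.88.  This instantiates the "standard random
ensemble" contrast for the observation that source nodes are rare in random
networks but common in curated biological models; the >75% source-free
bound is tested as a bound against Monte Carlo sampling with an exact
binomial confidence interval, not as an equality.

## What the fixtures do and do not establish

The built-in fixtures reproduce the canonical worked examples: the one-node
negation oscillator (δ = h∞ = 1, φ = 0, q = 1 — pure phase shift), the
oscillator plus a source (h∞ = 1 in both schemes, φ = 0.5 — half the
separation is time lag), the mutual-inhibition motif (update-scheme-
dependent attractor repertoire, scheme-robust mean node values), the
three-node rotation (attractor/quasiattractor counting), and an
all-constant network (perturbation extinction).  These are exact,
enumerable test points.  They deliberately do *not* emulate the features of
large curated models — long transients, heterogeneous in-degree,
thousands-fold state-space undersampling — so a green test establishes
correctness of the estimators and oracle, not convergence behaviour on
50-node models; for those, the convergence diagnostic must be checked per
run (the CLI exits nonzero when it fails, unless overridden).

## Known limitations

- Exact asynchronous analysis is capped at N = 6 (4^N pair states, dense
  in the worst case); beyond that only walker estimates are available.
- The fragility estimator's finite-window bias (above) is not corrected;
  widen T_w when exact-zero fragilities matter under asynchronous update.
- Multi-valued logic, SBML-qual import, and merging of multi-node
  encodings of one entity are out of scope; rule files are the interface.
- Continuous-time, random-order, and most-permissive update schemes are
  not implemented.
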