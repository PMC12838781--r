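---
title: "Recurrence resonance in small stochastic recurrent networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence resonance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recres)
```

## The model

`recres` studies *recurrence resonance* (RR): the phenomenon in which an
intermediate level of additive noise maximises the temporal mutual
information of a recurrent neural network's symbolic dynamics, because noise
lets the state explore attractors that deterministic dynamics would hide.
The network is a continuous-state, discrete-time stochastic recurrent
network of `n` neurons,

$$u_i^{t+1} = \tanh\Big(\sum_{j=1}^n w_{ij}\, u_j^t + r\,\eta_i^t\Big),
\qquad \eta_i^t \sim \mathcal N(0, 1),$$

with states in $(-1, 1)$, coupling matrix $w$, and noise strength $r$.
Analysis happens on the post-hoc binarised states $s_i^t = \mathbf 1(u_i^t >
0)$ (ties at zero map to 0) and their integer encoding $z_t = \sum_k s_k^t
2^{k-1}$ — neuron 1 is the least-significant bit, so the quiescent state is
0 and the saturated state of five neurons is 31.

Two diagnostics detect RR from the encoded series: the plugin entropy
$H(X) = -\sum_x p(x)\log_2 p(x)$ and the plugin mutual information between
consecutive states, $I(z_t; z_{t+1})$. RR is present when $I$ has a strict
interior maximum over $r$ while $H$ is still rising (elevated but
unsaturated). Directed interaction between two subsystems $A$ and $B$ is
measured by the first-order transfer entropy

$$TE_{A\to B} = \sum p(b', b, a)\,\log_2
\frac{p(b' \mid b, a)}{p(b' \mid b)},$$

estimated from the empirical joint of $(z^B_{t+1}, z^B_t, z^A_t)$.
Attractor structure is summarised by the empirical state transition matrix
(STM) $T_{xy} = N_{xy} / \sum_k N_{xk}$ over consecutive encoded states,
its marginal $P_x$, the visitation gain $G(x) = P_x \cdot 2^m$ against the
uniform baseline $P_{\mathrm{uni}} = 2^{-m}$, and the diagonal stability
$T_{xx}$.

## Connectivity as a rough-set lattice

The "quantum logic" connectivity condition is purely order-theoretic. A
binary relation $I \subseteq U_1 \times U_2$ between two copies of the
neuron set induces a closure operator
$\mathrm{Cl}(F) = R^*(r^*(F))$, where $r^*(F)$ collects every column related
to a member of $F$ and $R^*(G)$ keeps the rows related only into $G$. The
closure's fixed points, ordered by inclusion, form a complete lattice.
`pasted_relation()` builds the relation whose fixed points realise the
*pasting* of Boolean algebras — one $2^{k}$ block per neuron block, glued at
a shared top and bottom: within each block only diagonal pairs are related,
and every cross-block pair is related. For blocks $(3, 2)$ this yields the
ten-element lattice with $\mathrm{Cl}(\{A\}) = \{A\}$,
$\mathrm{Cl}(\{B,C\}) = \{B,C\}$ and $\mathrm{Cl}(\{C,D\}) = U$; the
lattice is non-distributive (witness $x = \{A\}$, $y = \{D\}$, $z = \{E\}$),
which is the defining algebraic property of the quantum-logic structure. A
purely diagonal relation instead yields the full (distributive) power set.
`check_distributivity()` verifies the identity over all ordered element
triples; `hasse_edges()`, `lattice_json()` and `lattice_dot()` export the
diagram.

```{r lattice}
rel <- pasted_relation(c(3, 2), u1 = LETTERS[1:5], u2 = letters[1:5])
lat <- build_lattice(rel)
length(lat)
check_distributivity(lat)$witness[c("x", "y", "z")]
```

## The connectivity generator

`build_weight_matrix()` is the synthetic-data generator: every experimental
condition is a deterministic function of a `condition_spec` and one integer
seed. Weights are drawn by exact rejection sampling from truncated normals
on the class ranges of the reference study, with $\mu$ the range midpoint
and, since no $\sigma$ is reported there, the default $\sigma = (q - p)/4$ (≈95% of
the untruncated mass already inside $[p, q]$; configurable). Each directed
entry is sampled independently; a symmetric mode is available but off by
default, because nothing in the figure captions establishes symmetry.

The cell-level layouts deserve explanation, because the reference study
reports the class *ranges* precisely but the class *positions* only through
figures, so parts of each layout are declared modelling assumptions:

* **Five-neuron excitatory lattice condition** (`ql5_exc`, blocks 3 + 2):
  the whole within-block region is strong (0.7–1.0), the two cross-block
  border cells (last neuron of one block to first of the next, both
  directions) are intermediate (0.2–0.3), and the remaining cells are weak
  (0.0–0.05). This layout reproduces the reported resonance location
  exactly: the ensemble MI peak of the global 5-neuron system at $W = 1$
  sits at $r^* = 1.0$ on a 0.2-step grid, and the quiescent/saturated
  states 0 and 31 rank top-2 by self-transition probability there. A
  diagonal-strong alternative shifts the peak to $r \approx 0.4$, which is
  why the full-block reading is the package default for this condition.
* **Inhibitory-modulated conditions** (`ql5_inh`, `ql10_inh`) use the
  `"pasted"` layout, the weight-level image of the pasted lattice relation:
  strong self-coupling on the diagonal (0.7–1.0, resp. 0.95–1.05),
  the weakest positive class on the within-block off-diagonal (0.0–0.05,
  resp. 0.02–0.08), and inhibitory weights on every cross-block cell
  (−0.8 to −0.4, resp. −0.75 to −0.55). This follows the reported
  description of the modified network — strong excitatory weights
  "maintained along the diagonal", previously intermediate cells
  attenuated, previously negligible cells reassigned to inhibition — and
  it is the only layout family we found in which disrupting the background
  is a meaningful operation (below).
* **Diagonal controls** (`diag5_exc`, `diag5_inh`, `diag10`): strong
  self-coupling only; the off-diagonal is weak (0.0–0.05), inhibitory
  (−0.26 to −0.16), or eliminated outright (exact zeros for the ten-neuron
  control, matching its description).
* **Broken condition** (`broken10`): the quantum-logic matrix with the
  *background* — every non-strong cell, i.e. the within-block negligible
  and cross-block inhibitory entries — randomly permuted among background
  positions. Values move together with their class labels, so per-class
  cell counts, connectivity density, and the sorted multiset of weights are
  conserved; only the topology is destroyed. Had the background been a
  single homogeneous class, this permutation would be a distributional
  no-op and the broken condition could not differ from the intact one.

Thresholding a generated matrix with `relation_from_weights()` recovers the
generating block relation exactly: the default threshold separates the
within-block (non-negative) classes from the background, sitting midway
between the largest inhibitory upper bound and the smallest non-negative
lower bound when inhibition is present.

## Simulation and scan protocol

Each simulation records all `T` post-update states — no burn-in is
discarded, matching the reported use of the full simulation period — and is
bit-reproducible from its seed (noise-free runs consume no random numbers
at all). The initial state is drawn uniformly on $[-1,1]^n$ from the run
seed, because the zero state is a deterministic fixed point at $r = 0$; a
zero start and explicit vectors are available.

`noise_scan()` implements the ensemble protocol: per trial one weight
matrix is drawn from the trial seed and held fixed across the whole noise
grid (noise, not connectivity, is the swept variable), and each (trial,
noise) cell is an independent simulation. The study conditions are 20
trials; 20,000 steps for five-neuron and subsystem observables (enough for
ergodic sampling of 32 states) and 100,000 steps for ten-neuron global
observables and transfer entropy. The default noise grid is 0–3 in steps of
0.2 plus sparse points at 4, 6, 9, 12 and 18; transfer-entropy comparisons
use 0–6 in steps of 0.5 (the ensemble-mean peaks are interior on this
range); the low-noise window 0–3 in steps of 0.25 locates the
resonance peak for attractor classification. Subsystem observables (the
partition A = neurons 1–5, B = neurons 6–10) are always computed from the
columns of the global trajectory, never from separate simulations.

All estimators are deliberately *uncorrected* plugin estimators with
base-2 logarithms and $0 \log 0 = 0$. At $T = 10^5$ samples over the
$1024^2$-cell joint of a ten-neuron system the finite-sample bias keeps the
temporal MI near 3.5 bits even for an i.i.d. uniform sequence; this floor
is part of the phenomenology being reproduced, so no Miller–Madow or
shuffle correction is applied anywhere in the analysis path (a shuffled
surrogate is easy to build by hand, as the test suite does).

## Attractor classification

States of the STM are classified hierarchically with the operational
thresholds: gain at or below 1 is transient noise; gain above 2 combined
with diagonal stability above 1.5× the baseline (the mean diagonal over
*visited* states — unvisited rows have undefined diagonals and are left
all-zero and flagged, never uniform-filled) marks a strong attractor;
everything else above the noise floor is a weak attractor, subdivided into
high-stability traps ($T_{xx}$ at or above baseline) and structural hubs
(below baseline). The Hopfield-type energy
$E(s) = -\tfrac12 \sum_{i\neq j} w_{ij} s_i s_j$ and its strict Hamming-1
local minima (`energy_landscape()`, exhaustive for $n \le 20$) provide the
descriptive energy-landscape view; classification itself uses only the
operational STM thresholds.

## What the generator does and does not emulate

The generator reproduces the reported weight classes, block structures,
scaling factors $W \in \{1, 2, 5, 10\}$ and seeds-to-matrices determinism.
It does not emulate: learned or plastic weights, asynchronous updating,
spiking dynamics, or any hardware noise model — the noise is i.i.d.
Gaussian per neuron per step, nothing else. Conclusions from passing tests
therefore concern this generative family only; in particular the exact
cell-level layout of the reference figures is not fully recoverable from
text, and two reported findings resisted every layout we constructed
within the reported ranges: the more-than-twofold growth of the inhibitory
five-neuron MI peak from $W=1$ to $W=2$ (in the saturated tanh regime the
dynamics are nearly invariant under $(W, r) \to (cW, cr)$, so peak heights
barely move while peak locations scale), and a mean strong-attractor
stability of ≈0.8 at the ten-neuron resonance peak (which would require
self-coupling-dominated fields, in tension with the reported 62-cell
inhibitory background). The corresponding checks are implemented at face
value and report what the model family actually produces.

## Numerical choices

* Ties: `find_peak()` breaks ties toward smaller noise; binarisation maps
  $u = 0$ to 0.
* Degenerate inputs: empty relations are allowed with a warning; unvisited
  STM rows are flagged; zero-variance groups in `compare_conditions()` are
  reported as degenerate rather than as an infinite variance ratio.
* The pairwise tests are classic pooled-variance t-tests by default
  (Welch optional), matching the generic "independent t-tests" of the
  protocol; the omnibus test is a one-way ANOVA on per-trial peak transfer
  entropies, extracted for every trial at the single grid point that
  maximises the ensemble-mean curve so that trials stay comparable.
* Lattice enumeration is exact over all $2^n$ subsets (guarded at
  $n \le 20$); meets are found by search over the fixed-point set and joins
  as the closure of the union.
* All random draws flow from explicit integer seeds below $2^{31}$;
  per-trial and per-run seeds derive from one master seed, so any single
  trial can be re-run in isolation.

## Problem sizes

The packaged tests run the five-neuron protocols at the full 20 trials ×
20,000 steps and the ten-neuron protocols at 20 trials × 100,000 steps on
the grids above; unit tests use miniature versions (hundreds of steps) of
the same paths. A full transfer-entropy comparison (three conditions × two
scaling factors) takes on the order of ten minutes on one CPU core.
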