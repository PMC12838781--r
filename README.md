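# recres

Recurrence resonance and attractor landscapes in small stochastic recurrent
neural networks.

## What this package is for

Recurrent networks driven by additive noise can show *recurrence resonance*:
at an intermediate noise strength the temporal mutual information of the
network's symbolic dynamics peaks, because noise unmasks attractors that the
deterministic dynamics would hide. `recres` is a self-contained simulation
and analysis toolkit for studying this phenomenon in small (5- and
10-neuron) networks whose connectivity is derived from non-distributive
("quantum logic") lattices built by pasting Boolean algebras. It is aimed at
computational-neuroscience and neuromorphic-computing researchers who want a
reproducible, tested implementation of the whole pipeline:

1. **Connectivity generation** — weight matrices drawn from truncated-normal
   weight classes (strong / intermediate / weak / negligible / inhibitory)
   under quantum-logic, diagonal and broken-background conditions, exactly
   regenerable from an integer seed (`network_condition()`,
   `build_weight_matrix()`, `break_background()`, `scale_weights()`).
2. **Dynamics** — the stochastic tanh network
   `u[t+1] = tanh(W u[t] + r * eta)`, binarisation at zero, integer state
   encoding, rasters (`simulate_network()`, `binarize()`, `encode_states()`,
   `raster()`); the hot loop is compiled (Rcpp), so 100,000-step ensembles
   run in seconds.
3. **Information metrics** — uncorrected plugin estimators of entropy,
   consecutive-state mutual information and first-order transfer entropy,
   ensemble noise scans and peak detection (`entropy_plugin()`,
   `temporal_mi()`, `transfer_entropy()`, `noise_scan()`, `find_peak()`).
4. **Attractor landscapes** — empirical state transition matrices,
   visitation gains, diagonal stabilities, strong / weak / transient
   classification with weak-attractor subtypes, and Hopfield-energy local
   minima (`build_stm()`, `classify_attractors()`, `energy_landscape()`).
5. **Rough-set lattices** — the closure operator of a binary relation, its
   fixed-point lattice, Hasse diagrams, and distributivity checks
   (`pasted_relation()`, `closure()`, `build_lattice()`,
   `check_distributivity()`, `hasse_edges()`).
6. **Experiments** — named end-to-end protocols, condition comparisons with
   ANOVA and t-tests, figure rendering (`rr_protocol()`, `run_protocol()`,
   `compare_conditions()`, `replicate_figure()`).

## Worked example

Five neurons, two blocks (3 + 2), purely excitatory quantum-logic coupling:

```r
library(recres)

# the pasted lattice behind the quantum-logic condition
rel <- pasted_relation(c(3, 2), u1 = LETTERS[1:5], u2 = letters[1:5])
lat <- build_lattice(rel)
lat
#> rough_lattice: 10 elements over U1 = {A,B,C,D,E}
check_distributivity(lat)$distributive
#> [1] FALSE

# a reproducible weight matrix and a 20-trial resonance scan
wm <- build_weight_matrix(network_condition("ql5_exc"), seed = 42)
scan <- noise_scan(network_condition("ql5_exc"), W = 1, trials = 20,
                   steps = 20000, seed = 7)
find_peak(scan, "MI_global")
#> MI peak: 1.399 bits at r = 1.0 (trial SD 0.045)

# the attractor landscape at the resonance peak
tr <- simulate_network(wm, 20000, noise = 1.0, seed = 7)
model <- build_stm(tr$encoded, 5)
cls <- classify_attractors(model)
table(cls$label)
#>    strong transient      weak
#>         3        24         5
cls[cls$label == "strong", c("state", "G", "Txx")]
#>  state         G       Txx
#>     31 12.299815 0.8429817
#>      0  8.051603 0.8436010
#>      7  2.382519 0.6306246
```

Reading the output: the ten-element lattice is the pasting of a 2^3 and a
2^2 Boolean algebra sharing top and bottom, and it is non-distributive —
the algebraic signature of the quantum-logic condition. The ensemble mutual
information of the encoded network state peaks at noise strength r = 1.0
while the entropy is still rising: recurrence resonance. At that noise
level the quiescent state (0) and the saturated state (31) are strong
attractors with self-transition probabilities ≈ 0.84, far above the 0.15
diagonal baseline, and noise has unmasked a third strong attractor — state
7, the configuration with exactly the first block (neurons 1–3) active,
i.e. an attractor aligned with the lattice's block structure.

For the ten-neuron analyses, `noise_scan()` takes the subsystem partition
(`subsystems = list(A = 1:5, B = 6:10)`, `te = c("A", "B")`) and returns
transfer-entropy curves whose peaks compare the quantum-logic, diagonal and
broken-background conditions; `compare_conditions()` runs the ANOVA and
pairwise t-tests on the per-trial peaks.

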