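# dendroseq

Deterministic 1-D reaction–diffusion simulation of **dendritic sequence
discrimination**: how a few microns of dendrite, hosting diffusively
coupled biochemistry, can respond selectively to synaptic inputs that
arrive in the correct spatio-temporal order on behavioural timescales
(seconds, microns).

The package is for computational neuroscientists and systems biologists
who want to study — or build on — the chemical mechanism of slow sequence
recognition: five Ca²⁺ pulse sites a few microns apart on a dendritic
segment, stimulated in one of the 5! = 120 possible orders, read out by
the total activity of a downstream signalling species.

## What it computes

**Stimuli.** Each site receives a Gaussian Ca²⁺ pulse,
`Ca(t) = amplitude · exp(−(phase − t)² / (2·width²))`, where the phase of
site *k* is `onset + interval · rank(k)` for a chosen permutation of
(0,1,2,3,4).  Exhaustive (120-order) and subsampled (12-order, every tenth
permutation) protocols are built in.

**Sequence-order metric.** `Q = m·R²` from the ordinary least-squares
regression of ordinal arrival-time rank on ordinal position: +1 for the
forward sequence, −1 for the reverse, ≈0 for scrambled orders.

**Readout and selectivity.** `Atot` sums the readout species over the five
sites from the first pulse to the end of the run;
`selectivity = (Asequential − mean(Atot)) / max(Atot)` over an order set,
ranging from 0 (unselective) toward 1 (only the sequence responds).

**Models.** Four abstract two-species chemistries (negative feedback,
feedforward inhibition, FitzHugh–Nagumo, and a bistable switch with
delayed inhibition) on a 100 μm × 1 μm chain with reactions confined to
five 1-μm patches, plus a mass-action MAPK switch (Ca → CaM buffering,
Ca-activated Raf → MEK → MAPK dual phosphorylation, PKC positive feedback,
MAPK-induced phosphatase negative feedback) on a 60 μm spiny cylinder with
49 spines.

**Engine.** Operator splitting: adaptive Runge–Kutta–Fehlberg 4(5)
integration of the local chemistry per compartment, implicit backward-Euler
diffusion solved exactly on the compartment tree, zero-flux boundaries,
bit-for-bit deterministic runs.

**Experiments.** Q-vs-Atot scatters, interval × spacing selectivity
matrices, rate/diffusion scaling (preferred sequence speed vs rate factor),
stimulus-amplitude shifts, and one-dimensional parameter-sensitivity
sweeps.

## Worked example

```r
library(dendroseq)

q_score(c(4, 0, 2, 1, 3))
#> <q_score> order [4,0,2,1,3]: m = -0.100, R2 = 0.010, Q = -0.001

m <- abstract_model("switch")
tab <- scatter_experiment(m, spacing = 4, interval = 2)
head(tab[order(-tab$Atot), c("order", "Q", "Atot")], 4)
#>        order      Q       Atot
#> 1  0-1-2-3-4  1.000 49.7693964
#> 12 4-2-1-0-3 -0.064  0.9404668
#> 10 3-4-0-1-2 -0.125  0.9387968
#> 8  2-4-3-0-1 -0.216  0.8497764

selectivity(setNames(tab$Atot, tab$order))
#> <selectivity> 0.9014  (Aseq = 49.77, mean = 4.906, max = 49.77, 12 orders)

selectivity_matrix(m, intervals = c(1.5, 2, 2.5), spacings = c(3, 4, 5))
#> <selectivity_matrix> switch model, subsample protocol (rows: interval s, cols: spacing um)
#>         spacing
#> interval     3     4     5
#>      1.5 0.300 0.306 0.470
#>      2   0.123 0.901 0.900
#>      2.5 0.032 0.081 0.146
```

The first call scores a scrambled order (Q ≈ 0).  The scatter experiment
runs one simulation per order of the 12-order protocol at the switch
model's tuned operating point: only the perfect forward sequence ignites
the travelling bistable response (Atot ≈ 50); every scrambled order stays
near 1, giving selectivity 0.90.  The matrix shows how that discrimination
is tuned in stimulus interval and spacing.

For the MAPK model:

```r
model <- build_spiny_model()
sequence_demo(model, 0:4)$Atot            # ordered input, ~45 uM·s
sequence_demo(model, c(4, 0, 3, 1, 2))$Atot  # scrambled, ~1.4 uM·s
pulse_protocol_demo(model)$summary        # paired-pulse suppression, step decline
```

`reproduce_report()` regenerates all reference tables (and, with ggplot2,
a multi-panel PDF) into one directory; `inst/cli/dendroseq.R` exposes the
same experiments as a command-line tool driven by JSON/YAML configs.

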