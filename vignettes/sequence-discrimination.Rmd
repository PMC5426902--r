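---
title: "Dendritic sequence discrimination by reaction-diffusion chemistry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic sequence discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroseq)
```

## The problem

Place cells, sensory relays and many other circuits activate ensembles of
neurons in a stereotyped order over seconds.  If those ensembles project in
spatial order onto a short stretch of dendrite, the postsynaptic chemistry
sees a travelling pattern of Ca²⁺ input: five synaptic sites a few microns
apart, each receiving its pulse one inter-stimulus interval after its
neighbour.  `dendroseq` asks whether diffusively coupled biochemistry on
that stretch can *discriminate* the correct spatio-temporal order from the
119 other arrangements of the same five pulses, and over what ranges of
spacing (μm) and interval (s) the discrimination is tuned.

The core idea is alignment: an input triggers local chemical activity that
spreads by diffusion; when the next input arrives just where and when that
activity front does, the two reinforce and the response builds up
supralinearly.  Misordered input misses the front, and inhibitory feedback
suppresses it.

## Measures

Three scalar measures quantify this.

* **Q** scores how ordered a stimulus sequence is: regress the ordinal
  arrival-time rank of each site against its ordinal position and take
  `Q = m R²` (slope times squared correlation).  `Q(0,1,2,3,4) = 1`,
  `Q(4,3,2,1,0) = -1`, scrambled orders sit near 0 (for example
  `q_score(c(4,0,2,1,3))$Q` is exactly −0.001).
* **Atot** is the total activity of the readout species: the readout is
  summed over the five stimulus sites and over all snapshots from the first
  pulse to the end of the run, times the recording interval (a Riemann sum,
  invariant to the recording rate).  The resting value of the readout is
  subtracted first.  This matters only for FitzHugh–Nagumo, whose resting
  activator sits at the negative classic fixed point (≈ −1.199 in these
  arbitrary units); without the subtraction the Eq.-style selectivity ratio
  below would be distorted by an arbitrary baseline offset.
* **Selectivity** `= (Asequential − mean(Atot)) / max(Atot)` over a set of
  stimulus orders — 0 for an unselective system, → 1 when only the
  sequential order responds.  Because it is scale-free, the arbitrary
  concentration units of the abstract models drop out.

Two permutation protocols are used: the exhaustive 120 orders, and the
12-order subsample (every tenth permutation of the lexicographic
enumeration, always including the sequential order) used for matrices and
sweeps where cost matters.

## The simulator

All models run on a 1-D chain (or spiny tree) of well-mixed compartments
with operator splitting: each splitting interval `dt_diff` the local
chemistry of every compartment is advanced independently by an adaptive
embedded Runge–Kutta–Fehlberg 4(5) step (Cash–Karp coefficients; relative
tolerance 10⁻⁶, absolute 10⁻⁸), then every diffusible species takes one
implicit backward-Euler diffusion step.  The diffusion system is solved
exactly per step by Gaussian elimination on the compartment tree
(children-before-parents ordering gives zero fill-in), which makes the step
unconditionally stable and conservative: with the zero-flux boundaries used
everywhere, the volume-weighted total of each species is preserved to
round-off.  Zero-flux ends model a sealed dendritic segment; the boundary
condition is a package choice, so absolute trajectory values carry that
caveat.

Numerical choices worth knowing about:

* **Splitting.** Lie splitting (react, then diffuse) is the default; Strang
  splitting is available via `solver_settings(method = "strang")`.  The
  default `dt_diff` is 5 ms for the abstract models and 50 ms for the
  (slower, stiffer-in-space) MAPK model.  These defaults were fixed by a
  self-convergence study: the bistable models are threshold systems, so the
  *location* of tuning-zone boundaries moves slightly with `dt_diff`, but
  at 5 ms the headline quantities (which orders ignite, the selectivity at
  the tuned operating points) agree with quarter-step integrations.
* **Reactive masking.** For the abstract models, reactions run only in five
  1-μm patches (the zones "under the spines"); diffusion acts over the full
  100 μm.  Masked compartments are untouched by the reaction step except
  for input deposition and first-order Ca removal, which is applied
  analytically there.
* **Input semantics.** The commanded Ca profile of a stimulus is a Gaussian
  (σ = `width`, truncated at ±4σ) or a square clamp.  While an event is
  active, local Ca relaxes toward the commanded value at `krelax` (20 s⁻¹
  for sequence pulses); outside its window an event exerts no force.  Ca
  additionally decays (4 s⁻¹) and diffuses (5 μm²/s) everywhere, so the
  input behaves like a localized, clamp-like source rather than a hard
  boundary condition.  The ±4σ truncation introduces a tiny step in the
  commanded profile; the reaction integrator absorbs such discontinuities
  by accepting floor-sized steps rather than shrinking `h` indefinitely.
* **Negativity.** The FHN variables are legitimately signed and are never
  clamped.  Mass-action species are clamped at zero (with a counter
  reported on the trajectory) because adaptive steps can undershoot.

## The four abstract chemistries

Each family has two species: the readout A and an inhibitory B (B always
inhibits A), driven by Ca.  The functional forms are canonical
reconstructions; the rate constants (registry v1, bundled as
`inst/extdata/registry.json`) were calibrated by random search against the
qualitative behaviours the families must show, then frozen.  Concentrations
are arbitrary units; no quantitative trace-level agreement with any
external dataset is claimed.

| family | dA/dt | dB/dt | signature |
|---|---|---|---|
| negFB | `k_act·Ca − k_deg·A − k_inh·A·B` | `k_ab·A − k_db·B` | step → peak then shallow plateau; no order preference |
| negFF | `k_act·Ca − k_deg·A − k_inh·A·B` | `k_b·Ca − k_db·B` | step → transient only; weak order preference |
| FHN | `k_a·(A − A³/3 − B + offset_A + Ca)` | `k_t·(a·A − b·B + offset_B)` | step → limit cycle; moderate, diagonal tuning |
| switch | `k1a·Ca + k2a·A²/(k2b²+A²) − k4a·A·(1+k4b·B)` | `k3a·A − k3b·B` | bistable ignition with delayed turn-off; strong tuning |

Calibration targets and the design decisions they forced:

* **negFB** is the control: its selectivity stays below 0.01 everywhere and
  its sequential and scrambled responses agree to better than 1%.
* **negFF** needed persistent (k_db = 0.02 s⁻¹), high-gain (k_inh = 40)
  inhibition for order to matter at all: the selectivity arises because B
  clouds diffusing from earlier sites suppress inputs that arrive at an
  adjacent site several intervals late, which penalizes most scrambled
  orders more than the sequential one.  Even so the effect is small
  (matrix maximum ≈ 0.1) and *sign-mixed* — at some (interval, spacing)
  combinations the sequential order is the more inhibited arrangement and
  the selectivity is slightly negative.  The A-gain `k_act = 10` only sets
  the readout scale (selectivity is scale-free) and was chosen so the
  impulse response is visibly large.
* **FHN** uses the classic excitable parameters (a = 1, b = 0.8, offsets 0
  and 0.7) with the timescales `k_a = 10 s⁻¹`, `k_t = 0.67 s⁻¹` and
  D = 1 μm²/s.  Under a sustained 0.4-amplitude step the point model sits
  inside the limit cycle and oscillates.  Spatially, excitation relays
  from patch to patch: each input fires its patch only when the
  subthreshold halo diffusing from the previously fired patch arrives in
  time, which produces the diagonal band in the tuning matrix (preferred
  spacing grows with preferred interval, i.e. a preferred *speed*) with a
  moderate maximum ≈ 0.3.
* **switch** is the headline model.  With B frozen the A-kinetics are
  bistable (nullcline roots at 0, ≈0.39 and ≈1.05; outer two stable — the
  certificate test re-runs this scan on every parameter change).  Diffusive
  leak out of a 1-μm patch (D = 5 μm²/s) raises the effective ignition
  threshold so that one pulse alone cannot ignite a patch; pulses aligned
  with the A-halo of the previously ignited patch can.  A full ordered
  sequence therefore ignites a travelling, self-reinforcing response while
  almost all scrambled orders die out, giving selectivity ≈ 0.8–0.9 at the
  tuned operating point (2 s, 4 μm) and the property that only |Q| = 1
  orders reach high Atot.  B accumulates slowly (k3a = 0.23, k3b = 0.03)
  and multiplicatively strengthens A's self-inhibition, so the point model
  switches on and autonomously returns to rest after ~5 s, and sustained
  input produces only a transient.
* The calibrated switch zone is **narrower in interval** (high selectivity
  at ≈1.5–2 s) than the broad zone the phenomenon is described with; its
  centre, the containment of the (2 s, 4 μm) cell, and the ordering
  switch > FHN > negFF > negFB ≈ 0 across families at their tuned points
  are all reproduced and tested.

## Sweep experiments

`selectivity_matrix()` sweeps intervals × spacings (defaults bracket
0.5–5 s and 1–10 μm; the structural tests use a coarse 6 × 6 grid with the
12-order protocol — about 430 simulations per matrix).  Cells whose
responses are all zero report `NA` rather than 0.

`rate_scaling_experiment()` multiplies every true rate constant and both
diffusion constants by a factor and divides the stimulus width by the same
factor.  Only 1/s-bearing constants scale — concentration-valued constants
(the switch's `k2b`, `k4b`) and FHN's dimensionless shape constants do not
— so the transformation is an exact rescaling of time.  The stimulus and
measurement machinery co-scales too (input relaxation rate, onset,
recording tail, splitting step): without this, protocol constants that fail
to scale blur the expected shift and the experiment measures the protocol
rather than the chemistry.  Because several cells tie near the matrix
maximum, the preferred *speed* is summarized by the selectivity-weighted
centroid of the high-selectivity zone (cells ≥ 70% of maximum) rather than
the raw argmax; the argmax cell is still reported, with ties broken toward
smaller interval then smaller spacing.  Under the frozen calibration the
preferred interval halves per factor-of-two speed-up while the preferred
spacing stays put, so the preferred sequence speed grows with the factor.

`amplitude_experiment()` re-runs the matrix at fractions of the calibrated
basal amplitude: ±10% visibly moves the argmax cell, and a 5× stimulus
drives selectivity toward zero because it overrides the inhibition and
ignites every order indiscriminately.

`parameter_sensitivity()` varies one rate constant (or the stimulus
amplitude/width, or D_A/D_B) by multiplicative factors and reports
Asequential, mean(Atot) over the 12 orders, and the selectivity per factor.
Because the frozen switch operates at a collective-ignition margin, it is
sensitive (selectivity collapses within ±10%) to the parameters that set
that margin — the input gain k1a, the self-activation k2a, the
self-inhibition k4a and the stimulus amplitude — and tolerant of the
others; this fragility is a property of the mechanism, not a defect of one
parameter set.

## The mass-action MAPK switch

The spiny-cylinder model translates the abstract switch into mass-action
units: a 60 μm × 1 μm dendrite at 1 μm resolution carrying 49 spines
(Poisson-placed along the cylinder — uniform positions conditional on the
count — with a fixed seed so the bundled geometry is reproducible; other
seeds regenerate freely).  Each spine is PSD → head (0.5 μm × 0.5 μm) →
shaft (1 μm × 0.2 μm) → dendrite, diffusively coupled through the
constriction cross-sections, with volumes from the cylinder formulas.  Five
spines near the midpoint, ≈3 μm apart, are the stimulated set.

The network (16 species, 18 reactions; μM and seconds) is a schematic
reconstruction, not a transcription of any published rate table: Ca — with
first-order turnover and CaM buffering — activates Raf; Raf drives MEK
phosphorylation; MEK-P doubly phosphorylates MAPK; active MAPK feeds back
positively through PKC onto Raf; and a MAPK-induced phosphatase (induction
τ ≈ 10 s, recovery τ ≈ 250 s) dephosphorylates MEK-P and MAPK-P, providing
the delayed negative feedback.  Active PKC and Raf are non-diffusible;
everything else diffuses.  Two design points were essential and are easy to
miss:

* **Zero-order ultrasensitivity.** With first-order dephosphorylation the
  cascade is a linear amplifier and no parameter set is simultaneously
  OFF-stable at rest and fast-switching (a random search over ~10⁵
  candidates found essentially none).  Making the constitutive
  phosphatases explicit, saturable enzymes (MKP, PP2A; Km = 0.1 μM, well
  below the substrate totals) creates Goldbeter–Koshland-style thresholds,
  and the operating points could then be placed by hand: basal Raf\* ≈
  0.015 μM sits 5-fold below the MEK-stage threshold, a ~2 μM dendritic
  Ca transient pushes it 2-fold above, and the PKC arm holds the loop on
  once MAPK-PP rises.
* **The marginal-input regime.** A 160 μM, 2.9 s PSD clamp delivers
  (after dilution through the spine neck and CaM buffering) a dendritic Ca
  transient just *below* the local switching threshold.  A single sequence
  input therefore does not ignite; inputs aligned with the diffusing
  MEK-P/MAPK-PP halo of their predecessor do.  This is what produces the
  strong order selectivity (≈0.7–0.9 over the 12-order protocol at 3 s,
  ~3 μm): the ordered train ignites a sustained travelling response while
  scrambled trains produce only small transients — larger *and*
  longer-lasting dendritic MAPK-P for the ordered input.  The price is
  that the paired-pulse/step characterization protocol
  (`pulse_protocol_demo()`) must drive the PSD harder (800 μM by default)
  to demonstrate single-pulse switching; with that suprathreshold pulse
  the second pulse 50 s later is suppressed more than 100-fold by the
  lingering induced phosphatase, and the response to a 50 s step peaks and
  decays below half-peak before the step ends.

All MAPK claims are behavioural and relative — switch-like turn-on, delayed
turn-off, paired-pulse suppression, step decline, order preference, moiety
conservation (checked to 10⁻⁶ along trajectories and structurally via the
left null space of the stoichiometry matrix).  Absolute concentrations and
time constants are not matched to measurements.

## What the simulations do and do not show

Everything here is deterministic, noise-free, one-dimensional chemistry
with idealized Gaussian/square inputs delivered exactly on schedule.  Real
dendrites add stochastic synaptic transmission, channel noise, branching,
electrical coupling and far richer Ca handling; passing these tests
therefore shows that the *mechanisms* (wave–input alignment, bistable
ignition with delayed inhibition, diffusive priming and suppression) behave
as described, not that any quantitative prediction transfers to tissue.
Morphologically detailed neurons, stochastic spine chemistry and electrical
modelling are out of scope.

## Reproducing the reference outputs

`reproduce_report()` regenerates the package's reference tables (point
responses, sequential-vs-scrambled traces, Q–Atot scatters, coarse
selectivity matrices, the rate-scaling summary and the MAPK demos) into one
directory, with a `report.md` recording the package version and the
md5-stamped parameter registry.  `run_from_config()` and the
`inst/cli/dendroseq.R` script drive the same experiments from JSON/YAML
configuration files; outputs are CSV with JSON sidecars and are
byte-reproducible given the same configuration.
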