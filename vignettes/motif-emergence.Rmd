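---
title: "Short-term synaptic dynamics, triplet STDP, and the emergence of connectivity motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term synaptic dynamics, triplet STDP, and the emergence of connectivity motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifnet)
```

## The scientific question

In cortical and olfactory-bulb microcircuits, excitatory neurons joined by
short-term *facilitating* synapses are found predominantly in **reciprocal**
pairwise motifs, while neurons joined by short-term *depressing* synapses
form predominantly **unidirectional** motifs. `motifnet` implements a
modelling framework in which this correlation emerges from nothing but the
interaction of two well-established synaptic mechanisms:

1. **Short-term dynamics (SD)** — the Tsodyks–Markram resource model, in
   which each presynaptic spike releases a fraction `u·x` of available
   resources; depressing synapses (high release probability `U`, slow
   recovery `τ_rec`) transmit strongly at low rates but saturate, so the
   steady synaptic flux is bounded by `1/τ_rec`; facilitating synapses
   (small `U`, slow facilitation decay `τ_facil`) transmit weakly at first
   but grow with rate.
2. **Triplet spike-timing dependent plasticity (STDP)** — the
   Pfister–Gerstner minimal all-to-all rule, with pair-based depression
   `−A₂⁻ o₁` at each presynaptic spike and triplet potentiation
   `+A₃⁺ r₁ o₂` at each postsynaptic spike. Its essential property is the
   **LTD-to-LTP reversal**: for post-before-pre pairing the net change is
   depression at low pairing rates and potentiation above a critical
   frequency, as observed experimentally.

The combination produces the motif dichotomy: recurrent networks of
facilitating synapses reverberate at high rates, pushing every synapse into
the rate-dominated "Hebbian" regime of the triplet rule (both directions of
every pair potentiate → reciprocal motifs); networks of depressing synapses
are rate-limited below the critical frequency, so only the causal,
timing-driven branch of STDP acts (exactly one direction of a pair wins →
unidirectional motifs).

## Provenance of the parameters

The defaults are the canonical published sets of the three component
models:

* Neuron: adaptive exponential integrate-and-fire with the standard
  regular-spiking constants (C = 281 pF, g_L = 30 nS, E_L = −70.6 mV,
  Δ_T = 2 mV, V_T = −50.4 mV, a = 4 nS, b = 0.0805 nA, τ_w = 144 ms,
  2 ms refractoriness, forward Euler at dt = 0.1 ms).
* SD: depressing `U = 0.5, τ_rec = 800 ms, τ_facil = 20 ms`; facilitating
  `U = 0.05, τ_rec = 130 ms, τ_facil = 530 ms`; PSC decay τ_syn = 5 ms.
* Triplet rule (minimal, all-to-all, visual-cortex fit): A₂⁺ = 0,
  A₃⁻ = 0, A₂⁻ = 7.1·10⁻³, A₃⁺ = 6.5·10⁻³, τ₊ = 16.8 ms, τ₋ = 33.7 ms,
  τ_x = 101 ms, τ_y = 114 ms.

With these values the critical frequency of the Poisson-averaged drift is

```{r}
critical_frequency()
```

and the frequency pairing protocol (60 post-before-pre pairs at −10 ms)
crosses from depression to potentiation at

```{r}
ltd_ltp_crossover(triplet_params(), delta_t = -10)
```

i.e. inside the experimentally reported 30–40 Hz band.

## Rule variants

`configure_rule()` derives the two controls used to isolate which features
of the plasticity rule matter:

* **pair** — both triplet amplitudes zeroed and the pair LTP amplitude set
  to `A₃⁺·ō₂(ρ_ref)`, where `ō₂` is the steady-state slow postsynaptic
  detector just before a spike at the reference pairing rate (1 Hz by
  default). By construction the timing window at `ρ_ref` matches the
  triplet window *exactly* for every offset, yet the rule shows **no**
  LTD-to-LTP reversal — and, in network simulations, no motif dichotomy.
* **anti** — the exact pre/post role mirror of the triplet rule: amplitude
  pairs and detector time constants are swapped and the update signs
  inverted. The timing window is the mirror image of the triplet window
  about Δt = 0 — post-before-pre now potentiates — a machine-precision
  identity used as a regression test, while the frequency reversal
  survives (now for pre-before-post pairs); motif emergence is preserved.

Both constructions are this package's own reading of the published
descriptions; the re-tuning rate of the pair control is exposed as
`pair_match_rate`.

## Numerical conventions

* **Within-step order**: decay states → apply external and synaptic
  currents → threshold test → spike-triggered updates (depression-side
  weight updates for all spikers, then potentiation-side updates, then
  unit increments of the four detectors, then synaptic release). Spikes
  reach their targets at the next Euler step; there are no axonal delays.
* **Coincident pre/post spikes** (same dt bin, or equal times in the
  event-driven engine) compute both weight updates from the pre-increment
  detector values, making Δt = 0 deterministic. The event-driven pairing
  engine and the network engine share this convention and are tested for
  exact agreement (a pairwise replay of the network's spike record through
  the event engine reproduces every final weight to 10⁻⁹).
* **Short-term update order at a spike**: facilitation first
  (`u ← u + U(1−u)`), then depression with the updated utilisation
  (`release = u·x`, `x ← x − u·x`) — the standard Tsodyks–Markram
  convention. Between spikes both variables relax exponentially to their
  resting values (`U` and 1), lazily and analytically, so the per-synapse
  state costs nothing between presynaptic spikes.
* **Spike detection** uses the emission-threshold ceiling (0 mV) with the
  exponential argument capped, so a coarse Euler step cannot overflow;
  halving dt changes 1-s spike counts by at most one spike.
* **Weight bounds**: every update clips the scaling factor to
  `[0, w_max]`; weights are uniformly initialised on that interval.
* **Mean-field roots** are bracketed on a 2000-point grid and refined by
  bisection to ~10⁻¹² residual; one-population stability uses the field
  derivative, two-population stability the eigenvalues of a central
  numerical Jacobian. The stationary SD factors use the classic
  approximation `u∞ = U(1+τ_f ν)/(1+U τ_f ν)`, `x∞ = 1/(1+u∞ τ_r ν)`,
  which neglects the u–x correlation and the within-spike update ordering:
  the time-average of `u` is exact, that of `x` is biased by up to ~25 %
  for strongly depressing parameters, which is why the Monte-Carlo
  consistency test uses an asymmetric tolerance.

## The stated world of the generators

All inputs are synthetic. Where the component models did not pin a value,
the following were chosen once, as a realistic regime, and are not tuned
per test:

* Wiring: all-to-all minus autapses, 20 % of directed edges pruned;
  maximal efficacy `A = 72000/(N−1)` pA so that the expected recurrent
  drive per neuron is network-size independent.
* Toy drive (N = 10): 0.2 nA baseline plus a travelling 1.0 nA pulse with
  a narrow Gaussian spatial profile (σ = 0.5 index units) dwelling 20 ms
  per unit and wrapping around the ring; each visit elicits a short burst
  (two spikes), giving a 10 Hz externally imposed rate.
* Background noise (large networks): per-neuron Ornstein–Uhlenbeck
  currents, exact discretisation, σ = 150 pA, τ = 5 ms, per-neuron means
  drawn once with unit coefficient of variation around 100 pA
  (heterogeneous layout) or 250 pA (homogeneous layouts).

**Calibration note.** The maximal efficacy was calibrated once so the
facilitating toy network reverberates above the measured crossover while
the depressing one stays below — the regime the underlying theory
identifies as the precondition for the motif dichotomy. Likewise, no single
`(A, noise)` pair made all three large-network layouts work at the scaled
size N = 100: conditions that ignite the facilitating half of a
heterogeneous network drive a homogeneous depressing network into
synchronized bursting, whose spike coincidences potentiate reciprocal
pairs. The large-network experiment therefore runs homogeneous layouts at
`A = 50000/(N−1)`, noise mean 250 pA and the heterogeneous layout at the
default efficacy, noise mean 100 pA, with cross-population initial weights
scaled by 0.3.

What a green test does and does not establish: the generators emulate
stationary drive, a single excitatory cell class and current-based
synapses. They do not emulate conductance effects, spiking inhibitory
populations (inhibition enters the spiking model only through the
balanced/unbalanced external term; the mean-field additionally offers an
optional fast interneuron population with fixed couplings, off by
default, under which the facilitating-above-depressing equilibrium
ordering is preserved), structural rewiring, or any experimental
dataset; agreement here is internal consistency of the model world, not
a fit to recordings.

## Mean-field module

Population rates follow a Wilson–Cowan relaxation
`τ ν̇ = −ν + [Σ J(ν_pre) ν_pre + h − ν_thr]₊` with threshold-linear gain and
`J = A w u∞ x∞`. The plasticity drift under independent Poisson firing,
`ẇ = λ k ν_pre ν_post (ν_post − ν_θ)` with `k = A₃⁺ τ₊ τ_y`, makes each
weight a bistable switch steered by the postsynaptic rate. Consequences
verified by the test suite:

* facilitating equilibria sit above depressing ones for matched coupling
  and input, and every depressing equilibrium respects the saturation
  bound `[A w/τ_rec + h − ν_thr]₊`;
* in the two-population heterogeneous setup with weak initial
  cross-coupling (scale 0.1; weaker than the spiking default because the
  threshold-linear gain has no saturation to arrest a transient runaway),
  the D→F coupling grows to its bound, the F→D coupling decays to zero,
  and the final rates straddle ν_θ — the stable heterogeneous motif;
* with per-synapse kind mixing (depressing with probability p), the top
  stable equilibrium interpolates monotonically between the pure cases.

Rate-model parameters (τ = 10 ms, ν_thr = 2, A = 10, unit gain slope, in
rate units) live in their own block and are deliberately not matched to
the spiking simulations.

## Known limitations

* Every printed constant of the source framework had to be reconstructed
  from the component models' original publications; quantities that were
  only ever reported numerically (exact symmetry-index values, motif
  fractions, firing rates of specific figures) are reproduced only
  qualitatively, at reduced network size and duration.
* The homogeneous large-network motif statistics at N = 100 are weakly
  non-random under the connection-independence null (the pattern is
  clear, but single-category significance needs the full N = 1000 scale).
* The symmetry-index null model assumes uniform random weights under the
  same pruning/clipping pipeline; it is a Monte-Carlo null, with the
  `(k+1)/(n+1)` estimator, not a closed form.
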