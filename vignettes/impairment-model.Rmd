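---
title: "Modelling ionic-regulation impairment with an extended AdEx neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ionic-regulation impairment with an extended AdEx neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adexz)
```

## The model and its assumptions

Hodgkin–Huxley-type models can reproduce seizure-like single-cell dynamics
driven by slow ionic changes (elevated extracellular potassium in
particular), but their stiffness makes them expensive as building blocks of
large networks. This package takes the opposite route: the two-variable
adaptive exponential integrate-and-fire (AdEx) neuron is extended with a
single slow variable `z` that lumps all consequences of impaired ionic
regulation:

$$
\begin{aligned}
C\,\dot V &= g_L\big((E_L+z)-V\big) + g_L\Delta_T
  \exp\!\Big(\frac{V-(V_T-\beta z)}{\Delta_T}\Big) - w - g_p z + I_s,\\
\tau_w\,\dot w &= a\big(V-(E_L+z)\big) - w,\\
\dot z &= \varepsilon\,(Z_0 - V - z),
\end{aligned}
$$

with the reset $V \ge V_D \Rightarrow V \to V_R,\ w \to w + b$ and a
refractory clamp of length $t_\mathrm{ref}$. The interpretation: a rising
`z` depolarises the leak reversal (`E_L + z`, the Nernst-potential shift of
a potassium build-up), lowers the sodium-activation threshold by a scaled
amount (`V_T - beta z`), and is opposed by a lumped restorative conductance
`g_p` (pumps, co-transporters, exchangers). `Z0` is the potential towards
which the impairment drags the system; it is the single severity dial. The
model deliberately cannot produce depolarization block: the reset forbids a
stable fixed point at depolarised `V`, so that family of patterns is out of
scope.

### Parameters, units, defaults

All quantities live in the canonical system mV / ms / pA / nS / pF, which is
dimensionally closed (nS·mV = pA, pF·mV/ms = pA). Defaults of
`adex_params()`:

| parameter | value | meaning |
|---|---|---|
| `C` | 200 pF | membrane capacitance |
| `g_L` | 10 nS | leak conductance |
| `E_L` | −65 mV | resting potential |
| `V_T` | −55 mV | exponential threshold |
| `Delta_T` | 2 mV | spike-initiation sharpness |
| `tau_w` | 500 ms | adaptation time constant |
| `a` | 1 nS | subthreshold adaptation |
| `b` | 60 pA | spike-triggered adaptation jump |
| `I_s` | 0 pA | external current |
| `V_D` | −40 mV | spike-detection potential |
| `V_R` | −65 mV | reset potential |
| `t_ref` | 5 ms | refractory period |
| `epsilon` | 5·10⁻⁴ ms⁻¹ | impairment relaxation rate |
| `Z0` | −40 mV | impairment attractor |
| `g_p` | 10 nS | counteractive conductance |
| `beta` | 0.5 | threshold-shift scaling |

Two unit decisions deserve a note. Published tables for this model family
quote the adaptation constant in seconds and the slow rate in s⁻¹;
`convert_params_si()` performs the conversion and logs it. For `epsilon` the
package fixes 5·10⁻⁴ **per millisecond** (a z time constant of 2 s). The
literal per-second reading would give a 33-minute time constant, under which
no regime change could express itself within the 8–20 s simulations the
model family is used for, and none of the regime boundaries below would be
observable; the 2 s timescale reproduces all of them, and matches the
unit-less parameter sets used for phase-space work (`tau_w = 200`,
`epsilon = 0.001`). `Delta_T` is a voltage (mV) even where tables typeset it
with a time unit.

## Numerical scheme

`simulate_neuron()` uses fixed-step explicit Euler, `dt = 0.1` ms by
default, with spike detection `V >= V_D` checked after each step and the
spike time recorded at the end of the detecting step (no sub-step
interpolation: at 0.1 ms it is immaterial for rate statistics). During the
refractory window the membrane is clamped at `V_R` while `w` and `z`
continue to integrate against the clamped potential (a flag freezes `w`
instead). The exponential term is evaluated as written; a non-finite result
aborts with the step index rather than being clipped, because it can only
arise from a missed detection. Steps above 1 ms are rejected. The choice of
Euler is deliberate: it is the standard for integrate-and-fire network
models, and the suite pins it with a convergence check (tonic spike count at
`dt = 0.1` vs `0.05` ms differs by at most 2) and with a bit-equality test
against an independent plain-R classical-AdEx reference in the `z = 0`,
frozen-z limit.

Initial conditions default to `(V = E_L, w = 0, z = 0)` — the healthy rest
state, from which the slow variable drags the cell into its regime.

## Fast-subsystem analysis

Treating `z` as a parameter (the `epsilon -> 0` limit, `frozen_z = TRUE` in
the integrator) leaves the planar `(V, w)` fast subsystem. Equilibria solve
a scalar equation in `V` along the w-nullcline; `fixed_points()` brackets
roots with a 4001-point sign scan on `V ∈ [E_L − 40, V_D]` refined by
`uniroot()`, which is derivative-free and robust to the exponential's
stiffness. Stability comes from the closed-form Jacobian
(`adex_jacobian()`, `trace_det()`). `bifurcation_diagram()` scans a z window
(default `[−30, 60]` mV, chosen to bracket both events for the defaults),
bisects the saddle-node on the root-count change and the Andronov-Hopf on
the trace sign change of the non-saddle branch (with a positive-determinant
check), both to 10⁻⁶ mV; equilibrium residuals are held below 10⁻⁹. One
subtlety found during development: for the default parameters the
trace-positive window on the lower branch is only ~5·10⁻³ mV wide — far
narrower than any reasonable grid — so the Hopf scan augments the grid with
points approaching each fold from below. Branch jumps above 5 mV between
adjacent grid points trigger local grid refinement instead of silent
continuation. The homoclinic structure connecting the spiking limit cycle is
*not* computed (detecting spiking onset is the simulation classifier's job),
and no limit-cycle continuation or Floquet analysis is attempted.

With `a = 0` the determinant is negative wherever the trace vanishes, so no
Hopf point can exist — the suite checks this, and the fold of the
V-nullsurface (`nullsurface()`, `fold_curve()`) sits exactly on
`V = V_T − beta z`.

## Classifying firing patterns

`classify_pattern()` discards a 2 s transient (the slow variable needs time
to express the regime; runs shorter than 12 s are refused) and applies, in
order:

* **quiescent** — post-transient rate < 0.1 Hz;
* **sustained ictal** — mean ISI ≤ 1.5·`t_ref` (firing pinned near the
  refractory-limited maximum, where `w` saturates), spiking covering > 90%
  of the window, and *at most one* silent gap > 200 ms;
* **bursting** — ≥ 2 fast-ISI clusters (intra-burst ISI < 50 ms) separated
  by ≥ 2 recurring silences > 500 ms;
* **tonic** — everything else.

The burst thresholds (50 ms / 500 ms) come from the visible timescales of
the patterns themselves and are exposed as arguments; they are the operative
definition of "bursting" here. The single-long-silence allowance in the
ictal rule exists because the slow passage into the ictal state crosses
exactly one burst-like silence shortly after the transient cutoff; a rule
demanding literally gap-free firing would misread the steady ictal state as
bursting and shift the apparent bursting/ictal boundary by ~8 mV. Silences
that *recur* are what distinguishes bursting.

`regime_boundaries()` sweeps `Z0` (defaults: −65 to −10 mV at 0.5 mV, 20 s
per point) and bisects each label change to 0.1 mV. With the defaults the
four regimes appear in order with three boundaries:

| boundary | |Z0| (mV) |
|---|---|
| quiescent → tonic | 48.0 |
| tonic → bursting | 43.0 |
| bursting → sustained ictal | 21.0 |

The quiescent→tonic value agrees to 0.03 mV with the fast-subsystem
prediction: quiescence requires the quasi-static equilibrium
`z* = Z0 − V*(z*)` to stay below the fold, which fails for `Z0` above
≈ −48. The tonic→bursting transition is sharp and dt-robust (identical at
`dt` = 0.1 / 0.05 / 0.02 ms: the post-transient ISIs jump from ~350 ms
regular to 5–9 ms clusters between `Z0 = −43.2` and `−43.0`), so the package
reports it at 43, a few mV above the round value of 40 often quoted for this
model family; both figures lie between the reference cases of tonic firing
at −45 and bursting at −40.

## The network

`build_network()` draws a directed Erdős–Rényi graph (each ordered pair
independently with `p = 0.05`), splits 10,000 cells 80:20 into
regular-spiking (RS) excitatory and fast-spiking (FS) inhibitory
populations, and assigns `Z0_impaired` to `N_SC` cells drawn uniformly from
the excitatory population; everyone else gets `Z0_healthy = −65 mV = E_L`,
which guarantees quiescence in isolation (`z* = 0`). FS cells are
non-adapting (`a = b = 0`, configurable) — a standard convention for
interneurons in AdEx networks, flagged here because it is a package choice,
not part of the published parameter table. Synapses are conductance-based
(`I_syn = g_E(E_E − V) + g_I(E_I − V)`, `E_E = 0`, `E_I = −80` mV) with
quantal increments `Q_E = 1.5` nS / `Q_I = 5` nS per presynaptic spike and
exact exponential decay (`tau_syn = 5` ms); the decay uses the closed-form
factor per step, so no Euler error enters the stiffest linear part.
Delivery is effective from the next step (one-step latency, no conduction
delays, no plasticity, no spatial structure). Identical configuration and
seeds give bit-identical event lists.

**Initial conditions.** The default starts every cell at `V = E_L` with the
impairment heterogeneously developed: `z(0) ~ U(0, Z0 − E_L)` per cell
(exactly 0 for healthy cells) and `w` on its nullcline. Two observations
force a choice here. A network started fully healthy (`z = 0` everywhere)
at, say, `Z0 = −50` mV is silent *forever*: −50 is below the isolated-cell
onset at −48, the quasi-static equilibrium never crosses the fold, and with
no drive there is nothing to perturb it — yet mildly-impaired networks are
precisely the interesting ones. Starting all impaired cells at the *same*
developed impairment instead makes them a perfectly synchronized volley that
detonates the whole network within milliseconds. The uniform draw is the
simple middle ground: impaired cells cross into activity progressively.
An optional homogeneous-Poisson background (`ext_rate_hz`, quantal `Q_E`
events per cell; default 0) is available to emulate the afferent tone of an
embedded cortical patch.

**Rates and regions.** `population_rate()` bins spikes at 5 ms, converts to
per-cell Hz and smooths with a centred 25 ms moving average; the maximum of
the smoothed trace is the summary used by `classify_region()`: region 1 if
the impaired population stays below 30 Hz, region 2 if impaired exceed it
but healthy excitatory cells stay below 30 Hz (inhibition contains the
pathology), region 3 if the healthy excitatory population is recruited too.
The 30 Hz cutoffs are package choices (exposed as arguments): well above any
physiological background, well below pathological oscillation amplitudes.

### A known, and honest, limitation

With the default parameter set the full-size network's recurrent excitation
dominates inhibition at every operating point: each cell receives ~400
excitatory afferents (quantal EPSP ≈ 2.4 mV, roughly one sixth of the
rest-to-threshold distance, against a rest rheobase of only ~80 pA) versus
~100 inhibitory afferents whose driving force near threshold is less than
half the excitatory one. In addition, the same inhibitory tone that should
shield healthy cells also clamps the FS population itself. The consequence,
reproduced over a wide range of initial conditions, impairment levels,
subpopulation sizes and background-drive rates: the network is effectively
bistable between silence/sparse contained activity (region 1) and global
saturation at the refractory ceiling of ~200 Hz (region 3), sometimes
cycling through adaptation-mediated silences. A middle regime in which the
impaired population oscillates at large but bounded amplitude (≲150 Hz)
while healthy cells keep normal rates — region 2 — does not emerge from
these parameters in this implementation. The acceptance checks encode the
three-region expectation anyway and are allowed to fail, because weakening
them to match the observed dynamics would hide a real property of the
parameter set. Users wanting a contained regime should expect to retune the
synaptic weights or add a stabilising ingredient (stronger or faster
inhibition, synaptic depression, external inhibitory tone).

## Problem sizes used by the tests

The test suite and the acceptance script run at the scales the methods are
specified at where that is cheap — the full 111-point regime sweep (20 s per
point) and full-size 10,000-cell, 8 s network runs — and at reduced scale
elsewhere: the three-region grid check uses a 3×3 grid at 4 s per run, and
the structural property tests (decoupled limit, decay, delivery,
reproducibility) use networks of 4–500 cells, where the properties are exact
rather than statistical. The synthetic spike-train generators
(`constant_train()`, `clustered_train()`, `poisson_events()`) provide
classifier and rate-estimation fixtures with known ground truth; they
emulate ISI structure only — no network correlations, no refractory
violations, no rate drift — so passing them validates the statistics
pipeline, not the biology.

## What the fixtures do and do not show

Synthetic trains and small deterministic networks verify the machinery:
delivery arithmetic, decay factors, classifier logic, reproducibility. They
cannot validate the model against physiology; the single-neuron regime
sequence and the fast-subsystem bifurcation structure are the points of
contact with the underlying biophysics, and the network-balance limitation
above marks where this parameter set stops being a faithful stand-in for
cortical tissue.
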