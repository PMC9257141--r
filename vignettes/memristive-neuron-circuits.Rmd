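---
title: "Memristive neuron circuits: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memristive neuron circuits: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memneuro)
```

## The models

The neuron cell membrane behaves electrically like a capacitor (the
phospholipid bilayer) in parallel with a leak (the ion channels). The
simplest circuit realization is the RC membrane: a fixed resistor `R` in
parallel with a capacitance `C`, driven by an external current, with

$$\frac{dV_m}{dt} = \frac{I_{ext}}{C} - \frac{V_m}{RC}.$$

`memneuro` simulates this model and its memristive twin, the MC membrane,
in which the resistor is replaced by a flux-controlled memristor: a
two-terminal element whose resistance $M(\varphi)$ depends on the
time-integral $\varphi = \int v\,dt$ of the voltage across it. Because ion
channels are themselves voltage-history-dependent, the memristor is a more
faithful electronic analogue of a channel population than a fixed
resistor, and because its resistance can collapse from $M_{off}$ = 20 kΩ to
$M_{on}$ = 100 Ω, the MC circuit charges and discharges up to two orders
of magnitude faster than an RC circuit sized at the same quiescent
resistance.

Unit conventions everywhere: time in ms, voltage in mV, current in µA,
resistance in Ω, capacitance in F, charge in C, power in W. Numerically
mV/ms equals V/s, so each ODE right-hand side is evaluated in SI and
applied directly on the ms/mV grid.

### The memristance law

Two laws are provided (`memristor_params(mode=)`), because the source
material for this device is internally inconsistent and we chose to keep
both halves testable rather than silently pick one:

* **`verbatim`** — the three-branch piecewise law: 20 000 Ω for
  $\varphi < -0.75$, $-3.98\times10^{8}\varphi + 10^{8}$ Ω on
  $[-0.75, 0.25)$, and 100 Ω for $\varphi \ge 0.25$, with exactly the
  printed inequality directions at the boundaries. Its linear branch is
  discontinuous at both thresholds and passes through $10^8$ Ω at zero
  flux — far outside the 100 Ω–20 kΩ operating range the same device is
  stated to occupy, and outside any range in which the membrane
  experiments could run.
* **`reconciled`** (default) — the linearization consistent with that
  operating range: $M(\varphi) = \mathrm{clamp}(10^4 - s\varphi,\,100,\,
  20000)$ with $M(0) = 10^4$ Ω and the slope $s = 9900/0.25 = 39600$ Ω
  per flux-unit chosen so the low-resistance endpoint is reached exactly
  at the upper threshold $\varphi = 0.25$. This mode is continuous,
  nonincreasing in flux and range-confined, and is what every membrane and
  network simulation uses.

**Flux units.** The thresholds ±0.75/0.25 are unreachable on a millisecond
time base if $\varphi$ is measured in V·s at mV drive (100 mV for 1 ms is
only $10^{-4}$ V·s). The internal flux unit is therefore the mV·s
(`flux_scale = 1e3` per V·s, configurable): 100 mV sustained for 2.5 ms
then crosses the 0.25 threshold, which is consistent with the
milliseconds-scale switching the transient experiments display.

### Transients

For the series charging circuit ($E$ = 100 mV, $C = 10^{-6}$ F,
$R = 10^3$ Ω, so $\tau = RC$ = 1 ms) the closed forms are
$V_C = E(1-e^{-t/\tau})$, $V_R = Ee^{-t/\tau}$, $I = (E/R)e^{-t/\tau}$;
discharge from $V_{C0}$ follows $V_C = V_{C0}e^{-t/\tau}$ with
$V_R = -V_C$. The MC circuit in *frozen* coupling holds $M$ at its value
for the initial flux and reuses these forms with $\tau = MC$ (0.1 ms in
the low-resistance state); in *coupled* mode the flux evolves with the
element voltage and the trace is integrated numerically. Traces carry full
charge ($Q = CV_C$) and power bookkeeping ($P_E = EI$, $P_C = V_CI$,
$P_{leak} = V_{leak}I$), and the package checks the resulting identities —
KVL, $P_E = P_C + P_{leak}$ while charging, $P_C + P_{leak} = 0$ while
discharging — rather than assuming them.

The finite-difference integrator is the corrected first-order recurrence

$$V_C(t+\Delta t) = V_C(t) + \frac{\Delta t}{\tau}\bigl(E - V_C(t)\bigr),$$

with $E = 0$ for discharge. The same recurrence is sometimes printed with
a minus sign before the drive term; in that form every step moves the
voltage *away* from the supply and the iteration diverges. The divergent
variant is retained behind `verbatim_recurrence = TRUE` purely so the
difference is demonstrable; it is excluded from every scientific code
path. Step-size policy: default $\Delta t = \tau/1000$; a warning above
$\tau/10$; a hard error at $\Delta t \ge 2\tau$, the explicit-Euler
stability boundary (for coupled memristor runs the check is re-evaluated
against the state-dependent $\tau = M(\varphi)C$ every step).

"Fully charged/discharged" is operationalized as the conventional
$5\tau$ criterion, threshold $1 - e^{-5} \approx 99.33\%$: 5 ms for the
reference RC circuit, 0.5 ms for the low-resistance MC circuit.
`crossing_time()` reports level crossings with linear interpolation
between grid points, so reported times are grid-resolution-independent to
first order.

One inconsistency is resolved in favour of the mathematics: during
discharge the capacitor voltage at $t = \tau$ is
$V_{C0}e^{-1} \approx 36.8$ mV (not 63 mV, which applies to charging);
the package follows the exponential discharge law.

### Membrane drives and response classes

`stimulus()` generates the step, single-pulse, pulse-train and
Gaussian-random drives. Pulse trains are specified by count and total
action time only; the on/off split within each period is governed by a
duty cycle, default 0.5 (symmetric alternation, matching the regular
waveforms of the reproduced experiments), because no pulse width is
printed anywhere in the source experiments. Sampling uses a
sample-and-hold convention: the value at a grid point applies over
$[t, t+\Delta t)$.

`classify_response()` labels trace morphology:

* `quiescent` — response below 1% of the steady-state scale
  $I_{max}R$;
* `oscillatory_potentials` — the repeated full charge/discharge
  excursions the circuits produce when each pulse leaves the membrane
  time to discharge: at least two peaks preceded by troughs below 50% of
  the peak, *and* such full excursions form the majority of all peaks;
* `subthreshold_superposition` — otherwise: pulses arrive faster than
  the membrane discharges and responses stack.

The majority requirement is a deliberate design choice. A bare "two
qualifying peaks" rule mislabels staircase superposition traces, because
the very first rise from rest always starts below any trough threshold
and the second trough of a stacking staircase sits right at the 50%
boundary (ratio 0.485 for the 4-pulse/20 ms case). Requiring full
excursions to dominate ties the label to the steady-state morphology,
classifies all the canonical configurations correctly (4 pulses/20 ms →
superposition; 16 or 38 pulses/1000 ms → oscillatory), and is invariant
under time-step refinement. Both thresholds (1%, 50%) are configurable;
this is a descriptive classifier of a first-order circuit's driven
oscillations, not a biophysical spike detector — the circuits have no
threshold mechanism, so "action potential" here means a full
charge/discharge excursion.

### The spiking network

The collective experiment couples 2 000 neurons (1 600 excitatory, 400
inhibitory — the 4:1 cortical ratio) for 2 000 ms with fresh Gaussian
thalamic drive every millisecond. Neuron dynamics follow the standard
quadratic integrate-and-fire-with-recovery scheme with the usual
heterogeneity (excitatory cells interpolate regular-spiking to
chattering, inhibitory cells the fast-spiking continuum), spike cut at
30 mV with reset, and two 0.5 ms half-steps of the membrane update per
millisecond to tame stiffness. Recorded potentials are clipped at the
spike cut, so the recorded peak of any spiking run is exactly 30 mV.

Two choices here deserve justification:

* **Weight normalization.** The reference parameterization is defined at
  1 000 neurons. Scaling the population to 2 000 while keeping per-synapse
  magnitudes doubles each neuron's summed synaptic input, and the network
  saturates into runaway firing (≈85 Hz per neuron) that is maximally
  synchronous regardless of inhibition — the asynchronous/synchronous
  contrast disappears. Weights therefore carry the standard $1000/N$
  normalization, which preserves the reference input scale at any
  population size: at defaults the asynchronous regime fires at ≈7 Hz with
  synchrony index ≈0.03 and the weak-inhibition regime reaches ≈0.99.
* **Regime switch.** "Reducing the inhibitory input by two orders of
  magnitude" is implemented as a ×0.01 multiplier on inhibitory synaptic
  *weights*, not on inhibitory thalamic drive; the former is the
  interpretation that changes the collective regime.

The MC network variant (`izhikevich_mc`) adds a memristive leak
$-v/(M(\varphi)C_m)$ per neuron, each neuron's flux integrating its own
membrane potential under the reconciled law. Numerically the leak is
applied as its exact exponential decay factor
$e^{-\Delta t/(M(\varphi)C_m)}$ per half-step: in the low-resistance state
the leak rate reaches $10^4$ s$^{-1}$, where explicit stepping at
$\Delta t$ = 0.5 ms is unstable, while the exponential form is
unconditionally stable and exact for the frozen-$M$ sub-step. The flux is
clamped to the interval over which the reconciled law actually varies
(between the $M_{off}$ and $M_{on}$ endpoints), which prevents unbounded
flux drift during long hyperpolarized stretches without affecting the
memristance. A pinned memristor (`flux_scale = 0`) reduces the variant
bit-exactly to the plain scheme with a fixed resistive leak
(`leak_R = M(0)`), which is how the equivalence is tested.

Since no synchrony statistic is printed in the source material,
`synchrony_index()` implements the variance-of-population-rate measure
$\chi^2 = \mathrm{Var}(\bar n)/\langle\mathrm{Var}(n_i)\rangle$ on binned
spike counts (default bin 10 ms): near the $1/N$ floor for independent
firing, near 1 for coherent firing, invariant to neuron relabeling, and
0 by definition for an empty raster.

## What the generator emulates — and what it does not

All data here are synthetic by construction: the package *is* the
simulator, and its default parameters are the study conditions
($E$ = 100 mV, $C = 10^{-6}$ F, $R = 10^3$ Ω for series transients,
$R = 10^4$ Ω for membrane drives, 10 µA stimuli, 1600/400 neurons,
2 000 ms runs). Passing tests therefore demonstrate internal consistency
of the circuit models and integrators, and reproduction of the printed
transient readings — not fidelity to biological membranes. In particular:
the first-order circuits have no refractoriness, no voltage-gated channel
kinetics and no spatial structure; the "action potentials" are driven
charge/discharge oscillations, not regenerative spikes; the network's
thalamic drive is white Gaussian current, not structured input; and the
memristance law is an idealized piecewise device, not a fitted physical
memristor model.

## Problem sizes

Closed-form traces are evaluated on grids of $10^3$–$10^5$ points;
convergence tests use $\Delta t = \tau/100$ vs $\tau/200$; membrane runs
use $\Delta t$ = 0.01 ms over up to 1 000 ms ($10^5$ steps); network
property tests use a 200-neuron, 400 ms configuration, while the
synchrony-ordering and recorded-peak checks run the full 2 000-neuron,
2 000 ms network (5 seeds per regime for the ordering, by median). These
sizes were chosen so each check exercises the regime it speaks about
while the whole suite stays desk-scale.

## Worked example

```{r example, eval = FALSE}
library(memneuro)

# RC charging: 63 mV across the capacitor after one time constant
tr <- rc_charge(series_circuit(E = 100, C = 1e-6, R = 1e3),
                seq(0, 5, by = 0.001))
round(tr$V_C_mV[tr$t_ms == 1], 2)   # 63.21

# the MC circuit in its low-resistance state charges 10x faster
mc <- series_circuit(memristor = memristor_params(), phi0 = 0.25)
crossing_time(mc_charge(mc, seq(0, 0.6, by = 1e-5)), 63.2)  # ~0.1 ms

# a 16-pulse train over 1000 ms produces full oscillations
tr <- integrate_membrane(membrane_circuit(),
                         stimulus("pulse_train", amplitude = 10,
                                  count = 16, duration = 1000))
classify_response(tr)               # oscillatory_potentials, 16 peaks

# asynchronous vs synchronous network regimes
p <- network_params(seed = 1)
synchrony_index(run_network(build_network(p), p))          # ~0.03
p2 <- network_params(seed = 1, inhibitory_scale = 0.01)
synchrony_index(run_network(build_network(p2), p2))        # ~0.99
```

## Known limitations

* The verbatim memristance law is kept exactly as printed, including its
  discontinuities; no interpolation is attempted at the branch
  boundaries.
* The coupled-MC "time constant" is state-dependent; the single 0.1 ms
  figure refers to the frozen low-resistance state.
* The reported half-current crossing times of the step experiment
  (8.392/8.286 ms) are not reproducible from the stated parameters
  ($\tau\ln 2 \approx 6.93$ ms after a 3 ms onset); the package asserts
  the analytic law instead.
* The network variant's memristive leak is a model extension defined by
  this package (the source gives no network-level equations); both the
  plain and memristive variants are provided so the comparison is
  explicit.
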