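---
title: "The axonwave conduction model: assumptions, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The axonwave conduction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`axonwave` simulates action-potential conduction along the myelinated
central axon of an auditory-nerve fibre and asks how dysmyelination after
acoustic overexposure (AOE) changes it. This vignette is the package's own
account of the model: what is assumed, which parameters matter, how the
numerics work, and where the design was genuinely open.

## The model

The axon is a periodic, unbranched chain: 7 nodes of Ranvier alternating
with 6 internodal regions (INRs), each INR containing two paranodes (PN),
two juxtaparanodes (JP) and a central axonal segment. Default node-to-node
spacing is 100 µm; axoplasmic resistivity is 70 Ω·cm; external resistance is
zero; both ends are sealed (zero axial flux).

Membrane currents:

* node: I~Na~ = g~Na~ m³h (V − V~Na~) and I~HT~ = g~HT~ n³(1 − γ + γp)(V − V~HT~),
  plus leak; g~Na~ = 50, g~HT~ = 15 mS·cm⁻², V~Na~ = +50 mV, V~HT~ = −80 mV,
  bare membrane at 1 µF·cm⁻² with g~L~ = 0.2 mS·cm⁻², V~L~ = −63 mV.
* juxtaparanode: I~LT~ = g~LT~ l r (V − V~LT~), g~LT~ = 2 mS·cm⁻²,
  V~LT~ = −80 mV (first-power l·r, configurable exponents).
* internodal membrane (PN/JP/axon): passive only. The myelin sheath is not
  modelled as a second cable; it is folded into effective lumped values
  (control: 0.0184 µF·cm⁻², 10.89 µS·cm⁻²; AOE: 0.0290 µF·cm⁻²,
  20.3 µS·cm⁻², the thinner post-exposure sheath being leakier and more
  capacitive).

Every gate obeys dj/dt = α~j~(V)(1 − j) − β~j~ j with α = k~α~e^{η~α~V},
β = k~β~e^{η~β~V} (`gating_rate_table()`). Gates therefore stay in [0, 1]
for any trajectory, and relax mono-exponentially to α/(α+β) under a voltage
clamp — both properties are exercised in the test suite.

### The repaired sodium closing rate

One rate constant is deliberately changed from the parameter set this model
family circulates with. As printed there, k~βm~ = 0.0381 ms⁻¹; together
with k~αm~ = 76.4 ms⁻¹ and the η values this puts sodium half-activation
near **−95 mV**, so m∞(−63 mV) ≈ 0.93: the channel is open at rest, the node
cannot hold a resting potential (a single node equilibrates near −29 mV with
h inactivated), and the cable cannot conduct at all. The package default
uses k~βm~ = 3.81 ms⁻¹ — a one-decimal-shift repair chosen on biophysical
grounds before any conduction measurement: it moves half-activation to
−37.5 mV (the standard value for auditory-brainstem sodium channels), keeps
the activation time constant in the tens of microseconds a node needs, and
yields a stable rest near V~L~. With the repair, the resting potential of
the full control cable settles at −68.5 mV and the control conduction
velocity lands within a few percent of the value this model is known for.
`gating_rate_table(beta_m = "printed")` recovers the literal set.

### Two AOE scenarios

Geometry (`region_geometry()`): AOE elongates the node (1.3 → 6.15 µm,
diameter 0.8 → 1.28 µm), shortens the PN (2.34 → 1.52 µm) and lengthens the
JP (5.14 → 6.23 µm).

* **AOE1** — channels redistribute evenly over the enlarged regions. Areal
  densities are multiplied by the control/AOE area ratio
  (`density_rescale_factor()`), conserving total channel number to machine
  precision. For the node that factor is 0.132, which reproduces exactly
  the alternative "6.6 / 1.98 mS·cm⁻²" nodal density set shipped as the
  `nodal_kanemasa` preset — strong internal evidence for the
  area-conserving reading (a length-ratio variant is available via
  `aoe1_scaling = "length"`).
* **AOE2** — channels stay where they were: the node keeps its control
  length (and densities) and is extended by two passive bare-membrane `n1`
  inserts of 2.425 µm (so n1 + node + n1 = 6.15 µm, the AOE1 node length);
  `j1` inserts extend the JP and are treated as myelinated internodal
  membrane, since they lie under the sheath.

In both scenarios dysmyelinated INRs take the AOE passive values; a node
takes AOE geometry when at least one flanking INR is affected. The central
axonal segment of each INR is stretched so the node-to-node spacing equals
the configured internode length — the tabulated region lengths alone sum to
only ~25 µm and could not realize a 100 µm internode, let alone the
internode-length sweep.

### γ

The weight γ of the modulatory p gate inside I~HT~ is constrained to (0, 1)
but has no published value; the package default is 0.1, exposed as
`channel_params(gamma = )`. At rest the p term contributes at most γ·(1−p∞)
≈ 2% of the n³ factor, and conduction velocity changes by well under 1%
across γ ∈ [0, 0.5] (the gate only matters during prolonged
depolarization).

## Numerics

Space: each region is split into compartments no longer than 0.1 of the
local passive length constant λ = √(rad·R~m~/(2R~a~)) (`discretize()`).
With the model's parameters λ is large (internodal λ ≈ 2 cm equivalent,
nodal λ ≈ 380 µm), so most regions are a single compartment and the default
control cable has 37 compartments. Axial resistance between neighbours is
the sum of half-compartment resistances 4R~a~(l/2)/(πd²).

Time: a staggered scheme. Gating rates are evaluated at the current
voltage and each gate advanced by the exact exponential update of its
locally linear ODE; the voltage system is then solved implicitly (backward
Euler) as a symmetric tridiagonal system via the Thomas algorithm — the
production path is C++ (`src/stepper.cpp`), with a line-for-line pure-R
twin (`backend = "r"`) kept as a readable reference and cross-checked to
1e-12 in the tests. An independent adaptive-step stiff integrator
(deSolve's `lsoda`) serves as the oracle for single-compartment
trajectories (agreement within 1 mV at dt = 0.001 ms).

Initialization: all compartments start at V~L~ = −63 mV with gates at
steady state, then relax stimulus-free for 20 ms (taken in coarse 0.1 ms
backward-Euler steps — unconditionally stable, and the settle phase has no
fast dynamics). The residual |dV/dt| must fall below 10⁻³ mV/ms or a
warning reports it. The true resting potential (−68.5 mV for control;
below V~L~ because the low-threshold K⁺ conductance is partly open at rest)
emerges from this phase.

Default dt for conduction measurements is 0.001 ms. This model's
inter-node delays are ~20 µs, so the historical 0.01 ms step of this model
family under-resolves them: CV at dt = 0.01 is 5.49 m/s and drifts to 6.13
as dt → 0.001, after which halving dt changes it by 0.7%. The package
default reports the converged value; the coarser step remains one
`sim_config(dt = 0.01)` away. The long firing-rate protocol uses
dt = 0.0025 ms (frequencies are insensitive to it).

Degenerate inputs: a 1-compartment cable bypasses the tridiagonal solve;
leak-free passive cables are legal (used by the charge-conservation test);
non-finite voltages abort with a "dt too large" diagnostic rather than
returning NaN.

## Measuring conduction in an electrotonically compact cable

The whole 7-node cable spans ~608 µm while the internodal λ is far larger,
so the cable is electrotonically compact: any local depolarization reaches
every node within ~0.1 ms — the same order as the total conduction delay.
Consequences, all visible in traces:

* After the first regenerative event the distal nodes fire in near
  synchrony; with strong stimuli the sealed far end (which receives a
  reflected, doubled depolarization) can even peak marginally *earlier*
  than its neighbour.
* Measured CV depends on stimulus amplitude: for control at dt = 0.001 ms,
  0.15 nA gives ~3.7 m/s, 0.2 nA gives 6.13 m/s, 0.3 nA gives ~15 m/s
  (distal nodes pre-depolarized by the stimulus fire sooner). There is no
  amplitude-invariant plateau; a CV for this cable is only meaningful
  together with its stimulus.

The package therefore fixes one protocol and reports it alongside every
measurement. Spike times are peak times (quadratically interpolated between
samples; threshold 0 mV), CV is the centre-to-centre axial distance from
node 0 to node 6 divided by the first-peak delay, and a measurement is
*valid* only if both nodes spike and the delay is positive; otherwise it is
a block (no distal spike) or flagged invalid (non-positive delay,
near-synchronous firing). The default stimulus is a 0.2 nA, 0.2 ms pulse at
node 0; when a cable cannot produce a valid measurement at that amplitude
(the AOE node has 7.5× the control nodal capacitance, so 0.2 nA is
subthreshold there) the amplitude doubles on a dyadic ladder until the
measurement is valid (`measure_cv()`). The ladder keeps the stimulus
minimal without per-condition hand constants; no single absolute amplitude
can serve every condition, because amplitudes that drive the AOE node
synchronize the control cable.

For the dysmyelination-extent sweep (`sweep_affected_inrs()`), affected
internodes are counted from the **distal** end so the stimulated node keeps
control geometry until the whole axon is affected, and the k = 0 row is
exactly the control measurement. The stimulus ladder still escalates
mid-sweep when the distal AOE block demands it (visible in the
`amplitude_nA` column), so the velocity-versus-k curve is monotone only
within a fixed-amplitude regime — an honest limitation of measuring a
compact cable, not of the sweep.

## The firing-rate protocol and its scope limit

`fi_curve()` injects 200 ms pulses and counts spikes at a mid-axon node.
The isolated central axon has an input resistance of roughly 3 GΩ (total
leak ≈ 3×10⁻⁴ µS), so currents of 0.2–1 nA exceed its dynamic range by
more than an order of magnitude: each pulse evokes an onset spike (or two)
followed by depolarization block, at every amplitude and in every
condition (~5–15 Hz equivalent counts). Sustained repetitive firing at
tens-to-hundreds of Hz under such currents requires the current sink of the
soma and peripheral axon, which this package deliberately does not model.
The protocol is implemented and tested for what it is; its acceptance-level
comparison against repetitive-firing behaviour fails and is left failing,
with this analysis, rather than being tuned around.

## Test and problem sizes

The test suite runs the default 37-compartment control cable (and its AOE
counterparts, 43–67 compartments) at dt = 0.001 ms over ~4 ms windows;
convergence checks halve dt and the compartment bound; analytic checks use
passive fixtures (single compartment for RC charging; a 6 mm uniform
cylinder, λ ≈ 472 µm, for exp(−x/λ) decay and the discretization
pigeonhole). The full suite completes in well under two minutes on one
CPU.

What the built-in conditions emulate — and what they do not: the geometry
and passive values describe a single canonical fibre, not fibre-to-fibre
variability; myelin is a lumped effective membrane (no explicit periaxonal
double cable); gating is deterministic (no channel noise); no temperature
dependence. Passing tests show the solver and protocols are faithful to
this parameterization, not that the parameterization captures any
particular biological axon.

## Known limitations

* CV is protocol-dependent (see above); cross-condition CV ratios inherit
  that dependence through the stimulus ladder.
* The internode-length sweep's shortest lengths (50 µm) put the cable deep
  into the near-synchronous regime and yield inflated velocities (~24 m/s);
  from 75 µm up the sweep sits in the physiological 2–12 m/s range and
  flattens towards 300 µm.
* The historical "about 200 µm" figure for the control length constant is
  not reproducible from any tabulated (radius, R~m~) pair with the stated
  formula; the package computes λ ≈ 0.202 **cm** for the internodal axon —
  suggestive of a unit slip — and treats λ purely as a discretization
  bound.
* Only the central axon is modelled: no soma, no peripheral axon, no
  synapse, hence no realistic F–I behaviour (see above).
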