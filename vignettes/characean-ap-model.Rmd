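---
title: "An IP3-gated calcium-store model of the characean action potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An IP3-gated calcium-store model of the characean action potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charAP)
```

## The model

Giant internodal cells of Characeae (here *Nitellopsis obtusa*, with
*Chara australis* as the reference) fire action potentials (APs) whose
depolarizing current is carried by Ca²⁺-activated Cl⁻ channels in the
plasma membrane. The Ca²⁺ that opens them is released from internal
stores through a channel gated by a second messenger; the model follows
the animal-physiology paradigm and uses IP₃ for that role. `charAP`
couples two pieces:

**Store excitation.** The store channel has four states — unbound (R,
fraction `x2`), IP₃-bound (RI, `x3`), additionally bound by an activating
Ca²⁺ (RIC₊, `x4`, the *conducting* state), and inactivated by a second
Ca²⁺ (RIC₊C₋, `x5`). Mass-action transitions with rates `k1, k_m1,
k2, k_m2, k3, k_m3` connect the chain, and the fractions always sum
to one. Cytoplasmic Ca²⁺ is carried in scaled form `x1 = C/C0`
(`C0` = 1.56 µM) and obeys

$$\frac{dx_1}{dt} = \lambda(\gamma_0 + \gamma_1 x_4)(1 - x_1)
  \;-\; \frac{p_1 x_1^{\,n}}{p_2^{\,n} + x_1^{\,n}},$$

with λ = 1 + ν_r the store/cytoplasm volume correction, γ₀ the IP₃-free
store leak, γ₁ the density of IP₃-activated channels, and a Hill-type
store pump (coefficients `p1 = p1'/C0`, `p2 = p2'/C0`, exponent
`hill_n`). Excitation begins with an IP₃ bolus `I0` at t = 0 decaying as
`I0·exp(-0.2 t)`; a brief TRP-like Ca²⁺ inflow is represented by a
dimensionless square-pulse increment `dCa` added to the `x1` value seen
by every consumer (release term, pump, state transitions, chloride gate)
inside its window.

**Membrane voltage.** The membrane PD obeys
`dV/dt = -(I_Cl + I_p + I_orc + I_bkg + I_TRP)/Cm` with five
outward-positive current densities:

* `I_Cl = G_Cl,max · y · (V - E_Cl)` — the Ca²⁺-activated chloride
  current. The gate is first order, `dy/dt = k_a x1 (1 - y) - k_i y`,
  so its steady state is the saturating function `k_a x1/(k_a x1 + k_i)`
  of cytoplasmic Ca²⁺. The gate starts closed (`y(0) = 0`): a resting
  chloride conductance would destroy the observed resting PDs,
  especially in saline conditions where `G_Cl,max` reaches 80 S m⁻².
* `I_p` — proton-pump current from a symmetric Eyring barrier:
  voltage-dependent rates `k_io = kio0·e^{z_pFV/2RT}`,
  `k_oi = koi0·e^{-z_pFV/2RT}` combined with voltage-independent cycle
  rates `kappa_oi`, `kappa_io`. Cells without pump activity omit the
  term entirely (`pump = NULL`), they never use zero rates.
* `I_orc` — K⁺ outward rectifier: GHK constant-field flux times two
  Boltzmann open probabilities. `P_o+` (half-activation `V50_plus` =
  +100 mV) shuts the channel at rest and opens it on depolarization —
  it is what makes the rectifier rectify. `P_o-` describes closure at
  strongly negative PDs; we implement it as the mirror Boltzmann
  `1/(1+e^{-z_gF(V-V_{50-})/RT})`, which is ≈ 1 everywhere above
  `V50_minus` and falls to 0 below it. (The alternative sign convention
  would shut the channel over the entire physiological range and reduce
  the rectifier to zero, contradicting its role in repolarization.)
  The GHK factor `u/(1-e^{-u})` is evaluated by series near `u = 0`, so
  the current is continuous through 0 mV and vanishes exactly at the K⁺
  Nernst potential.
* `I_bkg = G_bkg (V - E_bkg)` — empirical ohmic leak, `E_bkg` = -100 mV.
* `I_TRP = G_Ca (V - E_Ca)` inside the pulse window — the electrical
  counterpart of the `dCa` increment. `G_Ca` defaults to 0: the pulse
  then acts on the store model only, which is how the bundled parameter
  sets are defined.

## Parameters, units, and the bundled registry

Interfaces speak mV, µM, mM (= mol m⁻³), S m⁻², seconds; internally the
voltage equation runs in volts and A m⁻². Temperature is fixed at 293 K
(RT/F ≈ 25.25 mV). Two quantities are not part of the published
parameter columns and are package defaults, both exposed:
`Cm = 0.01` F m⁻² (typical characean plasma membrane) and
`V50_minus = -300` mV (so `P_o-` ≈ 1 over the physiological range).

`load_parameter_set(table, column)` returns any column of the three
bundled fitted-parameter tables (freshwater, sorbitol, and saline
conditions for several cells, plus the *Chara* reference column). Blank
cells in the printed tables mean "unchanged" and are resolved by
inheriting from the nearest filled cell to the left. The Hill exponent
defaults to `n = 2` for the *Chara* column and `n = 1` for all
*Nitellopsis* columns, following the fits; the original store model used
`n = 4`, and all three are available through `hill_n`.

```{r registry}
parameter_columns(2)
ps <- load_parameter_set(2, "AP_av Nitellopsis APW")
ps
resting_pd(ps)
```

### Schedules

Two slow drifts around the AP are modelled as explicit schedules on
simulation time (t = 0 at the IP₃ bolus):

* **Pump-rate ramp.** The proton pump is transiently inhibited by high
  cytoplasmic Ca²⁺; this is expressed as a piecewise-linear change of
  `kappa_oi`. The study reports only ranges for the ramp times (start
  0.5–5 s, stop 9–12 s), so the registry uses the mid-range `[2.75,
  10.5]` s. End values are never printed; the registry solves for the
  `kappa_oi` whose zero-current PD equals the printed *post*-excitation
  resting PD, because that is precisely what the ramp was introduced to
  reproduce. Columns whose post-AP PD is unreachable by any positive
  pump rate (depolarized cells resting above the background reversal)
  get no ramp.
* **Chloride-conductance decay.** Where a column prints a conductance
  range (`20–4.1` S m⁻²), `G_Cl,max` decays exponentially from the first
  to the second value over the first 5 s (`tau` = 1 s, both
  configurable). Neither time constant is stated in the source; 1 s
  makes the decay essentially complete within the printed 5 s window.

## Numerical choices

* Stiff/adaptive integration with `deSolve::lsoda`, `rtol = 1e-8`,
  `atol = 1e-10`. The dynamics span milliseconds (Ca²⁺ collapse under a
  strong pump) to tens of seconds (IP₃ decay), so an implicit-capable
  solver is the right default.
* Integration restarts at every discontinuity of the forcing (`dCa`
  window edges, ramp knots, decay cut-off), so the solver never steps
  across a jump.
* The effective Ca²⁺ `x1 + dCa` is floored at 0 inside rate terms. With
  even Hill exponents a negative effective Ca²⁺ would make the pump
  term a source and diverge in finite time; the floor removes that
  artifact without affecting admissible states.
* State fractions are never clipped inside the solver; conservation
  `x2+x3+x4+x5 = 1` holds to 1e-8 along trajectories and is asserted in
  the tests.
* The default initial state is all channels unbound and
  `x1 = Ca_rest/C0` (0.02 µM/1.56 µM ≈ 0.0128), the only configuration
  consistent with a stable pre-stimulus baseline; `store_rest_state()`
  returns the exact no-IP₃ fixed point of the `x1` equation when a
  strictly stationary start is wanted.
* The resting PD is found by bisection to 0.01 mV on `[-300, -40]` mV —
  the balance is monotone-in-practice over that bracket and bisection is
  immune to the pump current's steep exponential tails.
* Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  the full-trace residual in mV. The finite-difference step (`epsfcn =
  1e-6`) is set above the ODE-solver noise floor; the machine-precision
  default would difference pure integration error and produce garbage
  gradients. The optimizer is local and bounded, from a user-supplied
  start — the published parameter columns were themselves produced by
  manual local tuning, and we claim nothing global.

## Excitability of the bundled parameter sets

Under the equations above, excitation is regenerative only if the gain
of the loop x₁ → RIC₊ → Ca²⁺ release exceeds the store pump's grip at
low Ca²⁺. That balance differs sharply across the bundled columns:

* The *Chara* reference column (`n = 2`, `p2' = 0.035` µM) and the
  overnight-saline Cell 3 column (`n = 1`, `p2' = 0.33` µM) are
  excitable: the IP₃ bolus alone fires a full AP. Cell 3's modelled
  behaviour matches its measured one — this is the cell that produced
  spontaneous AP cascades.
* The *Nitellopsis* average-fit column (`n = 1`, `p2' = 0.0197` µM) is
  **sub-threshold**: with `n = 1` and so small a `p2'`, the pump holds
  resting scaled Ca²⁺ near 2·10⁻⁴ and removes the printed `dCa` pulse
  faster than the conducting state can build. A linear-stability
  estimate puts the firing threshold at `x4 ≈ 0.07` while the pulse
  reaches `x4 ≈ 0.01`; no reading of the pulse semantics we tested
  (offset visible to all consumers, offset invisible to the pump, state
  jump, source flux) crosses that gap, and the fixed-step RK4 oracle
  agrees with the adaptive solver that the column does not fire. The
  simulation of this column therefore reproduces the resting PD and the
  sub-threshold response, not a full AP, and the acceptance suite
  reports that honestly rather than adjusting any printed value.
  Properties that need an excited store (Hill-exponent repolarization
  ordering, inactivation residence) are tested as relaxations from an
  excited state, where they hold cleanly; threshold and
  parameter-recovery properties are tested on the excitable columns.

```{r excitable}
sim <- simulate_ap(load_parameter_set(2, "AP_av Chara APW"),
                   t_end = 20, dt_out = 0.01)
ap_features(sim$trace, rest_window = c(0, 1), post_window = c(18, 20))
```

## Trace arithmetic

`ap_features()` needs operational definitions the source never states:
the AP *duration* runs from the first upward crossing of rest + 5 mV to
the last downward crossing of post-rest + 5 mV (guard band
configurable), and the *half-width* is the time spent above the midpoint
between pre-rest and peak. `average_traces()` aligns on the stimulus
clock by default (peak alignment is available for multi-cell data with
variable latency) and reports the pointwise mean with the *population*
standard deviation. `subtract_tonoplast()` implements the series-sum
identity (vacuolar recording = plasma membrane + tonoplast): means
subtract, SDs add in quadrature, and when one ensemble is shorter it is
extended at its final resting value with the SD marked missing rather
than invented.

## Synthetic data: what it does and does not emulate

`generate_recording()` / `generate_population()` stand in for the
study's raw recordings, none of which were deposited. They emulate:
single APs of seconds duration started at t = 0, additive i.i.d.
Gaussian electrode noise (SD ~1 mV), lognormal cell-to-cell variability
on positive rate parameters (median-preserving, `sdlog =
sqrt(log(1+cv²))`), and optional repetitive-AP records built by
concatenation at a fixed interval. They deliberately do not emulate
electrode drift, impalement artifacts, the stimulation-current ramp
(the model replaces it with the IP₃ bolus), or any correlated noise.
Passing the recovery tests therefore shows that the pipeline is
self-consistent under the stated noise model — not that real recordings
with drift or correlated disturbances would be fit equally well.

## Problem sizes used by the tests

Unit tests integrate 8–20 s of model time at output steps of 0.01–0.05
s; the solver-against-oracle checks run fixed-step RK4 at dt = 1e-4 s
over 20 s; parameter-recovery fits use 12 s traces at 0.02 s sampling
with three free parameters and three noise seeds. The full suite runs
in a few minutes on one core.

## Known limitations

* No spatial Ca²⁺ diffusion, single store compartment, no explicit IP₃
  production kinetics (only the fixed exponential decay).
* Tonoplast electrophysiology is handled purely as trace arithmetic;
  there is no tonoplast transporter model.
* The voltage never feeds back into the store dynamics, so AP threshold
  behaviour lives entirely in the Ca²⁺ subsystem; depolarization-induced
  triggering cannot be represented.
* Repetitive/spontaneous AP trains are composed by the synthetic-data
  generator, not emergent from the single-AP simulator.
* The average-fit freshwater column is sub-threshold under these
  equations (see above); its printed peak envelope is not reproduced
  and is reported as such.
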