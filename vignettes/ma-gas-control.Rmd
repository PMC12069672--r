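---
title: "Modelling O2 control in a blower-ventilated modified-atmosphere storage box"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling O2 control in a blower-ventilated modified-atmosphere storage box}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabox)
```

## The system

A modified-atmosphere (MA) storage box holds respiring produce (the
reference case: 16 kg of broccoli in a 70 L airtight box) whose metabolism
depletes headspace O2. A small air blower plus a narrow diffusion tube are
the only air exchange paths. A microcontroller holds the O2 set point
(3%) with a feed-forward duty cycle: once per hour it reads the produce
temperature and computes the **blower-ON frequency (BOF)** — the seconds of
blower operation that replace the O2 the produce will respire that hour.
There is no O2 sensor in the loop; everything rests on the model below.

## The model

**Respiration.** Specific O2 uptake (mL kg⁻¹ h⁻¹) is Michaelis–Menten in
O2 with an uncompetitive-style CO2 inhibition term and a residual uptake
under low O2, each Arrhenius-scaled:

$$r(O_2, CO_2, T) \;=\;
\frac{V_{max}(T)\, O_2}{k_m + \left(1 + CO_2/k_i\right) O_2}
\;+\; R_{min}(T),$$

with $V_{max}(T) = R_{max}\,e^{-Ea_{max}/(R_g (T + 273))}$ and
$R_{min}(T) = R_{min}\,e^{-Ea_{min}/(R_g (T + 273))}$. The Kelvin offset is
273 exactly — the pre-exponential factors were fitted with that offset, so
it is part of the parameterisation (changing it to 273.15 without refitting
shifts every rate). Whole-box demand multiplies by the product weight
$W_p$; the package exposes it per hour (`respiration_box()`) and per second
(`respiration_box_s()`), which differ by exactly 3600.

**Gas exchange.** The box exchanges air with the ambient (21% O2) at a
coefficient $k$ (m³ s⁻¹) that depends on the blower state: forced
($k_{O_2,ON}$) or passive through the tube ($k_{O_2,OFF}$, three orders of
magnitude smaller). The instantaneous O2 influx is
$k\,(21 - O_2)/100$ (converted to mL s⁻¹), and over an interval the
headspace relaxes exponentially towards ambient with time constant
$V_f/k$, where $V_f = V_T - W_p/D_p$ is the free volume. All transport
arithmetic is done in SI units with mL and percentage points only at the
interfaces; the legacy scaling constant that appeared in earlier
formulations of the exchange equations (a combined empirical/unit factor of
0.36) is deliberately not used — explicit unit bookkeeping reproduces all
published controller statistics, whereas the literal factor does not yield
consistent magnitudes.

**The controller.** With demand $D$ (mL per cycle, evaluated at the set
point, the MA reference CO2 of 15% and the current temperature) and
exchange rates $r_{on}, r_{off}$ (mL s⁻¹ at the set-point gradient),

$$BOF = \frac{D - c\, r_{off}}{r_{on} - r_{off}}$$

for a cycle of $c$ seconds, clamped to $[0, c]$. The rates are evaluated at
the set point (a linearised operating point) rather than integrated along
the exponential: $k_{ON} t / V_f \ll 1$ within a burst, and this is the
form that reproduces the published sensitivity statistics. At the broccoli
base values and 10 °C the balance gives 47.9 s per hour.

```{r}
compute_bof(respiration_params(), box_geometry(), diffusion_params(),
            control_settings(), temp_c = 10)
```

## The simulator and its two kinetics modes

`simulate_box()` integrates the headspace mass balance with explicit Euler
at `dt = 1` s (configurable up to 60 s). Time constants are hours, so Euler
is ample; the stepping is verified against the exponential closed form in
the test suite, and fractional burst lengths are integrated exactly (the
boundary step uses a partial duty fraction), so per-cycle supply matches
the BOF to machine precision rather than to the step size. The run starts
at ambient; during **pulldown** the blower is off and respiration (at the
actual gas state) drains O2 to the set point. Control cycles then start,
anchored at the set-point crossing, and the BOF is recomputed each cycle
from the current temperature.

Two design questions were genuinely open, and both defaults were chosen to
reproduce the documented controller behaviour:

* **Rate evaluation during control** (`control_kinetics`). The firmware's
  equations are written entirely at the operating point
  ($O_{2,set}$, reference CO2), so the default `"setpoint"` mode integrates
  exactly that model: respiration fixed at the set-point demand, exchange
  at the set-point gradient. Because the BOF balance then closes exactly,
  each burst returns the headspace to the set point and the trajectory is a
  stable sawtooth whose trough is the set point minus the OFF-phase drop —
  at 20 °C about 1.5% and at 5 °C about 2.8%, the documented oscillation
  bands. The alternative `"state"` mode is the full mass balance with both
  rates at the actual state; it is the physically complete description, and
  its limit cycle instead settles where supply equals demand — band mean
  near the set point and peak *above* it (trough ≈ 2.3% at 20 °C). The two
  modes bracket reality; the setpoint mode is what the deployed controller
  predicts and is therefore the default.
* **Burst placement** (`burst`). The within-hour position of the blower
  burst is not documented. The default places it at the end of each cycle,
  which together with the setpoint kinetics pins the post-burst peak at the
  set point (the documented band top); `"start"` is available and changes
  only the phase of the sawtooth, not its amplitude.

```{r}
traj <- simulate_box(temperature_profile(24, 20))
limit_cycle_stats(traj, window_h = 5)
```

**CO2.** The variability analyses hold CO2 at 15% (`co2_mode = "fixed"`,
the default). A `"dynamic"` mode integrates CO2 with production
`rq × respiration` (respiratory quotient `rq`, default 1) and efflux
reusing the O2 exchange coefficients; it is exploratory only, because no
measured CO2 transport constants exist for this box, and no default claim
is made about the CO2 equilibrium.

## Variability analyses

The ten uncertain parameters (`broccoli_params()`) carry base values and
absolute errors; the absolute error is used directly as the standard
deviation of an independent normal distribution, truncated at zero by
redrawing (at these scales every parameter sits ≥ 8σ above zero, so
truncation is vanishingly rare). That identification of SD with the stated
absolute error is itself a modelling choice; it is validated by quadrature —
the root-sum-of-squares of the one-at-a-time half-ranges reconstructs the
Monte Carlo spread within 15%.

* `monte_carlo_bof()` — 10,000 draws by default, BOF per draw at fixed
  storage conditions (10 °C, CO2 15%, O2 set 3%, the optimum for broccoli).
  Mean ≈ 47.8 s, SD ≈ 3.7 s.
* `oat_bof_all()` — one-at-a-time ranges, the signed difference
  `BOF(base + err) − BOF(base − err)`; product weight (≈ +5.1 s), the
  low-O2 pre-exponential factor (≈ +3.8 s) and the Michaelis–Menten
  constant (≈ −2.3 s) lead the ranking. The box volume $V_T$ cancels out of
  the BOF balance entirely (demand and both exchange rates are independent
  of the free volume), so its range is exactly zero.
* `pareto_contributions()` — variance-based shares, $(\text{range}/2)^2$
  normalised to sum 1. The variance convention (not |range|) is what makes
  the top three parameters carry > 80% of the variability.
* `bof_correlations()` — Pearson r between each draw column and BOF
  (≈ 0.7 for weight, 0.5 for the low-O2 factor, −0.3 for $k_m$).
* `oat_o2_delta()` — trajectory-level perturbation: simulate baseline vs
  perturbed parameters over a temperature profile and difference the O2
  curves; a heavier load reaches the set point sooner.

```{r}
head(oat_bof_all(), 3)
pareto_contributions(oat_bof_all())[1:3, ]
```

## The synthetic world and what a green test establishes

The supply-chain preset (`preset_profile()`) carries the documented stage
temperatures 20 → 7 → 3 → 1 → 5 → 10 °C in order; the stage *durations*
were never published, so the defaults (8, 12, 24, 48, 12, 36 h) are a
realistic cold chain chosen once and labelled synthetic. Simulated
trajectories therefore reproduce the documented oscillation bands and
pulldown behaviour at each temperature, but not any experimental curve
point-by-point. Real data also contain measurement noise, door-opening
transients and produce heterogeneity that the generator does not emulate;
`temp_noise_sd` injects optional Gaussian noise into the temperature the
controller reads, and all randomness flows from a single seed.

## Numerical choices and limitations

* Explicit Euler, `dt` in (0, 60] s; `cycle_s` must be a multiple of `dt`.
* O2 is clipped to [0, 21]%; clipped volume is tracked in `clip_ml` so the
  mass-balance accounting still closes exactly (it is zero in normal
  operation).
* BOF is clamped to [0, cycle]; clamping is flagged per cycle.
* The controller is feed-forward from temperature only — no O2 feedback,
  no PID, no CO2 set-point control.
* Measured respiration rates at 20 °C reported for the validation
  experiment are not recoverable from the registry's pre-exponential
  factors (they stem from a reference-temperature parameterisation of prior
  work) and are out of scope, as are CO2 absorption kinetics.
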