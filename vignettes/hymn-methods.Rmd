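---
title: "Modelling hydrophobically gated memristive nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrophobically gated memristive nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hymn)
```

## The physical picture

A sub-nanometre hydrophobic pore in contact with water is bistable. The
lumen can be liquid-filled ("wet"), in which case ions flow and the pore
conducts, or occluded by a vapour bubble ("dry"), in which case it does
not. No moving parts are involved: the gate is the phase state of the
confined water. The order parameter used throughout is the filling
fraction $\xi_w \in [0, 1]$, and the central object is the free energy
$F(\xi_w)$ in units of $k_BT$, a double well whose minima are the dry and
wet states and whose barriers set the switching kinetics.

An applied voltage $\Delta V$ stabilises the liquid (electrowetting).
Above a critical voltage $V_c$ the wet minimum drops below the dry one.
Because the barrier crossings take time, the conductance of a pore
ensemble lags the driving voltage; under cyclic driving at intermediate
frequency this lag produces a pinched hysteresis loop in the I--V plane —
the defining signature of a memristor. `hymn` implements this chain
end-to-end: free-energy profiles, voltage-dependent rates, deterministic
and stochastic ensemble dynamics, design-space classification, and the
processing used on current recordings.

## Filling free energy

Two sources of profiles are supported.

**Capillarity (classical nucleation theory).** `build_cnt_profile()` uses
the simplest bubble geometry: a single axial vapour domain with flat
menisci in a cylinder of radius $R$ and length $L$. For vapour fraction
$v = 1 - \xi_w$,

$$W(v) = 2\pi R L \gamma \cos\theta \, v \;+\; \Delta P \,\pi R^2 L\, v
\;+\; c_m \gamma \pi R^2 \quad (v > 0), \qquad W(0) = 0,$$

with $\gamma$ the surface tension, $\theta$ the contact angle, $\Delta P$
the liquid--vapour pressure difference, and $c_m$ the number of menisci
charged to a partially dry pore (default 1: a bubble growing from one pore
mouth). For a hydrophobic wall ($\cos\theta < 0$) the profile is a ramp
with a jump at the wet end, so the drying barrier is the meniscus cost
$c_m\gamma\pi R^2$ and the wetting barrier is the wall-plus-pressure term.
Two consequences are worth stating because they shape the design maps:
the drying barrier is independent of pore length and of voltage, and the
dry state is globally stable iff the aspect ratio $L/d$ exceeds
$c_m / (4 |\cos\theta|)$ (about 1.03 at $\theta = 104^\circ$). Curved
menisci, annular bubbles and line tension are deliberately out of scope;
they change barrier heights by $O(1)$ factors but none of the qualitative
structure.

**Tabulated profiles.** Anything producing a two-column table of
$(\xi_w, F)$ can be read with `read_profile_tsv()`; `make_double_well()`
generates smooth parametric double wells for testing, built from
zero-slope cubic (smoothstep) segments so that the minima, saddle and
barriers are exactly the requested control values and no spurious extrema
exist.

**Electrowetting tilt.** The voltage dependence is the declared surrogate

$$F(\xi_w; V) = F(\xi_w; 0) - \left(a_{ew} V^2 + \mu_{ew} V\right)\xi_w ,$$

a capacitive interpolation that is linear in the filling (a dry pore
stores no extra dielectric energy, a wet one the full $a_{ew}V^2$).
With $\mu_{ew} = 0$ the response is even in $V$ — the symmetric,
*unipolar* device. A dominant dipole term $\mu_{ew}$ makes positive and
negative voltages act in opposite directions — the *bipolar* device, the
behaviour expected for pores with a strong intrinsic dipole. Two routes
fix $a_{ew}$: `calibrate_coupling()` solves for the value that makes the
two minima degenerate at a target $V_c$ (the reference model uses
$V_c = 1.2$ V, giving $a_{ew} \approx 12\,k_BT/\mathrm{V}^2$), and
`ew_from_geometry()` uses the parallel-plate estimate
$\alpha\,\varepsilon_0(\varepsilon_w - 1)\pi R^2 / (2 L k_BT)$ whose
dielectric efficiency $\alpha = 0.30$ is itself a calibration chosen once
so that the model pore's 10-second wetting voltage lands near 1.2 V.
$\alpha$ absorbs everything the plate picture ignores and should not be
interpreted microscopically.

State location on tabulated profiles (`locate_states()`) uses discrete
local extrema with plateaus collapsed to their smallest-$\xi_w$ point;
endpoints count as candidate minima because capillarity profiles have
their minima exactly at $\xi_w = 0$ and 1. When a tilt creates more than
two minima (the profile edge becomes a shallow extra minimum under strong
tilts) the landscape is split at the most prominent interior maximum and
the deepest minimum on each side is kept.

## From barriers to rates

`arrhenius_rates()` uses $k = \nu_0 e^{-B}$ with a single attempt
frequency $\nu_0 = 10^{10}\,\mathrm{s^{-1}}$ shared across the package, a
molecular attempt-frequency scale: with the reference barriers of 18 and
5 $k_BT$ it places the equilibrium wetting and drying rates at
$1.5\times10^2$ and $6.7\times10^7\,\mathrm{s^{-1}}$. Barriers never
produce super-attempt rates: once a tilt collapses a barrier the rate is
capped at $\nu_0$, and `rate_curves()` flags such voltages in its
`capped` column. Detailed balance $k_w / k_d = e^{-\Delta F}$ holds
exactly by construction.

The alternative estimator `mfpt_rates()` treats the filling coordinate as
overdamped diffusion with constant diffusivity $D$ and computes mean
first-passage times

$$\tau = \frac{1}{D}\int_{x_0}^{b} dy\, e^{F(y)}
\int_{\mathrm{edge}}^{y} dz\, e^{-F(z)},$$

with the absorbing boundary at the target minimum and the reflecting
boundary at the profile edge *behind* the starting minimum, so the whole
starting basin contributes its equilibrium population, as in the Kramers
picture. The double integral is evaluated exactly for the
piecewise-linear interpolant of the tabulated profile (per-cell
closed-form integrals of $e^{\pm F}$ plus the ordered same-cell term),
with log-shifts so barriers of hundreds of $k_BT$ cannot overflow. For
deep wells this estimator agrees with the Kramers rate
$\sqrt{F''_{\min}|F''_{\mathrm{saddle}}|}\,e^{-B}/2\pi$ to within a few
percent, and with Arrhenius rates within an order of magnitude when
$\nu_0$ is matched to the well curvatures.

Rate curves are tabulated on a voltage grid (601 points on $[-3, 3]$ V
for the reference model) and interpolated linearly in $\log_{10} k$;
requests outside the grid raise an error rather than extrapolate.

## Ensemble dynamics

For $N_p$ independent pores with single-pore wet conductance $g_0$, the
current is $I = N_p g_0 n \Delta V$ with $n$ the wet probability obeying
the two-state master equation

$$\frac{dn}{dt} = (1 - n)\,k_w(\Delta V) - n\,k_d(\Delta V).$$

`integrate_master_equation()` samples the voltage at step midpoints and
applies the exact constant-rate propagator per step,
$n \leftarrow n_\infty + (n - n_\infty)e^{-(k_w + k_d)\Delta t}$ with
$n_\infty = k_w/(k_w+k_d)$: unconditionally stable, $n \in [0,1]$ to
machine precision, and exact (not merely convergent) on
piecewise-constant voltage. The default resolution is 2000 steps per
cycle. For periodic driving the package exploits that one cycle of this
update is an affine map $n \mapsto An + B$ with $0 \le A < 1$; the
periodic orbit is the fixed point $B/(1-A)$, obtained from two cycle
integrations with no transient cycles to discard. `area_vs_frequency()`
builds on this to compute the enclosed area of the periodic I--V loop
(shoelace formula on the closed path, which also handles the
instantaneous sawtooth reset chord correctly) across a frequency sweep.

`simulate_pore_array()` simulates finite arrays: each pore is a two-state
Markov chain, advanced per step with the exact conditional flip
probability $(1 - n_\infty)(1 - e^{-K\Delta t})$ (wet) or
$n_\infty(1 - e^{-K\Delta t})$ (dry), $K = k_w + k_d$. This propagator is
unbiased with respect to the master equation for piecewise-constant
voltage — a naive $1 - e^{-k\Delta t}$ flip rule carries an
$O(k_w k_d \Delta t^2)$ occupancy bias that is easily visible in
large-ensemble averages. A hard precondition $\Delta t \le 0.1/\max(k)$
still bounds the voltage-resolution error; violating it is an error, not
a silent inaccuracy. Seeds are mandatory, traces are bit-reproducible,
and the caller's RNG stream is never touched. One pore yields a random
telegraph signal; tens of pores already give a visually continuous
cycle-averaged IV loop.

Waveform conventions: the sawtooth ascends linearly from 0 to its
amplitude over one period and resets instantaneously (phase 0 at $t=0$);
the triangle spans $-A \ldots +A$ symmetrically; pulse trains are
back-to-back triangular pulses $0 \to \pm\mathrm{peak} \to 0$. Initial
conditions default to the equilibrium $n$ at $V(0)$ and can be overridden
to expose the frozen-regime dependence on the starting state.

## Design criteria and region maps

A useful device must (1) be preferentially dry at 0 V, (2) wet below the
largest voltage $\Delta V^*$ the membrane can sustain, (3) dry quickly at
0 V, and (4) wet quickly at $\Delta V^*$. `evaluate_design()` and
`region_map()` score these with the closed forms of the capillarity
model: red cells fail (1); blue cells have $\tau_d(0) = e^{B_d}/\nu_0$
above 10 s (a vertical boundary in the diameter--aspect-ratio plane,
since $B_d = c_m\gamma\pi R^2$ depends on neither length nor voltage);
gray cells have $\tau_w(\Delta V^*) = e^{B_w(\Delta V^*)}/\nu_0$ above
10 s. Label precedence is red > green > blue > gray.

One genuinely open design choice deserves a note. Under the linear-in-
$\xi_w$ tilt the saddle of the capillarity profile sits adjacent to the
wet state, so the tilt lowers the thermodynamic gap and the wetting
barrier by the *same* amount; as a result the thermodynamic switching
voltage always exceeds the 10-second kinetic wetting voltage wherever
drying is fast, and a thermodynamic reading of criterion (2) would be
strictly stronger than the kinetic test (4) — the two regions could never
coexist and the kinetic window (e.g. aspect ratios about 1.0--1.9 at
$d = 1.04$ nm, $\theta = 104^\circ$, $\Delta V^* = 0.2$ V) would be
swallowed whole. The package therefore carries the wetting requirement on
the kinetic test, reports the thermodynamic switching voltage
`v_wet_thermo` in every evaluation, and reserves the green label for an
optional separate bound on it (`v_thermo_max`, default infinite). Models
whose saddle sits near the dry state would not have this degeneracy.

Allowed regions behave monotonically: raising $\Delta V^*$ only adds
allowed cells; raising the contact angle shrinks the allowed fraction
over the default grid ($d \in [0.5, 3]$ nm $\times$ AR $\in [0.5, 5]$,
$100 \times 100$).

## Trace analysis

**Capacitance subtraction.** Real recordings contain a membrane
capacitive current $C\,dV/dt$ and an ohmic leak $G_{leak}V$ on top of the
pore current. Under triangular or sawtooth driving $dV/dt$ flips sign
while $V$ does not, so the two are decorrelated over whole cycles and a
two-regressor least squares $I \sim C\,dV/dt + G_{leak}V$ separates them;
$dV/dt$ is taken by central differences with samples adjacent to slope
reversals excluded. Only the capacitive part is subtracted — the leak is
part of the device response and is reported, not removed. The leak
estimate absorbs the mean pore conductance, so it is accurate only when
the pore is mostly closed during the fit; the capacitance estimate does
not suffer from this and round-trips to well under 1% on synthetic
recordings.

**Cycle averaging and loop metrics.** `average_cycles()` folds the trace
modulo the period, splits branches by the sign of $dV/dt$ and averages
the current in 200 uniform voltage bins; branch noise shrinks as
$1/\sqrt{\text{cycles}}$. `loop_metrics()` integrates the
branch difference for the signed lobe areas, tests the pinch at the
origin against $3\times$ the bin-mean noise, and classifies polarity by
the point symmetry of the closed loop: a unipolar loop maps onto itself
under $(V, I) \to (-V, -I)$, which forces the two lobes to carry the
*same* signed area, while a bipolar loop breaks the symmetry,
self-intersects at the origin and carries opposite-signed lobes. The
classifier thresholds the antisymmetry defect at 15% of the RMS current
and treats loops whose area falls below 0.5% of the current--voltage
scale as polarity `none` (a resistor up to discretisation).

**Telegraph statistics.** At constant holding voltage the conductance
$G = I/V$ of a single gating pore is a two-level signal. The two modal
levels come from a two-component location fit (k-means); traces whose
modal separation is below 3.5 pooled standard deviations are rejected as
non-gating — the threshold sits above the ratio ($\approx 2.7$,
scale-free) that a forced two-component split reports on a single
Gaussian mode. Crossings are detected at the midpoint threshold with a
$\pm 0.5\sigma$ hysteresis band after a 5-sample running-median
prefilter; without the prefilter, single-sample noise excursions chop
dwells at 10--20 kHz sampling and inflate both rates severalfold. The
censored first and last dwells are excluded; rates are reciprocal mean
dwells, and `two_peak_fraction` reports the share of the mean conductance
attributable to samples within $2.5\sigma$ of the two modal levels.

## The synthetic-data generator

`synth_recording()` emulates the structure of planar-bilayer recordings:

$$I(t) = N_p g_0 s(t) V(t) + C\frac{dV}{dt} + G_{leak}V(t) +
\varepsilon(t),$$

with $s(t)$ the stochastic wet fraction from the pore-array simulator and
$\varepsilon$ white Gaussian noise. Defaults are conventional values for
this kind of experiment, declared once: $C = 100$ pF, $G_{leak} = 0.05$
nS, $\sigma = 0.01$ nA, 10 kHz sampling, $g_0 = 1$ nS. Ground truth
(including the seed) is stored in the trace metadata, and every
round-trip test reads the truth only from there. The generator does *not*
emulate 1/f noise, electrode drift, filter roll-off, sub-conductance
levels or pH-dependent protonation kinetics; passing round-trips
therefore validate the estimators against the stated noise model, not
against every artefact of real recordings.

Two deterministic model bundles are provided. `reference_fixture()` is
the unipolar reference: the 18/5 $k_BT$ double well (minima at
$\xi_w = 0.15$ and 0.90, saddle at 0.50, gap 13 $k_BT$), coupling
calibrated to $V_c = 1.2$ V, $\nu_0 = 10^{10}\,\mathrm{s^{-1}}$, rates on
$[-3,3]$ V. `bipolar_fixture()` is the synapse-demo model; since no
single set of device constants is canonical here, they were fixed once
from physical requirements and are declared, not fitted: a
nearly degenerate well with 25 $k_BT$ barriers so the state persists
between 0.2 s pulses ($k(0) \approx 0.14\,\mathrm{s^{-1}}$),
$\mu_{ew} = 150\,k_BT/\mathrm{V}$ so $\pm 100$ mV pulses tilt the
barriers by about 5 $k_BT$ in opposite directions, $a_{ew} = 12\,k_BT/
\mathrm{V}^2$ (negligible at 0.1 V, so the dipole dominates and the
device is bipolar), $g_0 = 1$ nS and $N_p = 4$ pores. Under the
$++++--++++$ triangular protocol (100 mV peaks, 0.2 s each) the mean
per-pulse conductance rises monotonically during excitatory runs, falls
during inhibitory ones, and the cumulative dissipated energy
$\int I V\,dt$ is of order 10 pJ.

## Numerical choices and problem sizes

* Profile grids default to 201 points on $\xi_w \in [0,1]$; barriers read
  off a tabulated capillarity profile carry one grid step of the ramp
  (about 0.5% at 201 points); the analytic closed forms are used where
  exactness matters (design maps).
* Bisection tolerance for $V_c$ is 1 mV; coupling calibration solves the
  degeneracy condition at the target voltage directly with `uniroot`, so
  the calibrated $V_c$ is exact by construction and $a_{ew}$ differs from
  the frozen-minima closed form by the relocation of the minima under
  tilt (about 0.5% for the reference well).
* Ties in extremum detection break toward smaller $\xi_w$ (plateaus
  collapse to their first point).
* The master equation uses 2000 steps per cycle by default; the stochastic
  $\Delta t$ bound $0.1/\max k$ is enforced as an error.
* Test problem sizes were chosen to keep the full suite fast while
  leaving the statistical checks well-powered: the stochastic-convergence
  check uses 200 seeds of $10^4$ pores over 50 samples; the
  cycle-averaged stochastic IV uses 50 pores over 20 cycles of a
  rate-rescaled reference model (the agreement properties are invariant
  under a common rate rescaling); telegraph round-trips use 60 s at
  10 kHz.

## Known limitations

* All profiles are surrogates: the capillarity form ignores meniscus
  curvature and elastocapillary effects, and the electrowetting tilt is a
  two-parameter caricature of the true field coupling. Quantities that
  depend exponentially on barriers inherit $O(1)$ uncertainty factors.
* Under the quadratic tilt calibrated to $V_c = 1.2$ V, driving to
  $2.5 V_c$ collapses the wetting barrier around 2.5 V, so wetting runs
  at the attempt-frequency cap near the sweep peak. This compresses the
  high-frequency decay of the hysteresis-area spectrum and pushes its
  maximum to about $2.4 \times 10^6$ Hz for the reference model — roughly
  a decade above the $\sqrt{k_w(0)k_d(0)} \approx 10^5$ Hz band-centre
  heuristic based on the equilibrium rates alone, and the quasi-static
  sawtooth loop retains the area enclosed between the ascent curve and
  the instantaneous reset chord. Rate curves, and everything downstream
  of them at strong driving, should be read as qualitative.
* The leak estimate in `subtract_capacitance()` is biased upward by the
  mean pore conductance of open pores (documented above).
* Pores are independent: no spatially resolved coupling, and membrane
  capacitance lives only in the recording generator and analysis, not in
  the dynamical state model.
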