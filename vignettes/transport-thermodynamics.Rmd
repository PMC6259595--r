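---
title: "Thermodynamic transmembrane transport: model, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic transmembrane transport: model, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionflux)
```

## The model

A transport event moves a fixed stoichiometry of molecules between the
extracellular (0) and intracellular (1) compartments: for each species $s$,
$n_s$ molecules from compartment $c_s$ to $d_s$. The work per event, in
units of $kT$, is

$$\Delta G_s = n_s (c_s - d_s)\left[\ln\frac{[s]_0}{[s]_1}
  - \frac{z_s v}{v_T}\right],
  \qquad v_T = \frac{kT}{q},$$

summed over species, plus an external term $\delta_{Ext}\, q\,v_{Ext}$ for
primary active transport (ATP hydrolysis, $v_{ATP}$ of order $-450$ mV).
The indicator $\delta_{Ext}$ is 1 exactly when the electrochemical part is
uphill. Forward and backward event rates split the Boltzmann factor with a
bias $b \in [0,1]$:

$$\alpha = r e^{-b \Delta G}, \qquad \beta = r e^{(1-b)\Delta G},
  \qquad \frac{\alpha}{\beta} = e^{-\Delta G} \ \text{for every } r, b,$$

giving the net flux $\Phi = \alpha - \beta$ and, for electrogenic
mechanisms ($\eta = \sum_s n_s (c_s - d_s) z_s \neq 0$), the current
$i = q\eta\Phi$. With the reversal composition
$v_o = \delta_{Ext} v_{Ext} + \sum_s n_s z_s (c_s - d_s) v_s$ the flux is
the bi-exponential

$$\Phi = r\left[e^{b x} - e^{(b-1)x}\right], \qquad
  x = \frac{\eta v - v_o}{v_T},$$

which vanishes at the reversal potential $v_o/\eta$, rectifies inward for
$b < 1/2$ and outward for $b > 1/2$, and reduces to a hyperbolic sine at
$b = 1/2$. One law therefore covers channels, ATPases, exchangers and
symporters; `mechanism_catalog()` provides twelve ready-made templates and
`flux()` evaluates both the concentration-explicit and the
reversal-potential form (the package tests their agreement to $10^{-10}$
relative).

Key assumptions worth keeping in mind:

* a single rate $r$ summarises the pore/carrier kinetics — no microscopic
  rate theory (temperature or pore-geometry dependence of $r$) is modelled;
* the bias $b$ is a structural property of the protein, constant in $v$;
* concentrations on both sides are fixed unless a model states otherwise
  (the pacemaker tracks intracellular Ca$^{2+}$ only);
* compartments are well mixed; no organelles, no spatial extension.

## The approximation ladder

`taylor_current()` expands the current about $v_o/\eta$ with coefficients
$1$, $(b - \tfrac12)$, $(3b^2 - 3b + 1)/6$; the order-1 term is exactly the
conductance-based current with $g = \eta^2 q r / v_T$
(`conductance_approx()`), which is why conductance models cannot rectify.
`ghk_current()` implements the constant-field current; multiplying its
numerator and denominator by $x_1^{b-1} x_0^{b} e^{(b-1) z_x v / v_T}$
turns it *exactly* into the bi-exponential form with a weakly
voltage-dependent amplitude (`ghk_amplitude()`), for any $b$ — the
constant-field model is a special case of the general law, not a rival to
it. At the extreme biases the current saturates one-sidedly
(`rectifier_limit_current()`), reproducing classical inward/outward
rectifiers.

A note on the divalent special case: substituting $\eta = -2$,
$v_o = -2 v_{Ca}$ into $2 q \eta r \sinh[(\eta v - v_o)/2 v_T]$ gives
$4 q r \sinh[(v - v_{Ca})/v_T]$ by oddness of $\sinh$ — the two printed
forms of the Ca-channel current are identical, and the package implements
the single general formula.

## Fitting current–voltage data

`fit_iv()` estimates $(v_o, b, rq)$ in

$$i(v) = rq\left[e^{\zeta b (v - v_o)/v_T} -
  e^{\zeta (b-1)(v - v_o)/v_T}\right]$$

by box-constrained least squares (`optim(method = "L-BFGS-B")`,
$b \in [0,1]$), with a deterministic data-driven start: $v_o$ from the
interpolated zero crossing of the observed current, $b = 1/2$, and $rq$
from the local slope (the model slope at $v_o$ is $rq\,\zeta/v_T$).
Identical inputs give bit-identical results; an independent
Levenberg–Marquardt fit (`minpack.lm`) is used as a cross-check in the test
suite, never as the implementation.

Choices made where the data source is silent:

* **Charge factor $\zeta$.** The embedded AMPA-Kainate measurements
  (`ampa_kainate_iv()`) were recorded in a Ca$^{2+}$ ringer, so the charge
  carrier is divalent and the fits use $\zeta = 2$. This is decisive: with
  $\zeta = 2$ the fitted amplitudes ($rq \approx 21$ pA) match the
  published fit, while $\zeta = 1$ forces $rq \approx 70$ pA and much
  shallower biases. The function default is $\zeta = 1$ (monovalent), set
  explicitly to 2 for these data.
* **Thermal voltage.** Oocyte recordings are made near room temperature;
  $v_T$ defaults to 25.7 mV in `fit_iv()` and is configurable.
* **Loss.** Unweighted ordinary least squares by default. These IV curves
  span two decades of current, so OLS is dominated by the large
  hyperpolarised currents; a $1/|i|$ weighting is available behind
  `weighting = "inverse_current"`. The weighted estimates differ
  noticeably (the GluR1+GluR3 bias moves from 0.42 toward 0.38), which is
  a useful sensitivity check but not the default.
* The OLS optimum of the digitized points does not coincide exactly with
  the fit parameters quoted alongside the original figure (which were fit
  to the original published curves, with an unstated objective and $v_T$);
  the package reports what the data given to it support.

`generate_synthetic_iv()` draws noiseless model currents on a voltage grid
plus i.i.d. Gaussian noise (default SD 5 pA on a 25-point grid spanning
$-100$ to $30$ mV, matching the scatter of the digitized data). It
emulates measurement noise only — no voltage-clamp series-resistance
artefacts, no leak subtraction errors, no correlated drift — so parameter
recovery on synthetic data demonstrates estimator correctness and
precision, not robustness to real-world recording artefacts.

## The membrane models

Both models write each membrane current as
$J_l = a_l \cdot (\text{gating}) \cdot \varphi_l(v)$ in pA/pF with
$\varphi(x, b) = e^{bx} - e^{(b-1)x}$, and gating built from the logistic
steady state $F_u(v)$ and the cosh-like rate $R_w(v)$
(`gating_steady_state()`, `gating_rate()`). The activation variable obeys
$\partial_t w = w^{k_w} [F_w(v) - w] R_w(v)$, a logistic-type flow that
keeps $w$ in $[0,1]$ (asserted numerically along trajectories).

**Sign conventions.** Outward current is positive and
$\partial_t v = -\sum_l J_l\ (+ i_{stim}/C_m)$. Each current's $\varphi$
argument is chosen so the current vanishes at its reversal potential and
has its physiological direction:

* K currents: $x = (v - v_K)/v_T$; pump: $x = (v - v_{NaK})/v_T$ with
  $v_{NaK} = 3 v_{Na} - 2 v_K + v_{ATP}$;
* transient Na (FS): $J_{NaT} = -a_{NaT} (1-w) F_m
  \varphi((v_{Na} - v)/v_T, b)$, inward below $v_{Na}$;
* L-type Ca (SAN): $J_{CaL} = a_{Ca}(1-w) F_m
  \varphi(2 (v - v_{Ca})/v_T, b)$, inward below
  $v_{Ca}(c) = (v_T/2)\ln(\mathrm{Ca}_{out}/c)$;
* Na-Ca exchanger (SAN): $J_{NaCa} = a_{NaCa}
  \varphi((\eta v - v_{NaCa})/v_T, b)$ with $\eta = -1$ and
  $v_{NaCa} = 2 v_{Ca} - 3 v_{Na}$, i.e. the net-charge convention applied
  inside the argument with a positive amplitude.

The exchanger convention deserves a frank paragraph, because the design
was genuinely open. Three readings were implemented and integrated:
(i) the fully sign-corrected thermodynamic current ($i = q\eta\Phi$ for
every mechanism) makes the exchanger an outward, hyperpolarising current
at diastolic potentials whenever intracellular Ca$^{2+}$ sits near its
resting value, and the pacemaker then has a globally stable fixed point
near $-76$ mV — no oscillation from any initial condition. (ii) Writing
the exchanger as $\varphi((v - v_{NaCa})/v_T, b)$ with
$v_{NaCa} = 2v_{Ca} - 3v_{Na}$ used directly as a reversal makes it a very
strong depolarising drive and collapses the cycle to roughly a third of
the reported period with a small amplitude. (iii) The convention above —
the equation set as printed, with positive normalised amplitudes
multiplying $\varphi((\eta v - v_l)/v_T)$ — is the only reading that
produces sustained pacemaking with the reported waveform features, and is
what the package implements. It is, however, thermodynamically anomalous
for the exchanger taken in isolation (the current is inward above the
composed reversal), and users building new models from `current()` and
`mechanism_catalog()` get the sign-corrected convention instead.

**Parameters.** `san_params()` and `fs_params()` carry the full default
sets: amplitudes (SAN: Ca 1, K 100, NaK 1, NaCa 3 pA on 30 pF; FS: Na
1400, K 4400, NaK 67 pA on 30 pF), potentials ($v_{Na} = 60$,
$v_K = -89$; $v_{ATP} = -420$ mV in the SAN set and $-430$ mV in the FS
set, composing pump reversals of $-62$ and $-72$ mV), gating
($g_m = 5, v_m = -25$; SAN $g_w = 3.6, v_w = -25, r_w = 0.005$ ms$^{-1}$,
$k_w = 0.3$, $b_w = 0.35$; FS $g_w = 4, v_w = -5, r_w = 2$ ms$^{-1}$,
$k_w = 1$, $b_w = 0.3$), biases (SAN $b_{NaK} = 0.35$, $b_K = 0.1$,
$b_{NaCa} = b_{Ca} = 0.5$; FS all $0.5$), and the SAN Ca balance
($c_\infty = 0.1$ µM, $r_c = 0.02$ ms$^{-1}$, $k_c = 0.00554$ µM·pF/pA/ms).
Everything is overridable by name. Three defaults are package decisions
rather than table transcriptions:

* **Time base.** All rates are per millisecond. The activation rates are
  tabulated in s$^{-1}$ in the source material, but $\partial_t v$ is in
  mV/ms and the reported periods and spike widths are only attainable on
  the millisecond scale; the literal per-second reading freezes the
  gating and produces no oscillation. Users wanting the literal reading
  can pass `r_w` (and `r_c`) scaled by $10^{-3}$.
* **Temperature.** 310 K ($v_T \approx 26.7$ mV), configurable through
  `transport_constants()`. The source never states the temperature, and
  the pacemaker period is quite sensitive to it (colder membranes cycle
  more slowly); all quantitative statements below are at 310 K.
* **Extracellular Ca$^{2+}$.** 2 mM (`ca_out = 2000` µM), a standard bath
  value, absent from the tabulated set; it only enters through
  $v_{Ca}(c)$, and logarithmically.

**Initial conditions** (unstated in the source): SAN
$(v, w, c) = (-60\ \mathrm{mV}, F_w(-60), c_\infty)$; FS
$(v, w) = (-72\ \mathrm{mV}, F_w(-72))$, which is within a couple of mV of
the FS resting fixed point. The first 2000 ms are discarded before any
metric is computed; the SAN settles onto its limit cycle well within that
(period and amplitude vary by under 1% across the last five cycles of a
7 s run, which is the problem size used throughout the tests and the
acceptance script).

**What the defaults actually produce** (computed by the test suite and
`scripts/acceptance.R` at 310 K): the SAN model cycles with period
$\approx 327$ ms, amplitude $\approx 84$ mV and maximal upstroke speed
$\approx 4.7$ V/s, with the Ca current showing exactly two inward peaks
per cycle — persisting when the $(1-w)$ inactivation is removed, which
confirms the double peak is a driving-force effect of the voltage
trajectory, not a gating artefact — and carrier currents (pump,
exchanger) an order of magnitude smaller than channel currents. The
reported reference values are $\sim 400$ ms and $\sim 70$ mV: the period
and amplitude under the printed parameter set therefore land about 18%
short and 20% large respectively. No admissible temperature reconciles
both at once (the amplitude is nearly temperature-invariant), so we
conclude the parameter set that generated the reference figures differed
from the printed one; the package keeps the printed values and reports
what they produce. The FS model is quantitatively faithful: rheobase
$\approx 44$ pA (within the reported 40–50 pA window) and maximal
$\partial_t v \approx 124$ V/s under an 80 pA step (within the reported
100–200 V/s).

## Numerical choices

* Energies are carried in $kT$ units end to end; voltages convert at the
  boundary through $v_T$. This keeps every exponent dimensionless and
  avoids unit bugs.
* The GHK quotient has a removable singularity at $v = 0$; for
  $|z v / v_T| < 10^{-4}$ it is evaluated by a second-order series of the
  quotient (continuity across the switch is tested).
* Integration uses `deSolve::lsoda` (adaptive, stiffness-switching) with
  `rtol = 1e-8`, `atol = 1e-10` and a 0.1 ms maximum step — the
  bi-exponential currents are stiff near spike upstrokes. Halving the
  tolerances changes the SAN period by well under 0.1%. Output is sampled
  every 0.05 ms (0.02 ms for FS stimulus runs), and the instantaneous
  $\partial_t v$ is recorded from the vector field along the solution, so
  upstroke-speed estimates are exact at sample points rather than
  finite-difference approximations.
* Spike detection uses linear interpolation of upward threshold
  crossings; thresholds are $-30$ mV for the SAN (mid-upstroke of a slow
  Ca spike) and 0 mV for the FS cell (mid-upstroke of a fast Na spike),
  both configurable. Metrics use the last 5 cycles by default.
* Rheobase is found by bisection (resolution 1 pA on [0, 100] pA);
  "sustained spiking" means at least 3 spikes in the final 500 ms of a
  2000 ms step, so single-spike transients do not count.
* Extremum detection in current traces tolerates flat runs (zero first
  differences) by locating sign changes between non-zero difference runs.
* CSV floats are written with a fixed 10-significant-digit format:
  identical runs give byte-identical files, and round trips are lossless
  to better than $10^{-9}$ relative.

## Limitations

* The SAN pacemaker under the printed defaults does not reproduce the
  reported period/amplitude pair (see above); treat its quantitative
  outputs as properties of the printed parameter set, not of the
  reference figures.
* The exchanger sign convention inside the SAN model is phenomenological
  (see the conventions section); energy accounting across a full SAN
  cycle should not be read off those currents.
* $r$ is a lumped rate: no temperature dependence, no saturation with
  concentration, no gating-current contribution.
* Na$^+$ and K$^+$ pools are static in both membrane models; only
  intracellular Ca$^{2+}$ is dynamic, with a single linear
  removal/buffering term.
* Fits assume a single transport pathway with voltage-independent $b$;
  mixtures of channel populations with different biases are not
  identifiable from a single IV curve.

## A worked mechanism, end to end

```{r, eval = FALSE}
library(ionflux)

cst <- transport_constants(310)
ncx <- mechanism_catalog("Na-Ca exchanger")
eta(ncx)                      # -1: electrogenic, one charge inward per event
reversal_vo(ncx, cst)         # 2 v_Ca - 3 v_Na from the default gradients
delta_G_total(ncx, v = -60, cst)

# approximation ladder at a glance
kch <- mechanism_catalog("K channel", bias = 0.1)
v <- seq(-120, 40, by = 1)
plot(v, current(kch, v, cst), type = "l")
lines(v, taylor_current(kch, v, order = 3, constants = cst), lty = 2)

# fit the embedded receptor data (divalent carrier)
fit <- fit_iv(ampa_kainate_iv("GluR3"), charge = 2)
summary(fit)
plot(fit)

# pacemaking and spike metrics
traj <- simulate(san_model(), tmax = 7000)
spike_metrics(traj, threshold = -30)
ca_current_extrema(traj)

# neuronal excitability
find_rheobase(fs_model())
```
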