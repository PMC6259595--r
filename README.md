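# ionflux

Thermodynamic models of passive and active transmembrane transport, for
electrophysiologists and modellers who want channels, pumps, exchangers and
symporters described by **one** current law instead of a zoo of ad hoc
formulas.

## The model

A transport event moves `n_s` molecules of each species `s` from
compartment `c_s` to `d_s` (0 = out, 1 = in). The work per event in kT
units is

    ΔG_s = n_s (c_s − d_s) [ ln([s]₀/[s]₁) − z_s v / v_T ],    v_T = kT/q

summed over species, plus an external energy `δ_Ext · q·v_Ext` for
ATP-driven transport. Forward and backward rates split the Boltzmann
factor with a rectification bias `b ∈ [0, 1]`,

    α = r·exp(−b ΔG),   β = r·exp((1−b) ΔG),   α/β = exp(−ΔG),

so the net flux is `Φ = α − β` and the current of an electrogenic
mechanism (`η = Σ n_s z_s (c_s − d_s)` ≠ 0) is `i = q η Φ`, equivalently

    i = q η r [ exp(b·x) − exp((b−1)·x) ],    x = (η v − v_o)/v_T,

with reversal potential `v_o/η`. `b = 1/2` gives a non-rectifying
sinh-shaped current; `b < 1/2` rectifies inward, `b > 1/2` outward.
Conductance-based currents are the tangent of this law at the reversal
potential (`g = η² q r / v_T`), and the Goldman–Hodgkin–Katz equation is
an exact algebraic rewriting of it — both available as explicit
approximations, with the identities enforced in the test suite.

On top of the core law the package provides:

* a twelve-mechanism catalogue (Cl/K/Na/Ca channels, Na-K/Ca/H ATPases,
  Na-Ca and Na-H exchangers, Na-I, K-Cl, Na-K-Cl symporters) with energy
  budgets, `η` and reversal compositions;
* least-squares fitting of `(v_o, b, rq)` to current–voltage data
  (`fit_iv()`, a classed model object with `coef`/`predict`/`plot`/…),
  including the embedded AMPA-Kainate receptor IV table;
* two ready-to-run membrane models built from the same current law — a
  cardiac sinoatrial-node pacemaker (v, w, Ca) and a striatal fast-spiking
  interneuron (v, w) — with a deterministic stiff integrator;
* spike-train analysis: threshold crossings, period/amplitude/upstroke
  metrics, bisection rheobase, per-cycle Ca-current extrema;
* a CLI (`inst/cli/ionflux.R`) with `catalog`, `fit`, `approx`,
  `simulate`, `analyze` and `rheobase` subcommands.

## Worked example

Fit the rectification bias of an AMPA-Kainate receptor from its IV curve
(currents carried by Ca²⁺, hence `charge = 2` in the exponents):

```r
library(ionflux)
fit <- fit_iv(ampa_kainate_iv("GluR3"), charge = 2)
fit
#> Rectifying-current fit to 'GluR3' (14 points)
#>   i(v) = rq [exp(2 b (v - v_o)/v_T) - exp(2 (b-1)(v - v_o)/v_T)], v_T = 25.7 mV
#>   v_o = -33.060 mV,  b = 0.4640,  rq = 21.643 pA
#>   residual SS = 592.1 pA^2
```

The receptor reverses near −33 mV and `b = 0.46` (just below 1/2) says the
flux is almost symmetric, with slight inward rectification; the
GluR1+GluR3 heteromer gives `b = 0.42` — more inwardly rectifying, as
expected from its subunit composition.

Energy bookkeeping for the Na-K pump at a holding potential of −70 mV:

```r
nak <- mechanism_catalog("Na-K ATPase", v_atp = -450)
delta_G_total(nak, v = -70)
#> Energy breakdown (kT units):
#>   Na       +15.3366
#>   K        +1.8699
#>   species total +17.2066
#>   external      -16.8453
#>   grand total   +0.3613
```

Moving 3 Na⁺ out and 2 K⁺ in costs ~17.2 kT against the gradients; one
ATP contributes ~16.8 kT, so at −70 mV the pump sits just above its
reversal (−60.3 mV under these concentrations) and runs forward only for
`v > v_NaK`.

Pacemaking from the bundled sinoatrial-node model:

```r
traj <- simulate(san_model(), tmax = 7000)
spike_metrics(traj, threshold = -30)
#> Spike metrics: period 326.88 ms (3.06 Hz), amplitude 83.87 mV,
#>   max dv/dt 4.650 V/s, 16 spikes
```

A slow (~3 Hz) Ca-driven action potential with a sub-10 V/s upstroke —
pacemaker-like, not neuron-like. `ca_current_extrema(traj)` shows the
L-type Ca current peaking twice per cycle, a driving-force effect that
survives removal of its inactivation term. The fast-spiking interneuron
model fires repetitively above `find_rheobase(fs_model())` ≈ 44 pA with
upstrokes of ~124 V/s under an 80 pA step.

## CLI

```sh
Rscript $(Rscript -e 'cat(system.file("cli","ionflux.R",package="ionflux"))') catalog
# name,stoichiometry,eta,v_o_expression,v_o_mV,alpha_beta_expression   (12 rows)
```

All CLI outputs use fixed numeric formatting, so identical configurations
produce byte-identical files; each `--out` gets a JSON manifest recording
the package version and full configuration.
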