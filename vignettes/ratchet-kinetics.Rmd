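---
title: "Brownian-ratchet kinetics of DNA replication under load: models, simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian-ratchet kinetics of DNA replication under load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnapratchet)
```

## The kinetic problem

A processive DNA polymerase completes one chemical cycle per incorporated
nucleotide: dNTP binding, a rate-limiting activation-plus-chemistry step
(lumped as $k_{cat}$), and pyrophosphate (PPi) release. Somewhere in this
cycle the enzyme also moves forward by one template position. Where that
mechanical step sits determines how an external load $F$ applied along the
DNA reshapes the force–velocity relationship, and that is what this package
models, simulates and fits.

Every force-sensitive rate is given a Bell/Arrhenius dependence
$k_i(F) = k_i(0)\,e^{F d_i / k_B T}$, with $d_i$ the distance to the
transition state along the pulling coordinate. We adopt one sign convention
everywhere: **aiding load is positive, hindering load negative**, matching
how force–velocity data are plotted. A consequence is that the
force-decomposed Michaelis–Menten expressions carry $e^{-F d / k_B T}$: at
hindering (negative) load the exponentials grow, $1/V_{\max}$ rises and
$K_M$ rises, which is the observed phenomenology.

Three coupling schemes are implemented as closed forms
(`velocity_model1/2/3`), each derived from the steady state of its cycle
and verified in the test suite against `unicycle_steady_state()`, a direct
linear solve of the master equation for any unicyclic scheme:

* **Binding power stroke** (`velocity_model1`): translocation rides on dNTP
  binding; $V_{\max} = k_{cat}$ at every load. Signature: force-flat
  $1/V_{\max}$.
* **PPi-release power stroke** (`velocity_model2`): translocation rides on
  PPi release; since $k_{-cat}/k_{ppi} \ll 1$, $K_M/V_{\max}$ is nearly
  force-flat.
* **Brownian ratchet** (`velocity_model3`): a reversible translocation step
  between PPi release and dNTP binding carries all the force dependence,
  giving
  $1/v = a + b e^{-F d_b/k_BT} + (r + s e^{-F d_s/k_BT})/[\mathrm{dNTP}]$
  with the exact algebra $a = 1/k_{cat}$, $b = 1/k_T(0)$,
  $r = (1 + k_{off}/k_{cat})/k_{on}$, $s/r = k_{-T}(0)/k_T(0)$,
  $d_b = d_T$, $d_s = d_T + d_{-T} = \delta$.

The ratchet cycle is kept three-state, with PPi release treated as
instantaneous (its literature rate, $10^3$–$10^4\,s^{-1}$, is one to two
orders faster than $k_{cat}$) and irreversible (raising PPi a
thousand-fold has no measurable effect on velocity in this system). Both
simplifications matter for interpretation: lumping PPi release makes the
identity $M_{bound} = v/k_{cat}$ exact, which is how the occupancy
estimates at the detachment velocity are computed; a sub-dominant
$1/k_{ppi}$ contribution to $a$ would bias $k_{cat} = 1/a$ by at most
about 1%. The four-state cycle with explicit $k_{ppi}$ remains available
through the generic solver.

Derived quantities follow from the same algebra:
$K_\delta(F) = k_T(F)/k_{-T}(F)$, $\Delta G_{trans} = -\ln K_\delta$ (in
$k_BT$), the landscape tilt $-F\delta$ and barrier shift $-F d_T$ under
load (`translocation_landscape`), the per-state occupancies
(`occupancy`), and the predicted detachment load — the hindering load at
which $v$ falls to the empirical 7 nt/s detachment criterion, solved by
bracketed bisection on $[0, 200]$ pN to $10^{-6}$ pN; the velocity is
strictly monotone in load so the root is unique, and a substrate
concentration whose zero-load velocity is already below the criterion
returns `NA` rather than an error (`rupture_force`).

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| $k_BT$ | pN·nm | 4.075 (22 °C) | assay temperature; configurable because PPi titrations are often run at 28 °C |
| $k_{on}$ | /µM/s | 5 | published apparent binding rate for Phi29 DNAP |
| $k_{off}$ | /s | 0 | the data constrain only $r \sim 1/k_{on}$, i.e. $k_{off}/k_{cat} \approx 0$; the exact factor $(1+k_{off}/k_{cat})$ is retained |
| $k_{cat}$ | /s | 120 | rate-limiting step at saturating dNTP |
| $k_T(0), k_{-T}(0)$ | /s | 670, 420 | zero-load translocation rates |
| $d_T, d_{-T}$ | nm | 0.35, 0.05 | barrier position; their sum is the 0.40 nm step, close to the 0.34 nm B-DNA rise |
| $k_{ppi}$ | /s | $10^4$ | upper end of the literature range; lumped in the 3-state cycle |

The defaults are deliberately the published best-fit values for Phi29 DNA
polymerase so that the simulator, the recovery experiments and the worked
examples all share one ground truth.

## What the synthetic data emulate — and what they do not

`synthesize_trace()` reproduces the statistical structure the analysis
assumes: exact Gillespie stepping through the ratchet cycle with
force-dependent propensities; the template geometry (a 229-nt
single-stranded stretch for primer extension, 3487 bp of duplex for strand
displacement); 60 Hz sampling with Gaussian measurement noise (2 nm SD, a
typical dual-trap figure); load-independent off-pathway pauses injected as
a Poisson process (0.05 s⁻¹) with exponential durations (mean 1 s) that
freeze the mechanical coordinate; and two load schedules — constant force,
and a "no feedback" ramp in which load grows as trap stiffness
(0.1 pN/nm) times accumulated length change until the smoothed stepping
velocity (a 30-incorporation window) first drops below the 7 nt/s
detachment criterion, at which point the trace ends with a flagged
detachment. Pause statistics are not quantified in the source experiments
beyond their detectability at 0.4–0.8 s resolution; the defaults were
chosen once to make detection non-trivial but not dominant.

The generator does **not** model bead–DNA hydrodynamics, photon noise,
drift, sequence-dependent kinetics, the exonuclease branch, or a molecular
model of bond rupture (detachment is phenomenological, via the empirical
velocity criterion). Passing tests on these data therefore demonstrate
that the estimators are unbiased and correctly calibrated for the assumed
noise model, not that they are robust to instrument pathologies real
traces may contain.

`synthesize_fv_dataset()` draws per-condition mean velocities around the
ratchet closed form: each record is the mean of $n$ Gaussian replicates
with stated relative SD and carries the replicate SEM, mirroring how
force–velocity tables are assembled from pooled traces (±2.5 pN force
bins, implemented in `pool_rates_by_force`).

## Trace processing

Tether-length changes convert to nucleotides through worm-like-chain
spacings per nucleotide at the measured load: the extensible high-force
interpolation $x/L = 1 - \tfrac12\sqrt{k_BT/FP} + F/S$ for dsDNA
(P = 50 nm, S = 1200 pN, 0.34 nm/bp) and its inextensible form for ssDNA
(P = 0.75 nm, 0.59 nm/nt) — standard literature values, configurable,
since the exact elasticity constants for the assay buffer are not pinned
down. These interpolations were chosen over exact numeric inversion of the
Marko–Siggia relation for speed and simplicity; the exact inversion is
kept as a test oracle, and calls below the interpolation's validity range
(where it would return a non-positive extension) are rejected rather than
silently extrapolated. Which spacing divides the signal follows the
experimental geometry: under opposing load, primer extension consumes
ssDNA and strand displacement shortens duplex; under aiding load the
downstream duplex lengthens in both modes.

Instantaneous velocities are centred sliding-window least-squares slopes
over 50 samples. At 60 Hz, 50 points span 0.83 s; the window is exposed in
points, the sharper of the two equivalent definitions in circulation.
Velocity distributions are histogrammed at 5 nt/s and fitted with a
two-component Gaussian by nonlinear least squares on the counts (the form
the published histograms imply), one component initialized at zero (the
paused state) and one at the robust positive mode (the active state);
weights are component areas. Degenerate inputs are handled explicitly: a
trace with no sub-threshold samples returns a single positive component
with weight 1, pure noise returns a single zero component, and a
non-convergent two-component fit falls back to one component and is
flagged.

Pauses are maximal runs of $|v|$ below a threshold lasting at least 0.4 s.
The published pause-scoring method is described only by reference, so the
detector here is a velocity-threshold run-length scorer with the threshold
at the midpoint of the two mixture means (or half the active mean when no
paused samples exist; an explicit threshold is required if the mixture fit
fails). Average rates are line fits to nucleotides versus time; the
pause-free rate excises pause intervals and stitches the remaining
segments in time before fitting, which is unbiased for plateau-type
pauses. On synthetic ground truth the detector reaches ≥ 0.9 sensitivity
and precision for pauses ≥ 0.8 s at default noise; shorter pauses are
increasingly missed, as expected at this resolution.

## Fitting and model discrimination

`ratchet_fit()` fits all records simultaneously by weighted nonlinear
least squares (Levenberg–Marquardt). Weights are $1/\mathrm{SEM}^2$ by
default — the natural choice when SEMs are reported, though unweighted
fitting is available since the original objective is not stated. All three
schemes are fitted as constrained cases of the six-coefficient family,
which makes the AIC comparison exact: the binding power stroke is
$(a, s, d_s)$ with $b = r = 0$, the PPi power stroke is $(a, b, d_b, r)$
with $s = 0$, the ratchet is all six. Positive coefficients are fitted in
log space; force distances in natural units bounded to $[0, 2]$ nm.
Because $a/b$ and $r/s$ exchange roles when the force dependence is weak,
the optimizer is restarted from multiple (default 10) randomized
initializations and the best solution kept. Whether the original analysis
constrained $d_s \ge d_b$ is unknown; we fit both freely, which lets the
data falsify the implied $d_{-T} \ge 0$ — the inverse mapping to rates
rejects $d_s < d_b$ beyond numerical tolerance.

Uncertainties come from the fit covariance (delta method through the log
parameterization) and from seeded case-resampling bootstrap (default 200
draws), which is the headline interval because the per-record SEMs are
themselves estimates. Goodness of fit is a Gaussian log-likelihood with
the SEMs as known standard deviations, so `AIC()` is comparable across the
three nested-by-constraint models.

`discriminate_models()` adds the two signature tests that carry the
mechanistic argument: weighted-regression slopes of $\log 1/V_{\max}(F)$
and $\log K_M(F)/V_{\max}(F)$ versus load, from per-force Michaelis–Menten
fits, with bootstrap confidence intervals (resampling records within each
force). A natural alternative — regressing $\log(1/V_{\max} - a)$ — is
undefined exactly in the regime the test must detect (no force
dependence, where the subtracted quantity is noise around zero), so the
raw log-slopes are used; they are zero under the corresponding power
stroke and negative under the ratchet, which is the same discrimination.

## Problem sizes and numerical checks

The test suite validates every closed form against the master-equation
solver to $10^{-8}$ relative over random parameter sets, and the solver
itself against matrix-exponential propagation. Stochastic checks use
deliberately moderate sizes chosen for statistical resolution: velocity
recovery over 3 500–5 000 simulated incorporations (3-SE criteria),
velocity-distribution peaks pooled over 8 traces per load, parameter
recovery and model discrimination over 50 synthetic datasets
(7 forces × 6 dNTP levels, 8% relative noise, 8 replicates — the
published design), and bootstrap coverage over 20 datasets with a binomial
bound that a true 90% coverage fails with < 3% probability.

## Known limitations

* The coefficient-to-rate map inherits the lumping assumptions
  ($k_{off} \approx 0$, instantaneous PPi release); $k_{on}$ and $k_{cat}$
  are therefore effective rates, accurate to the extent those assumptions
  hold.
* The WLC interpolations lose accuracy below a few pN, and the ssDNA form
  below ~2 pN; traces at very low force need the exact inversion or
  measured calibration curves.
* The pause detector cannot see pauses shorter than the velocity window,
  and its threshold derivation assumes a bimodal velocity distribution.
* Detachment is an empirical criterion, not a bond model: the simulator
  reproduces where detachment happens, not why.
* No exonuclease branch, sequence dependence, or PPi-concentration
  dependence of the reverse reaction is modelled.
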