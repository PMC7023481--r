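---
title: "Mechanistic biopharmaceutics modelling of oral ibuprofen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic biopharmaceutics modelling of oral ibuprofen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbbm)
```

## The problem

After an oral dose of an ionizable, highly permeable drug such as
ibuprofen (a monoprotic acid, pKa 4.54), systemic exposure is controlled
less by permeation than by what happens upstream: when the stomach
releases the solid particles, how fast they dissolve at the prevailing —
and strongly fluctuating — luminal pH, and how long they reside in the
absorbing segments. `pbbm` implements a complete, testable pipeline for
this problem: a pH-dependent solubility model, a six-state
gastrointestinal dissolution-and-transit model with migrating-motor-complex
(MMC) phase-III gastric emptying, simultaneous fitting of that model to
luminal and plasma concentrations, non-compartmental analysis and
Wagner–Nelson deconvolution, a nine-compartment absorption-and-transit
simulator, spectral detection of phase-III motility from manometry, and
a virtual-cohort generator so every stage can be exercised without any
external data.

## pH-dependent solubility

For a monoprotic acid the total (intrinsic + ionized) solubility follows
Henderson–Hasselbalch:

$$S(\mathrm{pH}) = S_0\,\bigl(1 + 10^{\mathrm{pH} - pK_a}\bigr),$$

optionally truncated at $S_0 \times \mathrm{cap}$, where the *solubility
factor* `cap` is the ratio of the maximum to the intrinsic solubility.
The ibuprofen profile is anchored so that $S(6.2) = 1990$ µg/mL, giving
$S_0 \approx 42.6$ µg/mL. By default no cap is applied: the predicted
maximum-solubility plateau of the reference curve is not available as an
equation, so the uncapped curve is used and `cap` is exposed for users
who have an independent estimate. Measured solubilities in aspirated
human GI fluids are packaged separately
(`ibuprofen_fluid_solubilities()`) for overlay plots only — they
reflect real-fluid media effects (bicarbonate buffering, bile
components, surface-pH depression) that the bulk equilibrium curve
deliberately does not model.

## The six-state gastrointestinal model

The model tracks amounts (µg) of solid drug in the stomach, solid and
dissolved drug in the duodenum and jejunum, and drug in plasma:

$$
\begin{aligned}
\dot M_{s}   &= -K_{empt} M_{s} \\
\dot M_{ds}  &= K_{empt} M_{s} - K_{TD} M_{ds} - R_{duo} \\
\dot M_{dd}  &= R_{duo} - K_a M_{dd} \\
\dot M_{js}  &= K_{TD} M_{ds} - K_{TJ} M_{js} - R_{jej} \\
\dot M_{jd}  &= R_{jej} - K_a M_{jd} \\
\dot M_{p}   &= K_a (M_{dd} + M_{jd}) - K_{el} M_{p}
\end{aligned}
$$

with concentrations $C = M/V$ for the duodenal ($V_1$), jejunal ($V_2$)
and plasma ($V_3$) pools. The assumptions are deliberate and testable:

* no gastric dissolution or absorption (gastric pH is far below the
  pKa, so the stomach only stores and releases solids — no gastric pH
  series is needed);
* luminal compartments are well mixed;
* dissolved drug is absorbed where it stands ($K_a$ fixed at 12 h⁻¹, a
  high value reflecting permeability-unlimited absorption) and never
  transits;
* only solids move aborally; solids leaving the jejunum are tracked as
  unabsorbed distal loss, closing the mass balance;
* no luminal degradation, one-compartment disposition ($K_{el}$, $V_3$
  fixed from non-compartmental analysis of the subject's plasma data).

Two variants differ in emptying and dissolution. The basic variant uses
first-order dissolution $R = K_{d} M_{solid}$ and purely exponential
emptying. The pH-aware variant uses the bilinear saturation-gap law

$$R = K_{Diss}\, M_{solid}\,\max\{0,\; C_s(\mathrm{pH}(t)) - C\},$$

which is the only form that is simultaneously proportional to the
remaining solid, responsive to pH through $C_s$, and dimensionally
consistent with $K_{Diss}$ in mL/(µg·h); the driving force is clamped
at zero so a pH drop cannot re-precipitate absorbed drug. Luminal pH
series are interpolated piecewise-linearly with constant extrapolation,
and the solubility is re-evaluated continuously along the integration.
In the pH-aware variant gastric emptying is first order **until** the
phase-III wave at $T_{MMC}$, when the remaining gastric content is
transferred to the duodenum as a bolus. The integration is split at the
event — the solver never steps across the discontinuity.

Numerics: the right-hand side is compiled C run under `deSolve::lsoda`
at `rtol` 1e-8 / `atol` 1e-10 µg; the pH-to-solubility forcing is
sampled so that no linear segment spans more than 0.02 pH units, keeping
the interpolation error of the convex solubility curve near 0.1% or
better. Mass balance (six states + cumulative eliminated + cumulative
distal loss = dose) closes to 1e-6 relative or better on every
simulation in the test suite, and the adaptive solution agrees with an
independent fixed-step RK4 oracle at dt = 1e-3 h to within 0.1%.

## Fitting the model to three concentration streams

`fit_gis()` estimates $\{K_{empt}, K_{TD}, K_{TJ}, K_{Diss}$ (or
$K_d), V_1, V_2\}$ by minimizing, over the duodenal, jejunal and plasma
streams jointly,

$$\sum_{\text{stream } s}\; \frac{\mathrm{SSR}_s}{\max_i C^{obs}_{s,i}{}^2},$$

i.e. each stream's residual sum of squares scaled by its squared maximum
observed concentration. The scaling equalizes the luminal (~10²–10³
µg/mL) and plasma (~10¹ µg/mL) scales; without it the plasma stream is
numerically invisible. $V_1$ and $V_2$ are estimated rather than fixed
to imaging-based values: the fitted volumes represent the fluid actually
in contact with the dissolving solids, which exceeds resting fluid
volumes in a secreting, flowing intestine.

Optimization is bounded local least squares from a screened multi-start:
a Latin-hypercube pool of candidate parameter vectors (default 128) is
scored with a single objective evaluation each, and the best candidates
(default 16) plus the geometric mid-point of the bounds are polished
with Levenberg–Marquardt on the log scale. Bounds span the observed
fitted ranges of the reference cohort widened tenfold each way;
candidates are drawn from the unwidened interior, because corner
parameter sets produce extremely stiff systems that waste optimizer
budget. Two numerical details matter in practice:

* the finite-difference step of the numerical Jacobian is widened
  (`epsfcn` = 1e-8) above the ODE-solver noise floor — with default
  settings the derivative estimates are dominated by integrator
  round-off and the optimizer stalls silently far from the optimum;
* candidate screening is what makes the search robust: blind random
  starts repeatedly converge to a degenerate basin
  ($K_{TD}\to 0$, $K_{TJ}\to$ upper bound, $V_2 \to$ lower bound) whose
  objective is locally competitive on noisy data.

Tmax on discrete grids is defined as the first time attaining the
maximum. Deviation metrics (`deviation_metrics()`) report
$100\,|pred-obs|/obs$ for Cmax, Tmax and trapezoidal AUC per region.

### What recovery simulations show — and what they cannot

With noise-free data generated at the reference median parameters the
fit drives the objective to ~1e-15 and recovers every parameter to well
under 1%. At 10% proportional noise, replicate virtual subjects expose a
structural identifiability limit of the *design*, not the optimizer: at
the median parameter values only ~0.3% of the dose leaves the jejunum as
solid, so halving or doubling $K_{TJ}$ moves the weighted objective by
~5e-5 against a noise floor three orders of magnitude larger. The
maximum-likelihood estimate of $K_{TJ}$ therefore collapses toward a
bound on most noisy replicates, and the correlated pair
$(K_{TD}, V_2)$ wanders along a shallow valley (errors of ±30–50% with
opposite-signed compensation). We verified that multi-start optima
coincide with refits started at the truth — the scatter belongs to the
likelihood, not the search. $K_{empt}$, $K_{Diss}$ and $V_1$ are
recovered with median errors under ~10–15%. Users fitting real data
should treat reported $K_{TJ}$ (and to a lesser degree the
$K_{TD}/V_2$ pair) as weakly identified; the reference cohort's own
spread for $K_{TJ}$ (0.000–1.14 h⁻¹, CV ≈ 197%) points to the same
conclusion.

## NCA, Wagner–Nelson and the IV disposition model

`nca()` uses the linear trapezoid throughout — appropriate for the
monotone-rise/short-tail profiles at this sampling density — and
estimates $\lambda_z$ by log-linear regression over the last 3–6
positive post-peak points, keeping the set with the best adjusted
R². `wagner_nelson()` computes

$$F_{abs}(t) = \frac{C(t) + k_{el}\,AUC_{0-t}}{k_{el}\,AUC_{0-\infty}},$$

with $k_{el}$ taken from the subject's NCA. This assumes one-compartment
disposition even though ibuprofen is two-compartmental — a documented,
conventional bias of the method; on dense first-order data the result
matches $1 - e^{-k_a t}$ to 1%. `absorption_rate()` differentiates
$dose \cdot F_{abs}$ by central differences (one-sided at the ends).

`fit_mammillary_iv()` fits 1-, 2- and 3-compartment mammillary models in
micro-constant form to constant-rate-infusion data (the reference IV
study infused 800 mg over ~6 min, modelled as a zero-order input over
0.1 h, not a bolus), using the eigendecomposition closed form of the
linear system, and compares models by
$AIC = n\ln(\mathrm{SSR}/n) + 2p$ together with R². On data simulated
from the reference two-compartment constants (K10 1.16, K12 4.55,
K21 3.46 h⁻¹, CL 4.05 L/h) the two-compartment model is recovered to 1%
and wins the AIC comparison against both neighbours.

## The nine-compartment absorption-and-transit simulator

`simulate_acat()` chains stomach, duodenum, two jejunal, three ileal,
caecal and ascending-colon compartments with linear transfer at
$1/\text{transit time}$ for both solid and dissolved species.
Dissolution follows Nernst–Brunner for shrinking monodisperse spheres,

$$\frac{dM}{dt} = \frac{3\,D\,M_{solid}}{\rho\, r(t)\, h_{eff}}
 \bigl(C_s(\mathrm{pH}_n) - C_n\bigr),\qquad h_{eff} = \min(r, 30\ \mu m),$$

with the particle radius computed from the total remaining solid mass
(monodisperse particles shrink uniformly wherever they are). The radius
is floored at 1% of its initial value — below that point less than
one millionth of the dose remains solid, and the un-floored cube-root
law is non-Lipschitz at zero, which stalls any adaptive integrator.
Absorption from solution proceeds at $k_{abs} = 2 P_{eff}/R_n$ with
documented per-compartment radii (the stomach absorbs nothing); absorbed
drug enters the central compartment of the two-compartment disposition
model. No first-pass loss is modelled — ibuprofen undergoes no
significant first-pass extraction — so the amounts reaching the portal
vein and the systemic circulation coincide.

The drug card for ibuprofen uses dose 800 mg, $P_{eff}$ 4.1e-4 cm/s and
particle radius 62 µm. True density (1.2 g/mL) and aqueous diffusivity
(7.5e-6 cm²/s) are not independently reported for this formulation and
default to values typical of a small organic acid; at the default
settings the simulation is not sensitive to either (dissolution is far
from rate-limiting above pH 6).

Volume and pH schedules are step-hold: the most recent entry at or
before $t$ is in force, matching a 15-minute re-specification
granularity, and the integration restarts at every schedule breakpoint.
A volume change re-equilibrates the concentration but moves no mass —
only transit flows transport drug. This is the key simplification
relative to real fluid dynamics, where a collapsing fluid pocket would
carry dissolved drug with it.

Under the default static schedule the simulator absorbs 100% of the
dose (reaching ~95% within 2 h), and the plasma AUC equals
$dose \cdot F_{abs}/CL$ to 2% — both checked in the test suite. The
gastric-transit sensitivity scan (`psa_gastric_transit()`) reproduces
the expected direction: the later the stomach empties, the lower the
plasma Cmax, strictly monotone across 0.25–4 h. Absolute exposure
metrics of the reference commercial simulator are *not* targets: they
depend on undisclosed internals (absorption scale factors, paracellular
terms), which is why this is an ACAT-*like* model and why only the
robust 100%-absorbed bound and directional results are asserted.

## Phase-III detection from manometry

Phase-III contractile bursts (the MMC "house-keeper wave") appear in
duodenal manometry as 11–12 contractions/min averaging ~33 mmHg for at
least 3 min, and antrally as 2–3/min at ~75 mmHg for at least 2 min.
`extract_features()` slides 2-min windows (30 s hop) over each channel
and computes the fraction of smoothed-periodogram power in the 9–12
cycles/min band, the threshold-crossing contraction rate, and amplitude
summaries; the band fraction is the single most discriminating feature,
and it is invariant to amplitude scaling. `train_phase3_classifier()`
fits an L2-penalized logistic regression (fitted along a decreasing
penalty path — single-penalty fits of near-separable data do not
converge reliably). `detect_phase3()` thresholds window probabilities,
attributes windows at their midpoints, merges runs, enforces the
regional minimum durations, and reports $T_{MMC}$ as the start of the
first retained post-dose interval. On seeded synthetic traces the onset
is recovered within one hop in well over 90% of cases. Window length,
hop, band edges, penalty and threshold are all configuration, since the
underlying clinical protocol specifies the method family rather than
the settings.

## The virtual-cohort generator

`generate_subject()`/`generate_cohort()` emulate the study design the
analysis assumes: 800 mg with 250 mL water in the fasted state, GI
sampling at 0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7 h and
plasma sampling to 28 h; $T_{MMC}$ lognormal around a 2.04 h median
(geometric SD 1.4); true model parameters lognormal around the
reference cohort *medians* — medians, not means, because the published
per-subject values have CVs up to ~360% and strongly right-skewed
distributions — with a default 30% between-subject CV; and luminal pH
simulated as a mean-reverting random walk on a 5-min grid (duodenum
mean 6.0, clipped to 4.0–7.0; jejunum mean 6.6, clipped to 4.5–7.5;
reversion 2 h⁻¹, volatility 1.0 pH·h^(-1/2), stationary SD ≈ 0.5 pH
units), emulating the strong fluctuations of low-buffer-capacity
intestinal fluid. Observations are truth × lognormal error (default CV
10%); values below the assay quantification limit (0.32 µg/mL, the
bottom of the reported calibration range) are reported as zero.
Everything is deterministic per (seed, subject index).

What the generator does *not* emulate: real pH fluctuation amplitude
and timescale are only known graphically, so the process parameters are
plausible defaults flagged as such in the cohort manifest; there is no
inter-occasion covariance beyond independent redraws for duplicate
visits; no fed-state arm; and observation noise is homoscedastic on the
log scale. Passing recovery tests therefore demonstrate internal
consistency of generator + estimator under these assumptions, not
performance on clinical data.

`generate_manometry()` builds two-channel traces with the stated
regional contraction signatures embedded at the subject's $T_{MMC}$
over sporadic phase-II activity, and `generate_dynamic_schedules()`
stamps per-compartment volume/pH every 15 min over 0–7 h as clipped
mean-reverting walks around the static defaults.

## Problem sizes used by the shipped tests

The test suite simulates at the clinical sampling grids; property tests
use 200 random parameter draws for positivity/mass balance, 20
replicate subjects for the recovery study, 100 seeded traces for
phase-III detection, and a 6-subject cohort for the model-comparison
direction check. The fixed-step RK4 oracle runs at dt = 1e-3 h. These
sizes give stable medians and proportions while keeping the whole suite
in the minutes range on a single core.

## Known limitations

* $K_{TJ}$ is weakly identified at realistic noise (see the recovery
  section); interval estimates, not point estimates, should be reported
  for it on real data.
* The dissolution law of the six-state model is bilinear in solid mass
  and saturation gap; it does not resolve particle size, so it cannot
  extrapolate across formulations with different particle-size
  distributions (the nine-compartment simulator does track a shrinking
  radius, but assumes monodispersity).
* Bulk pH drives solubility everywhere; surface-pH depression at the
  dissolving particle, bicarbonate buffer kinetics, and bile-salt
  solubilization are out of scope.
* Disposition in the six-state model is one-compartmental by design
  (matching how the fixed $K_{el}$, $V_3$ were obtained); the
  two-compartment model is used only by the nine-compartment simulator.
* The ".cat"-style schedule format is a CSV analogue, not a
  vendor-compatible file format.
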