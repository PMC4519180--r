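---
title: "Models and design choices in fpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in fpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpscreen)
```

`fpscreen` analyses a fluorescence-polarization (FP) competition screen for
allosteric modulators of ABL kinase and the secondary assays that
characterize its hits. This vignette explains the statistical models, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the choices made where the design was genuinely open.

## The screen and its statistics

A bound fluorescein-labeled probe peptide tumbles slowly and polarizes the
emitted light; the FP signal (mP) therefore reports SH3-domain occupancy
of the target protein. Each plate carries 28 positive-control wells
(wild-type protein + probe + DMSO, high FP), 28 negative-control wells
(non-binding SH3 mutant, low FP) and ~300 single-concentration compound
wells. Plates are read three times and the reads averaged per well before
any statistic — replicate reads estimate instrument noise, not biological
variation, so averaging first is the right order.

Three per-compound statistics drive triage:

* **Mean FP** (raw scale, comparable across the screen only to the extent
  plates are comparable).
* **NPI** `= (x − μ_pos)/(μ_neg − μ_pos)·100`, a per-plate affine
  rescaling: 0 % at the positive-control mean, 100 % at the
  negative-control mean. Invariant under any common affine change of a
  plate's mP values.
* **Z-score** `= (x − μ_samples)/σ_samples`, computed per plate over that
  plate's compound wells. The per-plate scope mirrors how NPI is
  plate-normalized and removes plate effects; it is the package default
  (screen-wide scoring would conflate plate shifts with compound effects).

Sample standard deviations use the n−1 denominator throughout, matching
common plate-QC practice.

**Hit rule.** Compounds are ranked screen-wide by increasing mean FP,
decreasing NPI and increasing Z-score; the top `ceiling(0.01·N)` of each
ranking is selected (N = 1200 gives 12; the rounding rule is a package
choice) and a raw hit must appear in ≥ 2 of the three selections. Rank
ties are broken deterministically by compound id so results are invariant
under permutation of input order; the brute-force sort–slice–intersect
oracle in the test suite uses the same tie policy.

**Why three redundant-looking rankings are not redundant.** On an
artifact-free plate the three statistics are monotone transforms of one
another and the ≥2-of-3 rule would collapse to "top 1 %" (~12 hits). The
rule only has bite because real plates disagree: raw FP is sensitive to
whole-plate drift, NPI to errors in the control means (e.g. a placement
bias on the control block), and the Z-score to heavy-tailed compound
populations (auto-fluorescent library members inflate `σ_samples`). The
intersection keeps only compounds that look like hits under all readings
of the plate.

**Confirmation and counter-screen.** Raw hits are retested in
quadruplicate against same-plate DMSO controls; a hit is confirmed only if
a two-tailed Welch t-test rejects at α = 0.05 *and* its mean lies at least
3 control SDs below the control mean. Welch's unequal-variance form is
used because nothing guarantees equal variances between a compound and the
controls. The −3σ band uses the sample SD of the same-plate DMSO control
wells. Confirmed hits are then retested in probe-only wells (no target
protein): a compound that pulls the probe-only FP or the raw fluorescence
intensity more than 3σ below the DMSO probe-only wells is flagged as a
fluorescence quencher, not a binder.

**Plate QC.** `Z′ = 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|`; values ≥ 0.5 indicate a
robust assay. The headline figure is computed from all control wells
pooled across plates ("overall" Z′), so plate-to-plate shifts degrade it
even when individual plates are clean — the per-plate values are reported
alongside for exactly this reason.

## Secondary-assay models

**FP titration and competition.** Assay development uses the minimal
monotone models: a one-site hyperbola `FP = FP_max·d/(h + d)` for the
saturable signal versus target amount (dose kept in µg/well, as measured),
and a three-parameter log-logistic with hill slope 1,
`FP = b + (t − b)/(1 + d/IC50)`, for competition. Zero-dose points anchor
the baseline (saturation) or the top plateau (competition). Nothing deeper
is warranted: these curves guide assay setup, not mechanism.

**DSF.** Melt curves are background-corrected against a no-protein
control (matching temperature grids required; linear interpolation is
opt-in), duplicates are averaged, the curve is truncated at its global
fluorescence maximum to exclude post-peak aggregation decay (standard DSF
practice), and the Boltzmann sigmoid
`F(T) = F_min + (F_max − F_min)/(1 + e^{(Tm−T)/s})` is fit by
Levenberg-Marquardt least squares. Tm is constrained to the fitted window
and a flat curve raises an unidentifiability error rather than returning a
boundary value. ΔTm is sample minus DMSO reference; negative values mean
destabilization.

**SPR.** Sensorgrams follow the closed-form 1:1 Langmuir model:
association `R(t) = R_eq(1 − e^{−(k_aC + k_d)t})` with
`R_eq = R_max·C/(C + K_D)`, dissociation
`R(t) = R(t_s)·e^{−k_d(t − t_s)}`, continuous at the 180 s buffer switch.
One (k_a, k_d, R_max) triple is fit globally across all concentrations —
per-curve fits of a single-concentration sensorgram identify only k_obs
and k_d, so the global fit is the identifiable choice; replicate
injections enter as separate curves. Initialization is deterministic: k_d
from a log-linear regression of the dissociation tail, k_a from the
observed-rate regression `k_obs = k_a·C + k_d`. Optimization runs on log
parameters (positivity for free) and K_D is always the derived ratio
k_d/k_a, never an independent parameter. Mass-transport and drift terms
are deliberately excluded. Analyte concentrations default to
K_D·{⅓, 1, 3, 9}.

**Kinase kinetics.** The ADP-fluorescence assay chain is: build the ADP
standard curve (OLS line, RFU per pmol); subtract the no-enzyme control
(non-enzymatic ADP production — this also cancels the standard-curve
intercept); subtract the autophosphorylation signal (no-substrate control
minus no-enzyme control); convert to pmol with the slope; divide by the
kinase amount (ng). Division by ng before the linear fit commutes with
OLS, so the order is a documentation choice, not a numerical one. The
initial velocity is the OLS slope of the longest prefix window (≥ 5
points) with r² ≥ 0.99 whose slope is within 5 % of the minimal 5-point
window; a flat curve returns velocity 0. Note the 5 % drift allowance
bounds how closely the estimate can track the true initial slope on a
curving progress curve — recovery within ~2× that allowance is what the
estimator guarantees, and what the tests assert.

Velocities feed three fits: Michaelis-Menten `v = V_max·S/(K_m + S)`; the
activator saturation model `V_a = V_act·L/(K_act + L)` on basal-subtracted
velocities (with `V_act/K_act` reported as an overall-enhancement ratio,
and a no-activation flag — never a spurious K_act — when no increment is
positive); and a dose-response EC50 on raw velocities using the
log-logistic with hill fixed to 1 (free-hill optional). With hill = 1 the
EC50 of saturation-model data equals the generating K_act analytically —
the two parameterizations differ only in whether the basal rate is
subtracted.

All nonlinear fits share one Levenberg-Marquardt driver on residual
functions with box constraints; standard errors come from the
Gauss-Newton covariance at the optimum and are reported as `NA` when the
Jacobian is singular there (e.g. a parameter at its bound), rather than
aborting.

## The synthetic-data generators

Every input the pipeline consumes is generated by a pure function of
(configuration, seed). The default configuration encodes the study
conditions: 4 plates × 300 compounds at 10 µM with 28 + 28 controls,
triplicate reads, positive/negative control levels 160/40 mP (arbitrary —
only separation over noise is meaningful), pooled Z′ = 0.57; sensorgrams
with 180 s association and 300 s dissociation at 1 s sampling; melt curves
from 25 to 99 °C in duplicate with a linear background; 3 h progress
curves at 5-min intervals with 40 ng kinase, a 7 pmol ADP/min basal rate,
ATP K_m 9.78 µM, and activators with K_act 0.4 µM (V_act 3.0 pmol/min)
and 1.02 µM (V_act 2.4 pmol/min). The V_act defaults were chosen once to
give ~40 % stimulation at 10 µM with the first activator's maximal
enhancement above the second's.

**Plate artifacts are part of the default screen.** The generator includes
a small whole-plate drift (0/−10/0/0 mP), a placement bias on the
positive-control block (+9/−9/0/0 mP), a compound-dispense offset
(0/−4/+4/+4 mP) and ten auto-fluorescent compounds on each of plates 1–2
(+50–90 mP with matching intensity artifacts). These are the classic
FP-screen failure modes, and they are what makes the three rankings
disagree on null compounds; without them the ≥2-of-3 rule cannot yield a
hit set smaller than the top 1 %. Magnitudes were set by an
order-statistics argument (each plate's extreme tail should dominate at
most one ranking's selection) and validated across hundreds of seeds. The
within-plate control SD is then *solved numerically* so that the analytic
pooled Z′ — between-plate components included — equals the 0.57 target
exactly; with the default artifacts that gives ≈ 4.2 mP per well on a
120 mP separation.

Five spiked inhibitors (85/80/90/85/75 % FP reduction toward the
negative-control level) sit on the artifact-bearing plates; one of them is
a non-reproducible screen artifact (its retest effect is zero) and one is
a fluorescence quencher (probe-only FP and intensity reduced 60 %), so the
default screen exercises every triage stage: 5 raw → 4 confirmed → 3
advanced.

**What the generators do not emulate.** Compound effects are three
classes (active/inactive/quencher) with Gaussian homoscedastic well noise;
there is no dose-response structure in the screen, no spatial (edge)
gradients within a plate, no compound aggregation or solubility artifacts,
no baseline drift within a sensorgram, no two-state binding, no substrate
depletion unless the progress-curve curvature option is switched on, and
DSF fluorescence is in arbitrary units with no dye-concentration
modeling. Passing tests on this synthetic data therefore demonstrate that
the *computations* are correct and that the pipeline reproduces the
statistical structure it encodes — not that the pipeline is robust to
every pathology of real screening data.

## Numerical choices and degenerate inputs

* Classed error conditions separate format, integrity, insufficient-data,
  degenerate-input, grid-mismatch and fit-convergence failures.
* Degenerate inputs fail loudly or flag explicitly: equal control means
  (NPI, Z′), zero sample SD (Z-score), flat melt or dose-response curves,
  all-zero sensorgrams (R_max unidentifiable), non-positive activation
  increments (no-activation flag).
* Ties in hit ranking break by compound id; selection is permutation-
  invariant by construction.
* Tight LM tolerances (ftol = ptol = 1e-14, ≤ 500 iterations) make
  noiseless round-trips recover generating parameters to ≲ 1e-6 relative;
  the fits here are small (≤ 4 parameters, ≤ ~2000 residuals) so the cost
  is negligible.
* CSV round-trips write doubles at 17 significant digits, so a write/read
  cycle is bit-exact.

## Problem sizes

The test suite and the analysis drivers run the full-scale screen (1200
compounds, 4 plates) as in the study; stochastic recovery suites use
50–100 draws per parameter family and 20 draws for the global SPR fits,
sizes at which the medians under test are stable. The acceptance script
regenerates the complete 4-plate control layout (112 + 112 wells) and
reports the pooled empirical Z-factor.

## Known limitations

* The hit rule's behavior depends on plate-artifact structure; on cleaner
  (or dirtier) real data the ≥2-of-3 intersection can be larger or
  smaller, and the package makes no attempt to calibrate artifact
  magnitudes from data.
* No spatial normalization (B-score/median polish) — out of scope by
  design, as is dose-response screening.
* The SPR module fits simple 1:1 kinetics only; systematic misfit (mass
  transport, heterogeneity) must be judged from the reported per-curve
  residuals.
* The velocity estimator's 5 % slope-drift allowance is a bias bound, not
  a variance bound; strongly curved progress curves should be re-run at
  shorter times rather than trusted to the window heuristic.
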