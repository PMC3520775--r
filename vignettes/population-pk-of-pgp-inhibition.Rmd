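---
title: "Population PK modelling of P-gp-mediated tracer transport at the blood-brain barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK modelling of P-gp-mediated tracer transport at the blood-brain barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

P-glycoprotein (P-gp) is an efflux transporter at the luminal membrane of
brain capillary endothelial cells that pumps its substrates back into blood,
and its overactivity is one proposed mechanism of pharmacoresistance in
epilepsy. Dynamic PET with the P-gp substrate (R)-[11C]verapamil, combined
with the inhibitor tariquidar, probes P-gp function in vivo: inhibiting the
transporter raises brain tracer concentrations within minutes. A standing
mechanistic question is whether inhibition acts by *increasing influx*
(gatekeeper picture) or by *decreasing efflux* (vacuum-cleaner picture).

`petnlme` implements a nonlinear mixed-effects (population) analysis of such
paired-scan designs — a baseline scan during which tariquidar is
administered mid-scan, and a post-inhibition scan some hours later — in rats
(naive and 48-h post status epilepticus, 3 or 15 mg/kg tariquidar) and in
healthy humans (2 mg/kg). Because no subject-level data are deposited with
the source studies, the package ships a synthetic-study generator that
emulates both designs; all estimation machinery is exercised against it.

# Structural model

**Plasma.** Metabolite-corrected arterial plasma concentrations follow a
three-compartment mammillary model parameterized by distribution volumes
`Vc`, `Vp1`, `Vp2` (ml) and clearances `CL`, `Q1`, `Q2` (ml/min). The tracer
injection is a zero-order infusion over the recorded injection duration.

**Brain.** Each region is a two-compartment catenary chain driven by the
plasma concentration:

\[
\frac{dA_{br1}}{dt} = m_{in} Q_{in} C_c(t) - m_{out} Q_{out} C_{br1}
  - Q_{br}\,(C_{br1} - C_{br2}), \qquad
\frac{dA_{br2}}{dt} = Q_{br}\,(C_{br1} - C_{br2}),
\]

with \(C_x = A_x / V_x\). The tariquidar effect \(D\) multiplies either the
influx clearance (\(m_{in} = D\), placement `on_Qin`) or the efflux
clearance (\(m_{out} = D\), placement `on_Qout`); comparing the two
non-nested fits by OFV answers the mechanistic question. As printed in the
source literature the brain equations are concentration-form and
dimensionally inconsistent (clearance times concentration equated to a
concentration derivative); the package integrates the amount-form system
above, which preserves the intended steady state
\(C_{brain}/C_{plasma} \to Q_{in}/(D\,Q_{out})\).

The observed regional PET signal is taken as
\((A_{br1}+A_{br2})/(V_{br1}+V_{br2})\). The mapping of model compartments
to the measured signal is not specified by the source analysis; this
convention was chosen because PET measures total regional activity and
because it makes the equilibrium brain-to-plasma ratio equal
\(Q_{in}/Q_{out}\) *exactly*, matching the reported volume of distribution
definition \(V_{T} = Q_{in}/Q_{out}\).

**Covariates.** The inhibitor effect is a product of categorical covariates,
\(D = \mathrm{Eff}_{tariquidar}^{cov} \cdot \mathrm{Eff}_{scan}^{cov}\):
1 before administration, \(\mathrm{Eff}_{tariquidar}\) (per dose group) from
the start of administration to the end of scan 1, and
\(\mathrm{Eff}_{tariquidar}\cdot\mathrm{Eff}_{scan}\) throughout scan 2.
The onset is modelled as a step at the *start* of administration (the rat
bolus lasts 60 s, so the distinction is immaterial there; for the 30-min
human infusion the source does not state the convention and the step-at-
start choice is the package's documented default). Status epilepticus
enters as a multiplier \(\mathrm{Eff}_{SE}\) on `Vbr1` for post-SE animals.

**Statistical model.** Individual parameters are lognormal,
\(\theta_i = \theta_{pop} e^{\eta_i}\), with \(\eta_i \sim N(0, \omega^2)\)
and shared-eta blocks ({`Vc`,`CL`,`Q2`} and {`Vp1`,`Q1`} in the plasma
stage, mirroring the identical reported IIV values). Residual error is
proportional for both observation types. Published IIV entries are
interpreted as the standard deviation \(\omega\) (the source names
"standard deviation omega"), and residual-error entries as proportional-error
SDs; both are configurable.

# Simulation internals

Both submodels are linear time-invariant systems within time segments, so
the package never uses a step-size-controlled ODE solver: it propagates the
exact solution through each segment in the eigenbasis of the rate matrix
(closed-form 2x2 and analytic-cubic 3x3 eigendecompositions, compiled).
Plasma input is piecewise-constant (infusions); the brain forcing is the
plasma curve interpolated linearly on a fine grid (0.1 min up to 5 min,
0.25 min to 20 min, then 1 min), with the inhibitor step as a grid
breakpoint. The test suite verifies agreement with an independent adaptive
Runge-Kutta oracle to a relative error below 1e-6 across random parameter
sets.

# Estimation

The objective function value (OFV) is \(-2\log\) of an approximate marginal
likelihood, computed per subject by optimizing the random effects
(conditional modes, damped Gauss-Newton with analytic gradients in the
prediction space) and applying a Laplace-family curvature correction. The
default curvature is the interaction-aware Gauss-Newton form
\(H = \Omega^{-1} + \tfrac12 J^\top \mathrm{diag}(\partial^2 \ell_j /
\partial f_j^2) J\) with the exact second derivative of the proportional-
error log-likelihood (this is the FOCE-with-interaction family); when that
matrix is not positive definite the code falls back to an exact numerical
Hessian of the joint density (classical Laplace). With no random effects the
OFV reduces to the closed-form proportional-error sum. Accuracy is checked
against 64-node Gauss-Hermite quadrature on one-eta models (within 0.5 OFV
units across random configurations).

The outer problem minimizes the OFV over log-transformed free parameters
(positivity by construction) with a bounded quasi-Newton loop and an
explicit central-difference gradient whose step (1e-5) is kept well above
the inner optimization's noise floor; inner searches are warm-started across
outer iterations. Defaults: inner relative tolerance 1e-9, outer relative
tolerance 1e-7. Relative standard errors come from the inverse observed
Hessian of the OFV surface on the log scale (so SEs are directly relative);
a singular Hessian suppresses RSEs with a warning, mirroring the source
tables' "(-)" entries for the five-subject human fit.

**Sequential fitting.** Following the source strategy, the plasma stage is
fit first and then frozen: the brain stage treats each subject's plasma
curve as a known forcing function. The package uses the *individual*
(empirical-Bayes) plasma curve per subject by default — the source fixes
"plasma parameter estimates" without saying whether population or individual
curves drive the brain model — with `control$forcing = "population"` as the
alternative. Brain mass is not fed back into plasma; tracer amounts in brain
are negligible relative to the body, and the source itself fit plasma
separately. Each scan starts from zero tracer amounts (more than six
carbon-11 half-lives separate the scans and the data are decay-corrected;
decay itself is therefore not modelled).

# Covariate selection

Model building uses the classical OFV-based stepwise procedure: forward
addition accepts, at each step, the candidate with the largest significant
OFV drop (chi-square thresholds 3.84/6.63/10.83 at p = 0.05/0.01/0.001 —
the package returns the exact 0.05 quantile 3.84 although 3.83 is commonly
quoted), then backward deletion removes covariates whose deletion costs less
than the backward threshold. The backward level defaults to the forward
level (the source is silent); ties break lexicographically by candidate
name; the scan effect is never tested alone but always jointly with the
tariquidar terms, since it only modifies them.

# Classic PET reference analyses

For comparison with the population approach the package includes the
standard single-subject analyses: a two-tissue four-rate-constant (2T4K)
compartment fit (\(V_T = K_1/k_2\,(1 + k_3/k_4)\), no blood-volume term by
default as the source mentions none) and Logan graphical analysis, whose
late-time slope estimates \(V_T\) model-independently. Both integrate by
trapezoid on frame midpoints; frames acquired during and after tariquidar
administration are excluded (default window: administration start to the
end of scan 1), because the inhibitor violates the steady-state assumptions
of these estimators. The Logan start time `t_star` defaults to the earliest
time from which the regression attains \(R^2 \ge 0.99\); frame weighting is
uniform. A constant plasma-to-blood ratio of 1.29 converts whole-blood
curves to plasma where needed.

# The synthetic world

`make_rat_study()` reproduces the published design: 21 rats in four groups
(7/4/5/5; naive or post-SE, 3 or 15 mg/kg), group-specific body weights and
injected activities drawn from the published means and SDs (truncated at
zero), a 140-min baseline scan with a 1-min tariquidar bolus at 60 min, and
a 60-min post-inhibition scan 2 h later. `make_human_study()` gives five
volunteers, 120- and 40-min scans, and a 30-min infusion starting at
40 min. The exact PET framing of the original studies is not public; the
generator uses a conventional schedule (12 x 10 s, 6 x 30 s, 5 x 60 s, then
5-min frames) for both brain and plasma records, and treats arterial
sampling at the same midpoints — a simplification of continuous blood
sampling. Ground-truth parameters default to the published population
estimates. Because the source reports no brain-stage IIV, the generator
assigns lognormal SD 0.2 to `Qin` and `Qout` (independent etas) as a
realistic preclinical level — chosen once, not tuned. Noise is proportional
with the published residual SDs, truncated so observations are non-negative.

A green simulation-based test therefore establishes that the estimation
machinery recovers the stated world's parameters under the stated designs;
it cannot establish fidelity to the original scanner data, which include
features the generator deliberately omits (count statistics, partial-volume
effects, reconstruction artifacts, metabolite-correction error).

# Numerical and scaling choices

* Estimation is on the log scale with box bounds |log theta| <= 20.
* The inner Gauss-Newton clamps negative curvature weights to zero for the
  search direction only; the OFV correction uses the exact weights.
* Simulation studies in the test suite are scaled to the suite's time
  budget and documented in place: parameter recovery keeps the full 50-rat
  design (one fit); the placement comparison uses 20 replicates of a
  6-rat full paired-scan design (the mechanisms differ mainly through the
  slow-compartment coupling after the inhibitor step, so the complete
  post-inhibition time course is retained); stepwise selection uses 12
  replicates of a 10-rat baseline-only design. The null-covariate admission rate is asserted with
  a wide Monte-Carlo band (nominal 5%, asserted <= 25% at 12 replicates).
* The derived-quantity reports round half away from zero, volumes of
  distribution to two significant figures and fold changes to one decimal,
  matching the published tables. The published regional table mixes
  conditions (some entries back-compute with the scan effect, some
  without); the report labels conditions explicitly
  (`baseline` / `during_tariquidar` / `post_inhibition`) rather than
  guessing intent, and the summary SD across regions uses the sample
  (n-1) estimator.

# Worked example

```{r, eval = FALSE}
library(petnlme)

study <- make_rat_study(seed = 1)
truth <- default_true_model("rat")
data <- simulate_dataset(study, truth, seed = 1)

plasma_fit <- fit_population(data, default_plasma_model("rat"),
                             control = list(se = FALSE))
brain_fit <- fit_population(data, default_brain_model("rat"),
                            plasma_fit = plasma_fit,
                            control = list(se = FALSE))
tidy(brain_fit)
compare_transport_placement(data, default_brain_model("rat"),
                            plasma_fit = plasma_fit)

# derived report from the published estimates
vt_nlme_table(brain_param_estimates("rat"), dose_group = 3)
qout_change_summary(brain_param_estimates("rat"), 3, "during_tariquidar")
```

# Known limitations

* The approximate likelihood is Laplace-family; no SAEM or importance
  sampling estimator is provided, and omega matrices are diagonal up to
  shared-eta blocks (no general covariances).
* The human study (n = 5) does not support stable IIV estimation; the
  plasma stage for humans is fixed-effects only and RSEs are suppressed
  when the Hessian is singular.
* Indirect-response (ED50) models of the inhibitor effect are out of scope;
  the categorical-covariate description cannot extrapolate between doses.
* The original studies' OFVs and estimates cannot be reproduced exactly
  without their raw PET data; arithmetic consequences of the published
  estimates are reproduced exactly, and everything else is validated on the
  synthetic world.
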