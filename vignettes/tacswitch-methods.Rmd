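---
title: "Model and methods behind tacswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind tacswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical question

Tacrolimus therapeutic targets are defined on trough concentrations (Cmin)
measured during intermittent oral dosing. When a transplant patient is
switched to a continuous intravenous infusion, the measured quantity is a
flat steady-state concentration (Css) with no trough, and treating a
Css reading as if it were a Cmin target systematically under-doses the
patient: at equal total exposure (equal AUC over a dosing interval) the
time-average of an oscillating oral profile necessarily sits above its own
trough. `tacswitch` quantifies the two conversion factors a clinician
needs at the switch:

* the **Css/Cmin ratio** — the factor by which an infusion target should
  exceed the familiar trough target at equal AUC, and
* the **PO/IV dose ratio** — the oral daily dose divided by the
  AUC-matched intravenous daily dose, which for linear kinetics equals the
  reciprocal of oral bioavailability, `1 / (fa * Fg * Fh)`.

Both ratios shift with hepatic and intestinal CYP3A activity, which in a
liver transplant is split between two genomes: the graft (donor) genotype
governs hepatic CYP3A5, the recipient genotype the native intestine.

## Model structure

The simulator is a lumped mechanistic model, deliberately smaller than a
full multi-organ system. The quantities the analysis reports depend on
oral bioavailability, systemic clearance, and the shape of the whole-blood
profile — not on tissue concentrations — so disposition is reduced to a
blood-referenced two-compartment model while the mechanistic detail is
kept exactly where the scenarios act: enzyme-specific, organ-site-resolved
CYP3A metabolism.

For each compound the state is gut-lumen amount, central (blood) amount,
peripheral amount, and cumulative elimination. An oral dose deposits
`fa * dose` in the lumen; the absorption flux `ka * A_lumen` reaches the
circulation scaled by two availabilities evaluated at the current instant:

* **Gut wall** (flow-limited "Qgut" form):
  `Fg = Q_ent / (Q_ent + fu_gut * CLu_int_gut)`, with
  `CLu_int_gut = clint_3A4_gut * abund_3A4 * inh_3A4 +
  clint_3A5_gut * abund_3A5 * inh_3A5`.
* **Liver** (well-stirred):
  `CL_h = Q_h * fu_b * CLu_int_H / (Q_h + fu_b * CLu_int_H)`,
  `Fh = 1 - CL_h / Q_h`, with the hepatic intrinsic clearance summed over
  CYP3A4 and CYP3A5 in the same abundance-times-inhibition form.

Systemic elimination uses the same `CL_h` plus renal clearance (zero for
tacrolimus). Gut extraction is applied algebraically to the absorption
flux rather than through an explicit enterocyte compartment: it reproduces
the Fg mechanism the scenarios manipulate with far fewer undocumented
parameters.

Whole-blood binding is hematocrit-aware. The blood-to-plasma ratio is
rescaled from its reference value assuming a fixed red-cell partition
coefficient, `B:P(h) = (1 - h) + h * K_rbc`, and the unbound blood
fraction follows as `fu_plasma / B:P(h)`; the blood-referenced volume of
distribution is rescaled by `bp_ratio_ref / B:P(h)` so that a change in
hematocrit moves clearance and volume coherently (terminal half-life is
approximately preserved, as expected when binding changes for a
low-extraction drug). For the anemic virtual twin (hematocrit 23.7%) this
raises the unbound blood fraction of tacrolimus by ~80%.

### Drug–drug interaction

Inhibition is purely competitive and reversible: each enzyme's intrinsic
clearance is multiplied by `1 / (1 + I / Ki)`. The perpetrator
(itraconazole 200 mg once daily, oral solution or 1-h IV infusion) is
co-simulated with its own linear PK, and the victim sees two exposures:

* **hepatic site** — the perpetrator's unbound systemic blood
  concentration, for both routes;
* **gut site** — for an oral perpetrator, the standard absorption-flux
  estimate `I_gut = ka_p * fa_p * dose_p / Q_ent` while drug remains in
  the perpetrator's lumen (above 0.1% of the dose), falling back to the
  unbound systemic concentration afterwards; for an IV perpetrator, the
  unbound systemic concentration throughout.

This asymmetry — enterocytes see luminal drug during absorption but only
unbound systemic drug when the perpetrator arrives by vein — is what makes
oral itraconazole collapse the PO/IV dose ratio (gut extraction is
abolished, oral bioavailability rises sharply) while IV itraconazole
mostly just lowers clearance for both routes. No time-dependent
inactivation and no hydroxy-itraconazole metabolite are modelled; the
itraconazole auto-inhibition of its own clearance is likewise omitted
(its PK is linear here), which understates accumulation but is absorbed
by the Ki calibration below.

## Parameters and provenance

The compound files shipped in `inst/extdata/compounds/` are flat key-value
YAML; every value carries a row in `compound_provenance()`. Structural
constants (molecular weight, `fu_plasma` 0.01, B:P 15 at hematocrit 0.45,
renal clearance 0, blood Vss 1.3 L/kg for tacrolimus; binding, B:P 0.58,
clearance 21 L/h for itraconazole solution) come from the literature.
Four groups of values are *calibrated*, i.e. fixed once by inverting the
model against well-established whole-blood pharmacokinetics:

* hepatic `clint` values invert the well-stirred model at blood
  clearances of 2.0 L/h (CYP3A5 non-expressors) and 4.9 L/h (expressors,
  ~2.5-fold, consistent with pharmacogenetic studies);
* gut `clint` values invert the Qgut model at intestinal availabilities
  of ~0.41 (non-expressor) and ~0.26 (expressor);
* `fa = 0.66` fixes the *population geometric-mean* oral bioavailability
  at ~0.235 (capsule bioavailability ~20–25%) — the population mean
  rather than the reference subject, because log-normal abundance
  variability enters Fg and Fh nonlinearly and shifts the geometric mean
  about 5% below the median subject;
* the disposition pair `k12 = 2.0, k21 = 0.12` (with `ka = 0.7/h`)
  reproduces the steady-state peak-to-trough fluctuation of twice-daily
  capsules (Css/Cmin ~1.3 at 2 L/h clearance, ~1.7 at 4.9 L/h) together
  with a terminal half-life near 35 h.

The itraconazole unbound Ki (6 ng/mL, both enzymes) sits inside the very
wide published in-vitro range (~2–270 nM) and is chosen so that simulated
steady-state unbound exposure at 200 mg daily reproduces the reported
2–3-fold tacrolimus AUC increase. All values are overridable through
`load_compound(..., overrides = )` or a compound file.

## The virtual population

`sample_population()` draws organ-site abundances log-normally with median
1 (liver CV 35%, gut CV 60%), a subject-level absorption-rate multiplier
(CV 30%), and demographics from documented ranges (healthy 20–50 y,
geriatric 65–85 y, sex-specific weight/height/hematocrit). Each subject
is a CYP3A5 expressor with probability 0.17 (the Caucasian expressor
frequency) — positive sampled abundance at liver, intestine and colon —
or a non-expressor with all three at zero. Genotype is modelled as a
single binary because the analysis uses only the two extremes. The
dispersions are typical population-PBPK values, declared defaults rather
than inferred ones: the emulated population libraries are named but not
parameterised in the sources. One master seed drives everything;
per-trial child seeds are `(seed + 104729 * trial) mod (2^31 - 1)`, so a
population is reproducible trial-by-trial.

The **virtual twin** fixes age, sex, weight, height, hematocrit and
genotype (the shipped case: 70-year-old female, hematocrit 0.237, CYP3A5
non-expressor at all sites; weight 70 kg and height 163 cm are assumed,
as the case description does not state them) and is simulated as ten
trials of one subject. Because the patient's covariates are fixed, the
twin's residual abundance variability across trials is much narrower than
an open population's: its CVs default to 12%, calibrated to the
trial-to-trial spread reported for virtual-twin simulations (roughly
±15–20% on exposure over ten trials). Reduced graft function is a pure
multiplier on
hepatic CYP3A4+CYP3A5 abundance (`liver_function_fraction`), leaving
liver flow and size untouched.

What the generator does *not* emulate: age-dependent physiology (the
geriatric variant only shifts the age range — the emulated twin's graft
is treated as functionally normal), within-subject variability over time,
non-adherence, assay error, or disease-state physiology beyond hematocrit
and the liver-function multiplier. Population results should therefore be
read as healthy-volunteer predictions, exactly like the analysis they
reproduce.

## Scenarios and the matching pipeline

`apply_scenario()` translates transplant genetics into organ-site edits:
donor-only expression zeroes intestinal/colonic CYP3A5 and keeps the
liver; recipient-only does the opposite; scenarios requiring expression
set the sampling frequency to 100% before zeroing. For every subject,
`run_scenario()` simulates the oral regimen (1 mg q12h, 168 h), computes
the AUC over 156–168 h by the log-trapezoidal rule, finds the continuous
infusion rate with the same AUC, and re-derives the infusion's NCA. The
matching exploits dose linearity — one probe infusion of 1 mg/24 h is
simulated and scaled — and is verified by re-simulation to a residual of
1%, with bracketed root-finding as a fallback that linear kinetics never
actually triggers.

Numerical choices:

* stiff-capable `lsoda` with relative tolerance 1e-8 and absolute
  tolerance 1e-12 mg on amounts; dosing handled as solver-restarting
  events, including zero-magnitude events at infusion on/off edges;
* output grid 0.5 h, refined to 0.1 h over the NCA window (halving the
  refined step changes the AUC by well under 0.05%);
* log-trapezoid segments require strictly declining positive endpoints;
  rising, flat or zero-touching segments use the linear trapezoid; window
  endpoints off the grid are interpolated log-linearly on declining
  segments;
* a negative-state guard aborts the run rather than silently clamping
  anything below -1e-6 mg;
* **Cmin** is the concentration at the end-of-window pre-dose instant
  (168 h; doses fall at 0, 12, ..., 156 h, so 168 h is a trough);
* **Css** is the window-average AUC/12 rather than the terminal value:
  the two coincide at true steady state and the average is robust to
  residual accumulation, which is separately flagged
  (`steady_state_ok` compares the 144–156 h and 156–168 h AUCs at 2%).
  With a ~35 h half-life the flag is genuinely `TRUE` at 156 h for
  typical subjects, but *false* under deep liver-function reduction —
  the matching is still exact there because both routes use the same
  window, and the reference analysis used the same 168-h horizon.

Summaries are geometric means; the headline ratios divide geometric means
(`GM(Css)/GM(Cmin)`, which equals the GM of per-subject ratios, and oral
daily dose over `GM(matched IV dose)`). The 90% interval is the empirical
5th–95th percentile of individual values by default; the trial-level
confidence interval of the GM (the convention of commercial population
simulators, and visibly the narrower bracket style of the reference
table) is available via `interval_method = "trial_ci"`. Rounding to two
decimals happens only in `scenario_report()`.

## Problem sizes

Population scenarios are simulated as 10 trials of 100 subjects (the
twin: 10 trials of 1) in the acceptance script and the shipped
configuration; the test suite exercises the same pipeline at 10 trials of
20 subjects, a scale at which the geometric-mean ratios are stable to a
few percent while the whole suite stays fast. The twin scenarios always
use ten subjects, so their geometric means carry a few percent of
Monte-Carlo error at the twin's 12% abundance CVs.

## Known limitations

* Absolute exposures (AUC, Cmin, Css) from a reduced lumped model track
  the reference full-physiology engine only to within tens of percent;
  the package treats them as sanity quantities and puts its weight on the
  *ratios*, which depend on availabilities and profile shape rather than
  on absolute clearance calibration.
* No P-glycoprotein transport (deliberately, following the model family
  this work builds on), no saturable victim kinetics, no enterohepatic
  recirculation, no dissolution model (capsule and solution are
  represented by `fa`/`ka` alone), and no hydroxy-itraconazole.
* The static absorption-flux estimate of gut inhibitor exposure is a
  convention, not a measurement; it is the recognised source of the
  oral/IV perpetrator asymmetry but its magnitude during the absorption
  window is an upper-bound style estimate.
* Expressor genotype is binary; heterozygous intermediate phenotypes are
  not represented.

## Reading the outputs

```{r example}
library(tacswitch)
scns <- reference_scenarios(seed = 1, n_trials = 10, n_per_trial = 100)
results <- run_scenarios(scns)
scenario_report(results)       # Table-1-style summary, one row per scenario
tidy(results$healthy)          # per-subject values
plot_steady_state(results$healthy)
```
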