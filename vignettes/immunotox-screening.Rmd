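---
title: "Methods: factorial screening analysis for in vitro fish immunotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial screening analysis for in vitro fish immunotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukotox)
```

## The screening problem

In vitro immunotoxicity screening exposes primary fish head-kidney
leukocytes to a chemical concentration series — with and without prior
lipopolysaccharide (LPS) stimulation, for a short (3 h) and a long (19 h)
period — and reads out innate immune function: phagocytosis activity,
respiratory burst, and pro-/anti-inflammatory cytokine transcription
(IL-1β, TNFα, IL-10) by qPCR. Two questions drive the analysis:

1. **Does the chemical alter an immune parameter at sub-cytotoxic
   concentrations?** Answered with a factorial linear model and Wald
   contrasts, yielding a LOEC (lowest observed effect concentration) per
   endpoint and exposure scenario.
2. **Is any observed effect specific, or just the foothills of
   non-specific (baseline, narcosis-type) toxicity?** Answered by comparing
   measured cytotoxicity (EC20) against a partitioning-based prediction of
   baseline toxicity (IC10) via the toxic ratio TR = IC10 / EC20, and by
   comparing effect potency against cytotoxicity via the specificity ratio
   SR = EC20 / LOEC.

This package implements that pipeline end to end, together with a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every stage is testable without laboratory data.

## The factorial linear model

For an immune endpoint \(Y\), observation \(i\) (a technical-replicate
average for one fish × time × LPS × concentration cell) is modelled as

\[
Y_i = \beta_0
 + \sum_{f} \beta_f\, I(\mathrm{fish}_i = f)
 + \beta_t\, I(\mathrm{time}_i = 19h)
 + \beta_\ell\, I(\mathrm{LPS}_i = \mathrm{yes})
 + \sum_{c} \beta_c\, I(\mathrm{conc}_i = c)
 + \beta_{t\ell}\, I(19h)\,I(\mathrm{LPS})
 + \sum_{c} \beta_{tc}\, I(19h)\,I(c)
 + \sum_{c} \beta_{\ell c}\, I(\mathrm{LPS})\,I(c)
 + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2).
\]

Key modelling choices, all visible in `build_design_matrix()`:

* **Reference-level coding.** First fish, 3 h, LPS "no" and concentration 0
  are absorbed into the intercept. The equation written with a full set of
  fish indicators is over-parameterised; treatment coding makes it
  identifiable and matches the default behaviour of standard linear-model
  software, so coefficients can be cross-checked directly against `lm()`.
  For \(|F|\) fish and \(|C|\) non-control concentrations the design has
  \(1 + (|F|-1) + 2 + |C| + 1 + 2|C|\) columns — 19 for seven fish and
  three concentrations.
* **Fixed fish effects.** Between-fish variation in base immune activity is
  a fixed offset per fish, not a random effect. With five to seven fish
  there is little information to estimate a variance component, and the
  contrasts of interest are within-fish.
* **Concentrations as unordered factors.** No monotone dose-trend is
  imposed; each tested level gets its own effect, and interactions with
  time and LPS are estimated per level.
* **Joint 3 h / 19 h fit.** Both time points enter one model (the time main
  effect and its interactions carry the difference). Fitting per time point
  is possible by subsetting the input; the joint model is the default
  because it pools the residual variance estimate.
* **No multiple-testing correction.** Significance is the raw two-sided
  p ≤ 0.05 per contrast. This is deliberate and exposed — a screening
  assay favours sensitivity, and the classification step (TR/SR) provides
  the specificity filter — but users should treat isolated hits
  accordingly.
* **qPCR endpoints are analysed on the ΔCt scale**, where the Gaussian
  error model is plausible; fold changes (2^−ΔΔCt) are reporting output
  only.

Fitting is ordinary least squares via a pivoted QR decomposition
(`fit_immune_lm()`). Rank-deficient designs (e.g. a concentration present
only at one time point) are handled by aliasing: redundant columns get `NA`
coefficients and are reported, the projection is unaffected, and contrasts
touching an aliased coefficient are refused as non-estimable rather than
silently extrapolated.

Inference is by Wald tests on linear combinations of coefficients
(`wald_contrast()`): estimate \(c^\top\hat\beta\), standard error
\(\sqrt{c^\top \hat V c}\), two-sided Student-t p value on the residual
degrees of freedom. `standard_comparisons()` emits the three families used
to read a screen — LPS control vs non-stimulated control, and each
concentration vs control without and with LPS — including the interaction
terms needed at 19 h, so each row estimates a difference of cell means.
`determine_loec()` then takes the smallest tested concentration with
p ≤ 0.05; when none is significant the endpoint is "not determinable" for
that scenario, which propagates (see below).

## Plate quality control

* **Blank normalisation** subtracts the mean dye-free blank per endpoint ×
  time grouping (plates are endpoint- and duration-specific).
* **Technical replicates** (three wells per treatment) are averaged before
  fitting; the replicate SD is retained.
* **The LPS validity rule**: a fish's data enter the analysis only if LPS
  stimulation raised its control wells above the non-stimulated controls by
  more than \(k\) × the technical error, defined here as the pooled SD of
  the fish's control technical replicates. The multiplier defaults to
  \(k = 1\) and is exposed as a parameter — the exact formula is an
  implementation choice, so it is configurable rather than hard-coded.
  Exclusion is per fish × endpoint, since validity can differ between
  assays run on separate plates.

## Cytotoxicity and EC20

Viability is calcein-AM signal (live-cell esterase activity) normalised to
DAPI nuclei counts, blank-corrected, and expressed relative to the control
ratio (control ≡ 1). EC20 is the concentration at which viability crosses
below 80% of control. Because range-finding data are per-level
measurements, not fitted curves, `estimate_ec20()` uses the minimal
assumption: linear interpolation in log10 concentration between the two
bracketing tested levels. Numerical conventions:

* a level measured exactly at 0.8 is itself the EC20;
* if even the lowest non-zero level is below 0.8, that level is reported as
  an upper bound (`lt_min`);
* if no level falls below 0.8, the EC20 is censored above the maximum
  tested concentration (`gt_max`) — censoring is carried, never replaced by
  a number;
* with a non-monotone series the first crossing from low concentration is
  used and the result flagged.

On a noise-free Hill curve (EC50 = 10, slope 1) sampled at {0, 1, 3, 10,
30}, interpolation recovers the true 80% crossing (2.5) within 6%; the
error shrinks towards zero as the grid densifies. Concentrations strictly
below the EC20 form the non-cytotoxic range that gates the immune assays
(`noncytotoxic_range()`).

## Baseline toxicity by equilibrium partitioning

Non-specific (narcosis-type) cytotoxicity occurs at a roughly constant
critical membrane concentration of 69 mmol per litre of membrane lipid,
independent of the chemical. `predict_ic10()` converts this into a nominal
medium concentration for a given assay system by an equilibrium mass
balance over water, medium protein and lipid (serum-derived), cell protein
and membrane lipid, and headspace. With partition capacities
\(V_w,\; D_{protw}V_{prot},\; D_{lipw}V_{lip},\; K_{aw}V_{air}\),

\[
IC10 = \frac{C_{mem}^{crit}}{D_{lipw}} \cdot
       \frac{\sum \text{capacities}}{V_{dose}} ,
\]

the nominal concentration at which the lipid phase reaches the critical
level. Conventions and limits:

* **Nominal means liquid dose volume.** \(V_{dose}\) is water plus protein
  and lipid volumes; the headspace contributes capacity (a loss term) but
  is not part of the dose volume. `air_loss_fraction()` reports the
  headspace share and raises a volatile flag above 10% — a chemical losing
  a large fraction to air (e.g. ~90% for a volatile chlorobenzene) is
  excluded from baseline comparison rather than "corrected".
* Distribution ratios \(D_{lipw}\), \(D_{protw}\) at pH 7.4 are inputs, not
  computed from structure; no ionisation correction is applied internally.
* Sorption to well-plate plastic is omitted (negligible in the presence of
  sufficient protein and lipid).
* `default_compartment_system()` is an illustrative stub for a 96-well
  setup (200 µL medium, 0.5% serum, 2×10⁵ cells, 150 µL headspace).
  Reproducing any published IC10 requires the system-specific measured
  protein and lipid contents; predictions from the stub are for
  demonstration and property checks only.

## Classification: TR and SR

* **Toxic ratio** TR = IC10 / EC20 (averaged over the four exposure
  scenarios). TR ≤ 10 means measured cytotoxicity is explained by baseline
  toxicity; TR > 10 indicates a specific cytotoxic mode of action. The
  threshold is applied mechanically as printed; ratios within ±1 of 10 are
  flagged borderline so the user sees near-threshold calls (e.g. a TR of
  10.9) instead of a silent binary.
* **Specificity ratio** SR = EC20 / LOEC per endpoint. SR < 10 means the
  immune effect is not meaningfully more potent than cytotoxicity. SR is
  computed per scenario and then averaged — not as a ratio of averaged
  columns, which is generally a different number; `build_summary()` emits
  both, with the per-scenario mean primary.
* **Censoring propagates.** A censored EC20 or a non-determinable LOEC
  never yields a finite TR or SR; where a censoring limit exists the ratio
  is reported as a bound, flagged as such.
* Table output is rounded to one decimal, half away from zero; full
  precision is retained in the machine-readable columns.

## What the synthetic generator does and does not emulate

`simulate_assay()` draws data exactly from the model above: the linear
predictor per cell, one biological residual per treatment cell
(`residual_sd`, the model's \(\varepsilon\)), and independent per-well
technical noise (`technical_sd`). Splitting the noise into two components
makes replicate averaging consequential: averaging suppresses only the
technical part. `simulate_viability()` uses a decreasing Hill curve — the
standard in vitro concentration–response form — as the generative truth.
`simulate_qpcr()` works at the Ct level: a reference-gene Ct per sample,
target genes at a true ΔCt above it, a treatment shift in cycles (the true
ΔΔCt), duplicate-level measurement noise, and a validity check that all
cycles lie in (0, 45].

Consequently, passing tests demonstrate that the estimators recover the
truth *under the assumed model*: Gaussian errors, homoscedastic across
cells, no plate or edge effects, no flow-cytometry event-level structure,
fixed amplification efficiency of 2. Real plate data can violate any of
these (heavy-tailed wells, plate gradients, efficiency drift), and the
tests say nothing about robustness to such violations. Effect magnitudes
and residual variances of real fish leukocyte data are not published, so
the generator defaults are illustrative values of realistic order (effects
of 0.2–0.8 on a unit-intercept scale, residual SD 0.2–1), chosen once and
not tuned.

## Simulation study sizes

The statistical guarantees are checked at fixed sizes chosen to make
Monte-Carlo error small relative to the tolerance being asserted: 200
random designs for equivalence with the reference `lm()` implementation
(tolerance 1e-6 relative); 10,000 null replicates for the type-I error of
the Wald contrast (99% binomial interval around 0.05); 2,000 replicates
for 95% interval coverage (99.9% binomial band per coefficient, since ~19
coefficients are checked simultaneously); 5,000 samples for ΔΔCt recovery
(within 3 standard errors). All loops are seeded; the acceptance script
derives every stream from its `--seed` argument.

## Known limitations

* No mixed-effects extension; fish are fixed offsets.
* No dose–response curve fitting for immune endpoints (discrete levels
  only, matching the factorial design).
* EC20 interpolation assumes a locally monotone decline between bracketing
  levels; steep curves coarsely sampled inherit interpolation error (the
  5-point Hill example above is accurate to ~6%).
* The partitioning model is equilibrium-only: no kinetics of uptake,
  evaporation or plastic binding, and no QSAR estimation of the input
  distribution ratios.
* The LPS technical-error multiplier \(k\) and the blank grouping are
  conventions exposed as parameters, not universally standardised rules.
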