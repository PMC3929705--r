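---
title: "Models and methods behind dystroflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dystroflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dystroflux)
```

## The problem

Dystrophin-deficient (mdx) skeletal muscle cycles through myofiber
necrosis, regeneration and growth, all of which are metabolically
expensive. Quantifying that cost requires combining several classical
measurement pipelines on the same animals: indirect calorimetry for
energy expenditure (EE), primed-continuous stable-isotope infusions for
whole-body protein turnover, flooding-dose radiotracer incorporation for
muscle fractional synthesis rates (FSR), and covariate-adjusted group
comparisons to separate disease effects from differences in body size.
`dystroflux` implements each of those computations as a reusable,
testable module, and pairs every estimator with a forward simulator so
that the whole pipeline can be validated by parameter recovery. No
animal-level raw data are distributed; the bundled group summaries
(`mdx_reference_values()`) parameterize the generator and the worked
calculations.

## Indirect calorimetry

Energy expenditure is computed per reading with the abbreviated Weir
equation, `EE (kcal) = 3.941 VO2 + 1.106 VCO2` with gas volumes in
litres. The urinary-nitrogen term is omitted, as is customary for rodent
metabolic-cage work; gas volumes are assumed already normalized to
standard conditions by the instrument. The coefficients are fixed at the
classic 1949 values; the equation is linear and homogeneous, so it
applies unchanged to epochs, phases, and days.

`summarize_trace()` integrates per-epoch EE over an analysis window that
must span an integer number of 24-h days (by default the trailing whole
days of the session, matching the practice of discarding an initial
acclimation period). The dark phase is 18:00–06:00 by default and
configurable. Respiratory quotients are ratios of summed volumes, not
means of ratios. Intake is `(Δfeeder − Δspillage) ×` diet energy density
(default 3.64 kcal/g), and balance is `intake − EE` computed per animal
before any statistical adjustment. A guard band warns when RQ leaves
[0.6, 1.3].

Resting EE (`resting_ee()`) is the mean of the two lowest-EE
non-overlapping 90-s readings in the window, extrapolated to 24 h
(×960). Ties break to the earliest timestamp. We impose no inactivity
precondition — the minima of real traces overwhelmingly occur in quiet
periods anyway — but an optional `quiet_epochs` filter is available for
users who want one. Feeder refills must be explicitly flagged;
unflagged positive jumps are treated as data errors and rejected with
the offending timestamp, never silently corrected, because spillage
artefacts are a known source of intake overestimation in these systems.

## Whole-body phenylalanine–tyrosine kinetics

At isotopic steady state the tracee rate of appearance follows from the
dilution of the infused tracer: `Ra = i (100/E − 1)` with the plateau
enrichment `E` in mole percent excess. Published renderings of the
dilution equation differ in whether they report tracee or total flux
(`i·100/E`); both conventions are implemented behind a flag, and the
simulator always shares the estimator's convention, so recovery results
are convention-invariant. The default infusion design is 16 (phe) and
11 (tyr) µmol·kg⁻¹·h⁻¹ continuous with equal priming doses.

The hydroxylation flux of phenylalanine to tyrosine is estimated
Thompson-style from the transfer of ring label into the tyrosine pool,

`Q_pt = Ra_tyr (E_d4tyr / E_d5phe) × (i_phe + Ra_phe)/i_phe`,

with the phenylalanine-infusion correction factor applied by default and
removable by configuration. `Q_pt = 0` exactly when no label appears in
tyrosine, and an estimate exceeding the phenylalanine flux is flagged as
an inconsistent-enrichment error rather than propagated. In the
postabsorptive state `Ra_phe` measures protein breakdown,
`PS_phe = Ra_phe − Q_pt` measures synthesis, and `−Q_pt` is the net
(irreversible) phenylalanine balance. Molar fluxes convert to protein
equivalents with a phenylalanine molar mass of 165.19 g/mol and an
assumed 4% phenylalanine content of mixed body protein. Enrichments
below an instrument floor (0.05 mpe by default) are treated as missing
observations, not zeros.

## Flooding-dose muscle protein synthesis

With a flooded precursor pool, the fraction of a protein pool renewed
per day is `FSR = S_B/(S_A·t) × 1440 × 100` (%/d) where `S_B` and `S_A`
are the protein-bound and precursor-free specific radioactivities and
`t` the labelling time in minutes (default 15). Blood and tissue free
pools are compared (`check_precursor_equilibration()`, default 15%
tolerance) to verify equilibration; failing samples are flagged but
retained, and the precursor used for the calculation is configurable
with the tissue pool as default. Translational capacity is RNA/TP (mg
RNA per g protein) and translational efficiency
`K_RNA = 10 × FSR / (RNA/TP)` (g protein per g RNA per day), which
makes `K_RNA × RNA/TP = 10 × FSR` an exact identity of every output
row. Absolute synthesis is `FSR/100 ×` TP mass; an absolute
myofibrillar rate is deliberately not provided because myofibrillar
purification is not quantitative.

## Degradation inference and necrosis arithmetic

Protein degradation is inferred by mass balance,
`degradation = synthesis − accretion`. In growing muscle, accretion is
taken as linear between the 4-wk and 8-wk total-protein masses (window
endpoints configurable); in adult muscle at protein-mass steady state,
accretion is zero, so degradation expressed as a percent of mass equals
the FSR exactly. Negative inferred degradation is reported with a
warning — it signals inconsistent inputs — rather than clipped.

The cumulative necrosis burden of a constant daily necrosis rate is
available in two forms: linear accumulation `min(1, p·d)` (default,
treating each fiber as affected once per episode) and compound
`1 − (1−p)^d`. At 3%/d over one week these give 21% and 19.2%; both are
exposed because the two readings of "fraction affected" are equally
defensible, and the compound form never exceeds the linear one.

## Energy partition model

Taking skeletal muscle as 30% of whole-body oxygen consumption and
protein synthesis as 17% of resting muscle oxygen consumption, muscle
protein synthesis accounts for `100 × 0.30 × 0.17 ≈ 5%` of whole-body
resting EE in a normal adult. A `k`-fold change in synthesis moves its
share of muscle oxygen consumption to `100 f_ps k/((1−f_ps) + f_ps k)`
(holding non-synthesis oxygen constant), and the default whole-body
increment is `100 f_muscle f_ps (k·m − 1)`, where `m` is the
case/control ratio of whole-body muscle protein mass proxied by
gastrocnemius TP masses. The increment's derivation from these inputs is
genuinely ambiguous — more than one formula is compatible with the
stated ingredients — so the formula is configurable
(`formula = "linear"` or `"renormalized"`) and we treat the increment as
a model output rather than a benchmarked quantity.

## Group comparisons

The statistics module mirrors a general-linear-model workflow: two-way
(genotype × age) ANOVA with Type-II sums of squares (via `car::Anova`;
statistical packages differ in their default sums of squares, and Type
II is the appropriate choice for the near-balanced designs here), ANCOVA
with body-size covariates, least-squares means at the grand covariate
mean (via `emmeans`), and Tukey studentized-range post hoc tests.
Covariate × factor interactions are screened by model comparison; a
p-value below 0.05 sets the `stratified` flag and triggers separate
per-age-group fits, mirroring the separate-analysis-by-age design used
when slopes are heterogeneous. A 0.10 threshold is used only for
annotating factor interactions in reports. Factors with a single
observed level are dropped with a note so degenerate (e.g.
juvenile-only) designs degrade gracefully. Missing values are handled
by listwise deletion with a logged count; collinear covariates are
rejected outright.

## The synthetic-data generator

The generator is first-class code, not a test fixture: it defines the
study conditions under which every estimator is validated.

* **Cohorts.** Animals are drawn from group means and SDs; the bundled
  defaults convert the tabulated group SEs to SDs as `SE × √n` with the
  tabulated n. Size variables (masses, lengths) load on a latent
  per-animal body-size factor (loading 0.96) so fat-free mass and
  skeletal lengths are strongly correlated within groups, as in real
  cohorts. Draws are floored at 1% of the group mean — masses are
  positive quantities — which biases means negligibly relative to their
  SEs at the bundled parameterization.
* **Gas-exchange traces.** VO2 is a sinusoid peaking mid-dark-phase
  (fractional amplitude 0.2 by default) times Poisson activity bursts
  (8/h dark, 2/h light) that add proportional VO2 increments and beam
  breaks; VCO2 is VO2 times a phase RQ (0.97 dark, 0.87 light). Gas
  volumes are renormalized per complete day on the pre-noise signal so
  that the Weir-integrated daily EE of a noiseless trace equals the
  target exactly, and multiplicative noise is applied afterwards. Meal
  events are concentrated in the dark phase with per-day eaten mass
  exact, and spillage is recorded as a separate mass so the intake
  correction is exercised.
* **Tracer and flooding samples.** Both simulators are exact algebraic
  inverses of their estimators, so noiseless round trips recover the
  truth to machine precision by construction, and the correctness
  content of the tests lies in the hand-derived worked values and
  independent oracles, not the inversion itself.
* **Noise model.** All measurement noise is multiplicative log-normal
  with unit mean; physiological measurements are positive with roughly
  constant coefficient of variation. Within-animal instrument CVs are
  not reported for this class of study, so the 5% defaults are
  conventions, stated in the configuration rather than buried.
* **Random streams.** One global seed fans out to per-animal substreams
  keyed by animal index, so enlarging a cohort never perturbs the
  animals already drawn, and every pipeline output is byte-identical
  under a fixed seed.
* **Group tracer truths.** Whole-body rates of appearance are not
  available per group in summary form, so the pipeline defaults use
  plausible values (higher in mdx and in juveniles, 450/330/320/200
  µmol·kg⁻¹·h⁻¹ for phenylalanine) with a 17% hydroxylation fraction
  throughout; these are generator choices, and parameter-recovery tests
  are valid for any positive setting.

What the generator does **not** emulate: chamber washout dynamics,
instrument drift, diurnal feeding–EE coupling beyond the shared phase
structure, between-muscle within-animal correlations, and the
non-normal tails of real biological variation. Passing recovery tests
therefore demonstrates the correctness of the estimators under the
stated noise model, not robustness to instrument pathology.

## Numerical and testing choices

Worked-value tests pin every formula to hand-computed numbers (e.g.
Weir at (1, 0.7) L → 4.7152 kcal; FSR at S_B = 3.24×10⁻³, S_A = 1,
t = 15 min → 31.1 %/d; dilution at i = 16, E = 4 mpe → 384
µmol·kg⁻¹·h⁻¹). The statistical machinery is cross-checked against
independent brute-force oracles: Type-II sums of squares recomputed
from explicit least-squares model comparisons, and Tukey p-values from
the studentized-range distribution directly. Problem sizes were chosen
to keep the default suite fast while leaving Monte-Carlo margins wide:
1000 replicates for bias checks (observed bias ≪ 1% at 5% noise), 4800
replicates for the standard-error scaling check, 2000 simulated null
cohorts of 32 animals for the type-I-error check (expected rejection
0.05 ± 0.01), and 24–72 h traces at 90-s epochs for calorimetry round
trips.

One internal-consistency check deserves mention: recomputing
translational efficiency from the bundled group means reproduces the
tabulated K_RNA within 5% for eleven of the twelve muscle × group cells;
the adult mdx diaphragm cell deviates by ~7%, as expected when a
mean-of-per-animal-ratios is compared with a ratio-of-means in the
smallest (n = 4), most variable subgroup. The package computes
per-animal ratios as primary and reports group ratios alongside, so the
discrepancy is visible rather than hidden.

## Limitations

The pipeline is steady-state throughout: no Steele-type non-steady
kinetics, no compartmental modelling of the priming phase, no fed-state
balance, and no correction for precursor decay during the 15-min label
(the flooding dose is assumed to hold S_A constant, as the method
intends). Degradation is inferred, not measured. The energy-partition
model is deliberately coarse — two literature fractions and a
fold-change — and its whole-body increment should be read as an order
of magnitude, not an estimate with an uncertainty.
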