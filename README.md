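# dystroflux

Energy expenditure and protein turnover analysis for dystrophic-mouse
phenotyping.

Duchenne muscular dystrophy and its mdx mouse model subject skeletal
muscle to repeated cycles of myofiber necrosis, regeneration and
growth — processes with a substantial metabolic cost. Quantifying that
cost for a whole animal requires stitching together several classical
measurement pipelines: indirect calorimetry in metabolic cages,
steady-state phenylalanine/tyrosine tracer kinetics, flooding-dose
muscle protein synthesis measurements, and body-size-adjusted group
statistics. `dystroflux` implements the full quantitative pipeline as a
tested R package for physiologists working with whole-animal metabolic
and stable-isotope data, with a synthetic-data generator standing in
for the animal measurements so that every stage is verifiable by
parameter recovery.

## What it computes

* **Energy budgets** (`summarize_trace`, `resting_ee`,
  `summarize_activity`): per-epoch energy expenditure by the
  abbreviated Weir equation, EE (kcal) = 3.941·VO₂ + 1.106·VCO₂ (L);
  24-h, dark- and light-phase EE; resting EE from the two lowest 90-s
  readings extrapolated over 24 h; respiratory quotients;
  spillage-corrected intake; and energy balance = intake − EE.
* **Whole-body protein kinetics** (`estimate_fluxes`): rates of
  appearance by isotope dilution, Ra = i(100/E − 1) at plateau
  enrichment E (mpe); Thompson-style phenylalanine→tyrosine
  hydroxylation flux Q_pt; postabsorptive partition
  PS_phe = Ra_phe − Q_pt with net balance −Q_pt; conversion to
  g protein·kg⁻¹·h⁻¹ via 4% phenylalanine content.
* **Muscle protein synthesis** (`summarize_flooding`): flooding-dose
  FSR = S_B/(S_A·t)·1440·100 (%/d), the myofibrillar/total ratio,
  absolute synthesis FSR·TP mass, translational capacity (RNA/TP) and
  efficiency (K_RNA = 10·FSR/(RNA/TP)).
* **Degradation inference** (`infer_degradation`, `necrosis_burden`):
  degradation = synthesis − accretion under linear-growth or
  steady-state assumptions, and cumulative necrosis-burden arithmetic.
* **Energy partition** (`baseline_contribution`,
  `muscle_ps_share_after_foldchange`, `wholebody_ee_increment`): the
  contribution of muscle protein synthesis to whole-body resting EE and
  the effect of fold-changes in synthesis.
* **Cohort statistics** (`two_way_anova`, `ancova_lsmeans`,
  `tukey_posthoc`): genotype × age ANOVA with Type-II sums of squares,
  ANCOVA least-squares means at the grand covariate mean,
  interaction-triggered stratification, and Tukey post hoc tests.
* **Simulation and orchestration** (`simulate_cohort`,
  `simulate_clams_trace`, `simulate_tracer_plateau`,
  `simulate_flooding_dose`, `run_all`): ground-truth-parameterized
  generators for every input, and an end-to-end pipeline with
  schema-validated CSV I/O (`validate_table`) and a recovery report.

## Worked example

Infer gastrocnemius protein degradation in juvenile dystrophic mice
from a synthesis rate of 31.1 %/d on an 11.1 mg total-protein pool
growing linearly to 29.2 mg over four weeks:

```r
library(dystroflux)
infer_degradation(31.1, 11.1,
  accretion_assumption("linear_growth", tp_start = 11.1, tp_end = 29.2))
#>   synthesis accretion degradation frac_synth_degraded deg_pct_of_mass
#> 1    3.4521 0.6464286    2.805671           0.8127434        25.27632
```

About 81% of the protein synthesized each day is degraded, amounting to
about 25% of the muscle's protein mass daily. The same call with
`accretion_assumption("steady_state")` makes degradation equal
synthesis, so in non-growing adult muscle the daily degradation as a
percent of mass equals the FSR.

A noiseless tracer round trip recovers its ground truth exactly:

```r
enr <- simulate_tracer_plateau(tracer_truth(300, 80, 0.17))
est <- estimate_fluxes(enr)
c(est$ra_phe, est$hydroxylation_fraction)
#> [1] 300.00   0.17
```

and the energy-partition model with its default fractions:

```r
partition_report(partition_params(k_fsr = 2.5))
#>                           quantity    value                               units
#> 1            baseline_contribution  5.10000          % of whole-body resting EE
#> 2 muscle_ps_share_after_foldchange 33.86454          % of muscle O2 consumption
#> 3           wholebody_ee_increment  7.65000 % increase in whole-body resting EE
```

i.e. muscle protein synthesis is ~5% of whole-body resting EE at
baseline, and a 2.5-fold rise in synthesis lifts its share of muscle
oxygen consumption to ~34%.

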