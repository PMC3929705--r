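#' Energy-partition parameters
#'
#' Constants of the model for the contribution of skeletal-muscle protein
#' synthesis to whole-body resting energy expenditure: skeletal muscle
#' accounts for a fraction `f_muscle` of whole-body oxygen consumption
#' (default 0.30) and protein synthesis for a fraction `f_ps` of resting
#' muscle oxygen consumption (default 0.17). `k_fsr` is a fold-change in
#' muscle protein synthesis rate and `m_ratio` the case/control ratio of
#' whole-body muscle protein mass (proxied by gastrocnemius total-protein
#' masses).
#'
#' @param f_muscle,f_ps fractions in (0, 1).
#' @param k_fsr,m_ratio positive scalars (defaults 1).
#' @return object of class `partition_params`.
#' @export
partition_params <- function(f_muscle = 0.30, f_ps = 0.17,
                             k_fsr = 1, m_ratio = 1) {
  df_assert(f_muscle > 0 && f_muscle < 1 && f_ps > 0 && f_ps < 1,
            "bad_params", "fractions must lie in (0, 1)")
  df_assert(k_fsr > 0 && m_ratio > 0, "bad_params",
            "k_fsr and m_ratio must be > 0")
  structure(list(f_muscle = f_muscle, f_ps = f_ps, k_fsr = k_fsr,
                 m_ratio = m_ratio), class = "partition_params")
}

#' Baseline contribution of muscle protein synthesis to resting EE
#'
#' In a normal adult animal, muscle protein synthesis accounts for
#' `100 x f_muscle x f_ps` percent of whole-body resting energy
#' expenditure (about 5% at the default 0.30 x 0.17).
#'
#' @param p a [partition_params()].
#' @return percent of whole-body resting EE.
#' @examples
#' baseline_contribution(partition_params())  # 5.1
#' @export
baseline_contribution <- function(p = partition_params()) {
  100 * p$f_muscle * p$f_ps
}

#' Protein-synthesis share of muscle oxygen consumption after a
#' fold-change
#'
#' With non-synthesis oxygen consumption held constant, a `k`-fold change
#' in muscle protein synthesis moves its share of muscle oxygen
#' consumption to `100 x f_ps k / ((1 - f_ps) + f_ps k)` percent (about
#' 33% at f_ps = 0.17, k = 2.5).
#'
#' @param f_ps baseline protein-synthesis fraction of muscle oxygen
#'   consumption, in (0, 1).
#' @param k_fsr fold-change in muscle protein synthesis (> 0).
#' @return percent of muscle oxygen consumption.
#' @examples
#' muscle_ps_share_after_foldchange(0.17, 2.5)  # 33.9
#' @export
muscle_ps_share_after_foldchange <- function(f_ps, k_fsr) {
  df_assert(f_ps > 0 && f_ps < 1, "bad_params", "f_ps must be in (0, 1)")
  df_assert(k_fsr > 0, "bad_params", "k_fsr must be > 0")
  100 * (f_ps * k_fsr) / ((1 - f_ps) + f_ps * k_fsr)
}

#' Whole-body resting-EE increment from altered muscle protein synthesis
#'
#' Default formula: `100 x f_muscle x f_ps x (k_fsr x m_ratio - 1)`
#' percent increase in whole-body resting energy expenditure, combining
#' the fold-change in synthesis rate with the relative muscle protein
#' mass. The derivation of the increment from these inputs admits
#' variants; an alternative that renormalizes the muscle share as in
#' [muscle_ps_share_after_foldchange()] is exposed via `formula`.
#'
#' @param p a [partition_params()].
#' @param formula "linear" (default) or "renormalized".
#' @return percent increase in whole-body resting EE (0 when
#'   `k_fsr = m_ratio = 1`).
#' @examples
#' wholebody_ee_increment(partition_params(k_fsr = 2.5))  # 7.65
#' @export
wholebody_ee_increment <- function(p = partition_params(),
                                   formula = c("linear", "renormalized")) {
  formula <- match.arg(formula)
  km <- p$k_fsr * p$m_ratio
  if (formula == "linear") {
    100 * p$f_muscle * p$f_ps * (km - 1)
  } else {
    # muscle O2 scales by (1 - f_ps) + f_ps*km; the excess over baseline
    # is attributed to protein synthesis
    100 * p$f_muscle * ((1 - p$f_ps) + p$f_ps * km - 1)
  }
}

#' Energy-partition report
#'
#' Small summary table combining [baseline_contribution()],
#' [muscle_ps_share_after_foldchange()] and [wholebody_ee_increment()]
#' for one parameter set.
#'
#' @param p a [partition_params()].
#' @return data frame with `quantity`, `value` (percent) and `units`.
#' @export
partition_report <- function(p = partition_params()) {
  data.frame(
    quantity = c("baseline_contribution",
                 "muscle_ps_share_after_foldchange",
                 "wholebody_ee_increment"),
    value = c(baseline_contribution(p),
              muscle_ps_share_after_foldchange(p$f_ps, p$k_fsr),
              wholebody_ee_increment(p)),
    units = c("% of whole-body resting EE",
              "% of muscle O2 consumption",
              "% increase in whole-body resting EE"))
}
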