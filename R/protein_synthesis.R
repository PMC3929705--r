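#' Verify precursor-pool tracer equilibration
#'
#' Compares the specific radioactivity of free phenylalanine in the
#' tissue pool with that in blood; after a flooding dose the two should
#' agree. The ratio tissue/blood is reported; a sample passes when
#' |ratio - 1| <= `tolerance`. Failing samples are flagged downstream,
#' not dropped.
#'
#' @param s_a_blood,s_a_tissue precursor specific radioactivities
#'   (dpm/nmol, > 0).
#' @param tolerance allowed fractional deviation (default 0.15).
#' @return data frame with `ratio` and logical `pass`.
#' @examples
#' check_precursor_equilibration(1.0, 0.90)  # pass
#' check_precursor_equilibration(1.0, 0.80)  # fail
#' @export
check_precursor_equilibration <- function(s_a_blood, s_a_tissue,
                                          tolerance = 0.15) {
  df_assert(all(s_a_blood > 0) && all(s_a_tissue > 0), "bad_sa",
            "specific radioactivities must be > 0")
  ratio <- s_a_tissue / s_a_blood
  data.frame(ratio = ratio, pass = abs(ratio - 1) <= tolerance)
}

#' Flooding-dose fractional synthesis rate
#'
#' The percentage of a protein pool synthesized per day from the
#' accumulation of label into protein over a short labelling period with
#' a flooded (constant) precursor pool:
#' `FSR = S_B / (S_A x t) x 1440 x 100` (%/d), with `t` in minutes.
#' Linear in `S_B`.
#'
#' @param s_b protein-bound phenylalanine specific radioactivity
#'   (dpm/nmol, >= 0).
#' @param s_a precursor free phenylalanine specific radioactivity
#'   (dpm/nmol, > 0).
#' @param t_label labelling time in minutes (> 0).
#' @return fractional synthesis rate, %/d.
#' @examples
#' fsr(3.240e-3, 1, 15)  # 31.1
#' @export
fsr <- function(s_b, s_a, t_label) {
  df_assert(all(s_a > 0), "bad_sa", "precursor S_A must be > 0")
  df_assert(all(t_label > 0), "bad_time", "t_label must be > 0")
  df_assert(all(s_b >= 0), "bad_sb", "S_B must be >= 0")
  s_b / (s_a * t_label) * 1440 * 100
}

#' Translational efficiency
#'
#' Protein synthesized per unit ribosomal RNA per day:
#' `K_RNA = (FSR/100) / (RNA/TP / 1000) = 10 x FSR / (RNA/TP)`, in
#' g protein / g RNA / d (numerically matching the conventional "mg/g"
#' presentation).
#'
#' @param fsr_tp total-protein fractional synthesis rate (%/d).
#' @param rna_per_tp translational capacity, mg RNA per g protein (> 0).
#' @return translational efficiency, g protein/g RNA/d.
#' @examples
#' k_rna(31.1, 17.7)  # 17.57
#' @export
k_rna <- function(fsr_tp, rna_per_tp) {
  df_assert(all(rna_per_tp > 0), "bad_rna", "RNA/TP must be > 0")
  df_assert(all(fsr_tp >= 0), "bad_fsr", "FSR must be >= 0")
  10 * fsr_tp / rna_per_tp
}

#' Absolute protein synthesis rate
#'
#' Product of the total-protein fractional synthesis rate and the
#' total-protein mass of the muscle. Absolute myofibrillar synthesis is
#' deliberately not computed (myofibrillar purification is not
#' quantitative).
#'
#' @param fsr_tp total-protein FSR (%/d, >= 0).
#' @param tp_mass total-protein mass (mg, >= 0).
#' @return absolute synthesis rate, mg/d.
#' @examples
#' absolute_synthesis(31.1, 11.1)  # 3.4521
#' @export
absolute_synthesis <- function(fsr_tp, tp_mass) {
  df_assert(all(fsr_tp >= 0) && all(tp_mass >= 0), "bad_input",
            "FSR and TP mass must be >= 0")
  fsr_tp / 100 * tp_mass
}

#' Per-muscle synthesis results from a flooding-dose table
#'
#' Computes, for every animal x muscle row: TP and MP fractional
#' synthesis rates, their ratio, total-protein mass
#' (concentration x wet mass), absolute TP synthesis, translational
#' capacity (RNA/TP) and translational efficiency (K_RNA), and the
#' precursor equilibration flag. The precursor pool is the tissue free
#' pool by default, blood otherwise.
#'
#' @param flooding data frame with columns `animal_id`, `muscle`,
#'   `s_a_blood`, `s_a_tissue`, `s_b_tp`, `s_b_mp`, `t_label_min`,
#'   `tp_conc_mg_g`, `muscle_mass_mg`, `rna_mass_mg`.
#' @param precursor which free pool supplies S_A: "tissue" (default) or
#'   "blood".
#' @param equilibration_tol tolerance for
#'   [check_precursor_equilibration()] (default 0.15).
#' @return data frame of class `synthesis_result`, one row per
#'   animal x muscle: `fsr_tp`, `fsr_mp` (%/d), `mp_tp_ratio`, `tp_mass`
#'   (mg), `abs_synthesis_tp` (mg/d), `rna_per_tp` (mg/g), `k_rna`
#'   (g/g/d), `equilibration_ratio`, `equilibrated`.
#' @export
summarize_flooding <- function(flooding,
                               precursor = c("tissue", "blood"),
                               equilibration_tol = 0.15) {
  precursor <- match.arg(precursor)
  need <- c("animal_id", "muscle", "s_a_blood", "s_a_tissue", "s_b_tp",
            "s_b_mp", "t_label_min", "tp_conc_mg_g", "muscle_mass_mg",
            "rna_mass_mg")
  miss <- setdiff(need, names(flooding))
  df_assert(length(miss) == 0, "bad_table",
            "flooding missing column(s): %s", paste(miss, collapse = ", "))

  s_a <- if (precursor == "tissue") flooding$s_a_tissue else
    flooding$s_a_blood
  eq <- check_precursor_equilibration(flooding$s_a_blood,
                                      flooding$s_a_tissue,
                                      equilibration_tol)
  fsr_tp <- fsr(flooding$s_b_tp, s_a, flooding$t_label_min)
  fsr_mp <- fsr(flooding$s_b_mp, s_a, flooding$t_label_min)
  tp_mass <- flooding$tp_conc_mg_g * flooding$muscle_mass_mg / 1000
  rna_per_tp <- flooding$rna_mass_mg / (tp_mass / 1000)

  out <- data.frame(
    animal_id = flooding$animal_id,
    muscle = flooding$muscle,
    fsr_tp = fsr_tp,
    fsr_mp = fsr_mp,
    mp_tp_ratio = ifelse(fsr_tp > 0, fsr_mp / fsr_tp, NA_real_),
    tp_mass = tp_mass,
    abs_synthesis_tp = absolute_synthesis(fsr_tp, tp_mass),
    rna_per_tp = rna_per_tp,
    k_rna = k_rna(fsr_tp, rna_per_tp),
    equilibration_ratio = eq$ratio,
    equilibrated = eq$pass)
  class(out) <- c("synthesis_result", "data.frame")
  out
}
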