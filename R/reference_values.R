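#' Bundled mdx study group summaries
#'
#' Group-level summary statistics (means and standard errors) for juvenile
#' (4- to 5-wk-old) and adult (12- to 14-wk-old) mdx and control mice:
#' body size and composition, per-muscle protein synthesis parameters, and
#' energy-balance outcomes. These are the default parameterization of the
#' synthetic cohort generator ([default_cohort_spec()]) and the inputs for
#' the worked protein-turnover and energy-partition calculations; no animal
#' level raw data exist, so simulated cohorts are drawn from these summaries.
#'
#' @return A list of data frames:
#' \describe{
#'   \item{body}{one row per genotype x age group: `n`, and mean/SE pairs for
#'     body weight (g), fat-free mass (g), fat (g), body/femur/tibia
#'     length (mm).}
#'   \item{muscle}{one row per muscle x genotype x age group: `n`, total
#'     protein mass `tp_mg`, TP and myofibrillar-protein fractional synthesis
#'     rates (%/d), their ratio, translational capacity `rna_per_tp_mg_g`
#'     (mg RNA/g protein) and translational efficiency `k_rna_g_g_d`
#'     (g protein/g RNA/d), each with SE.}
#'   \item{energy}{one row per genotype x age group: `n` and mean/SE pairs
#'     for intake, 24-h/dark/light/resting energy expenditure (kcal), energy
#'     balance and respiratory quotients. Values are least-squares means
#'     adjusted for fat-free and fat mass.}
#'   \item{tp_conc}{gastrocnemius and diaphragm total-protein concentration
#'     (mg/g wet weight) per genotype x age group.}
#'   \item{whole_body}{scalar constants: phenylalanine hydroxylation as a
#'     percent of phenylalanine flux (`hydroxylation_pct`, 17), the fraction
#'     of whole-body oxygen consumption attributable to skeletal muscle
#'     (`f_muscle`, 0.30), the fraction of resting muscle oxygen consumption
#'     due to protein synthesis (`f_ps`, 0.17), diet metabolizable energy
#'     density (`diet_kcal_g`, 3.64 kcal/g) and the assumed phenylalanine
#'     content of body protein (`phe_protein_content`, 0.04).}
#' }
#' @examples
#' ref <- mdx_reference_values()
#' subset(ref$muscle, muscle == "gastrocnemius")
#' @export
mdx_reference_values <- function() {
  grp <- function(genotype, age_group) data.frame(
    genotype = genotype, age_group = age_group, stringsAsFactors = FALSE)

  g4 <- rbind(grp("mdx", "juvenile"), grp("control", "juvenile"),
              grp("mdx", "adult"), grp("control", "adult"))

  body <- cbind(g4, data.frame(
    n              = c(8, 8, 12, 10),
    weight_g       = c(16.5, 21.0, 29.1, 28.6),
    weight_se      = c(0.7, 0.7, 0.6, 0.6),
    ffm_g          = c(14.6, 18.0, 27.5, 23.7),
    ffm_se         = c(0.4, 0.4, 0.3, 0.4),
    fat_g          = c(1.96, 2.30, 2.16, 4.95),
    fat_se         = c(0.44, 0.44, 0.36, 0.39),
    body_length_mm = c(77.7, 83.0, 96.7, 96.3),
    body_length_se = c(0.4, 0.4, 0.3, 0.4),
    femur_mm       = c(12.6, 13.0, 16.1, 15.7),
    femur_se       = c(0.1, 0.1, 0.1, 0.1),
    tibia_mm       = c(15.5, 16.0, 18.3, 17.9),
    tibia_se       = c(0.1, 0.1, 0.1, 0.1)))

  mus <- function(muscle, n, tp, tp_se, fsr, fsr_se, mp, mp_se,
                  ratio, ratio_se, rna, rna_se, krna, krna_se) {
    cbind(g4, data.frame(
      muscle = muscle, n = n,
      tp_mg = tp, tp_se = tp_se,
      tp_fsr_pct_d = fsr, tp_fsr_se = fsr_se,
      mp_fsr_pct_d = mp, mp_fsr_se = mp_se,
      mp_tp_ratio = ratio, mp_tp_ratio_se = ratio_se,
      rna_per_tp_mg_g = rna, rna_per_tp_se = rna_se,
      k_rna_g_g_d = krna, k_rna_se = krna_se))
  }

  muscle <- rbind(
    mus("gastrocnemius", c(8, 8, 8, 7),
        c(11.1, 15.1, 29.2, 24.8), c(0.6, 0.6, 0.6, 0.6),
        c(31.1, 12.5, 9.8, 3.9),   c(1.2, 1.2, 1.2, 1.3),
        c(24.7, 10.4, 6.7, 3.2),   c(0.9, 0.9, 1.0, 1.0),
        c(0.80, 0.83, 0.67, 0.82), c(0.03, 0.03, 0.03, 0.03),
        c(17.7, 10.2, 7.7, 5.3),   c(0.5, 0.5, 0.6, 0.6),
        c(17.6, 12.3, 12.9, 7.2),  c(0.8, 0.8, 0.9, 0.9)),
    mus("diaphragm", c(8, 8, 4, 4),
        c(7.4, 7.3, 15.5, 11.2),   c(0.4, 0.4, 0.5, 0.5),
        c(27.3, 13.7, 15.7, 9.6),  c(1.3, 1.4, 1.5, 1.4),
        c(21.5, 11.1, 10.5, 7.0),  c(0.9, 1.0, 1.1, 1.0),
        c(0.79, 0.82, 0.67, 0.74), c(0.03, 0.03, 0.03, 0.03),
        c(25.0, 18.9, 18.8, 12.9), c(1.0, 1.1, 1.7, 1.4),
        c(10.9, 7.2, 9.0, 7.2),    c(0.4, 0.5, 0.7, 0.6)),
    mus("heart", c(8, 8, 8, 7),
        c(14.3, 14.3, 19.2, 18.2), c(0.5, 0.5, 0.5, 0.5),
        c(15.1, 12.9, 8.4, 7.9),   c(0.5, 0.5, 0.5, 0.5),
        c(13.6, 12.9, 8.1, 8.0),   c(0.5, 0.5, 0.5, 0.5),
        c(0.90, 0.99, 0.97, 1.01), c(0.02, 0.02, 0.02, 0.02),
        c(16.2, 16.4, 12.3, 11.4), c(0.5, 0.5, 0.5, 0.5),
        c(9.5, 7.9, 6.9, 7.0),     c(0.5, 0.5, 0.5, 0.5)))

  energy <- cbind(g4, data.frame(
    n               = c(8, 8, 9, 12),
    intake_kcal_d   = c(11.0, 11.3, 11.7, 10.9),
    intake_se       = c(0.7, 0.4, 0.6, 0.4),
    ee_24h_kcal_d   = c(11.0, 10.5, 10.4, 10.0),
    ee_24h_se       = c(0.5, 0.3, 0.4, 0.3),
    ee_dark_kcal    = c(5.9, 5.7, 5.5, 5.6),
    ee_dark_se      = c(0.5, 0.2, 0.3, 0.2),
    ee_light_kcal   = c(5.1, 4.8, 4.9, 4.4),
    ee_light_se     = c(0.2, 0.1, 0.2, 0.1),
    ee_resting_kcal_d = c(9.0, 8.4, 6.5, 6.1),
    ee_resting_se   = c(0.4, 0.2, 0.3, 0.2),
    balance_kcal_d  = c(0.44, 1.03, 0.74, 0.77),
    balance_se      = c(0.16, 0.16, 0.15, 0.13),
    rq_24h          = c(0.91, 0.92, 0.95, 0.96),
    rq_24h_se       = c(0.02, 0.02, 0.01, 0.01),
    rq_dark         = c(0.97, 0.97, 0.99, 0.99),
    rq_dark_se      = c(0.02, 0.02, 0.02, 0.01),
    rq_light        = c(0.84, 0.87, 0.92, 0.93),
    rq_light_se     = c(0.02, 0.02, 0.02, 0.01)))

  tp_conc <- rbind(
    cbind(g4, data.frame(muscle = "gastrocnemius",
                         tp_conc_mg_g = c(134, 151, 142, 163),
                         tp_conc_se = c(4, 3, 3, 2))),
    cbind(g4, data.frame(muscle = "diaphragm",
                         tp_conc_mg_g = c(135, 149, 138, 146),
                         tp_conc_se = c(3, 6, 4, 5))),
    cbind(g4, data.frame(muscle = "heart",
                         tp_conc_mg_g = c(156, 158, 160, 162),
                         tp_conc_se = c(3, 2, 2, 2))))

  list(
    body = body,
    muscle = muscle,
    energy = energy,
    tp_conc = tp_conc,
    whole_body = list(
      hydroxylation_pct = 17,
      f_muscle = 0.30,
      f_ps = 0.17,
      diet_kcal_g = 3.64,
      phe_protein_content = 0.04))
}
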