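#' Specify a synthetic cohort
#'
#' A cohort specification names the experimental groups (genotype x age
#' group with their sample sizes) and, for each group, the mean and SD of
#' every per-animal variable to simulate. [default_cohort_spec()] builds the
#' specification from the bundled mdx study summaries
#' ([mdx_reference_values()]), converting tabulated standard errors to SDs as
#' SE * sqrt(n) with the tabulated group n.
#'
#' Size-related variables (masses and lengths) within an animal are coupled
#' through a latent body-size factor with loading `size_cor`, so that e.g.
#' fat-free mass and body length are strongly correlated within groups, as
#' observed in real cohorts.
#'
#' @param groups data frame with columns `genotype` ("mdx"/"control"),
#'   `age_group` ("juvenile"/"adult") and `n` (animals per group, >= 1).
#' @param params data frame with columns `genotype`, `age_group`,
#'   `variable`, `mean` (> 0) and `sd` (>= 0): one row per simulated
#'   variable per group.
#' @param seed integer; global seed fanned out to per-animal substreams
#'   (stable by animal index, so enlarging the cohort does not perturb
#'   existing animals).
#' @param size_cor latent body-size factor loading in [0, 1) applied to
#'   size variables (default 0.96).
#' @param size_variables character vector of variable names treated as
#'   size-coupled; others are drawn independently.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(groups, params, seed = 1L, size_cor = 0.96,
                        size_variables = c("weight_g", "ffm_g",
                                           "body_length_mm", "femur_mm",
                                           "tibia_mm")) {
  df_assert(is.data.frame(groups) &&
              all(c("genotype", "age_group", "n") %in% names(groups)),
            "bad_spec", "groups needs genotype, age_group, n columns")
  bad <- setdiff(unique(groups$genotype), c("mdx", "control"))
  df_assert(length(bad) == 0, "bad_group_label",
            "unknown genotype label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(groups$age_group), c("juvenile", "adult"))
  df_assert(length(bad) == 0, "bad_group_label",
            "unknown age_group label(s): %s", paste(bad, collapse = ", "))
  df_assert(all(groups$n >= 1), "bad_spec", "each group needs n >= 1")
  df_assert(is.data.frame(params) &&
              all(c("genotype", "age_group", "variable", "mean", "sd")
                  %in% names(params)),
            "bad_spec", "params needs genotype/age_group/variable/mean/sd")
  df_assert(all(params$mean > 0), "bad_spec", "all means must be > 0")
  df_assert(all(params$sd >= 0), "bad_spec", "all SDs must be >= 0")
  df_assert(is_num1(size_cor) && size_cor >= 0 && size_cor < 1,
            "bad_spec", "size_cor must be in [0, 1)")
  structure(list(groups = groups, params = params,
                 seed = as.integer(seed), size_cor = size_cor,
                 size_variables = size_variables),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param n_per_group optional named override of group sizes; defaults to
#'   the bundled study sizes.
#' @export
default_cohort_spec <- function(seed = 1L, n_per_group = NULL) {
  ref <- mdx_reference_values()
  body <- ref$body
  groups <- body[, c("genotype", "age_group", "n")]
  if (!is.null(n_per_group)) groups$n <- n_per_group

  long <- function(df, var, se_col, value_col, n) {
    data.frame(genotype = df$genotype, age_group = df$age_group,
               variable = var, mean = df[[value_col]],
               sd = df[[se_col]] * sqrt(n))
  }
  vars <- list(c("weight_g", "weight_se"), c("ffm_g", "ffm_se"),
               c("fat_g", "fat_se"),
               c("body_length_mm", "body_length_se"),
               c("femur_mm", "femur_se"), c("tibia_mm", "tibia_se"))
  params <- do.call(rbind, lapply(vars, function(v)
    long(body, v[1], v[2], v[1], body$n)))

  # gastrocnemius TP concentration feeds the flooding-dose stage
  tpc <- ref$tp_conc[ref$tp_conc$muscle == "gastrocnemius", ]
  tpc <- tpc[match(interaction(body$genotype, body$age_group),
                   interaction(tpc$genotype, tpc$age_group)), ]
  params <- rbind(params, data.frame(
    genotype = body$genotype, age_group = body$age_group,
    variable = "tp_conc_mg_g", mean = tpc$tp_conc_mg_g,
    sd = tpc$tp_conc_se * sqrt(body$n)))

  cohort_spec(groups, params, seed = seed)
}

#' Simulate a cohort of animals
#'
#' Draws one row per animal from the group means and SDs of a
#' [cohort_spec()]. Variables listed as size variables share a latent
#' standard-normal body-size factor with loading `size_cor`; all other
#' variables are independent normals. Deterministic under a fixed seed;
#' with SD = 0 every animal equals its group mean exactly.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `animal_id`, `genotype`, `age_group` and one
#'   column per variable in `spec$params`.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 7))
#' aggregate(ffm_g ~ genotype + age_group, cohort, mean)
#' @export
simulate_cohort <- function(spec) {
  df_assert(inherits(spec, "cohort_spec"), "bad_spec",
            "spec must be a cohort_spec")
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    geno <- spec$groups$genotype[g]
    age <- spec$groups$age_group[g]
    pars <- spec$params[spec$params$genotype == geno &
                          spec$params$age_group == age, ]
    df_assert(nrow(pars) > 0, "bad_spec",
              "no parameters for group %s/%s", geno, age)
    pars <- pars[order(pars$variable), ]  # stable draw order
    for (a in seq_len(spec$groups$n[g])) {
      idx <- idx + 1L
      vals <- with_substream(spec$seed, idx, {
        z <- rnorm(1)                      # latent body-size factor
        eps <- rnorm(nrow(pars))
        rho <- ifelse(pars$variable %in% spec$size_variables,
                      spec$size_cor, 0)
        v <- pars$mean + pars$sd * (rho * z + sqrt(1 - rho^2) * eps)
        # masses and lengths are positive quantities: floor rare negative
        # draws at 1% of the group mean (mean bias negligible vs the SE)
        pmax(v, 0.01 * pars$mean)
      })
      row <- as.data.frame(as.list(setNames(vals, pars$variable)))
      rows[[idx]] <- cbind(
        data.frame(animal_id = sprintf("M%03d", idx), genotype = geno,
                   age_group = age, stringsAsFactors = FALSE),
        row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specify a metabolic-cage acquisition
#'
#' Parameters of a simulated CLAMS-style gas-exchange session: sampling
#' epoch, circadian structure, activity bursts, measurement noise, light
#' cycle and diet energy density. The defaults emulate a 72-h acquisition
#' at 90-s epochs with lights on 06:00-18:00.
#'
#' @param duration_h session length in hours (default 72).
#' @param epoch_s seconds per reading; must divide 86400 (default 90).
#' @param basal_vo2 nominal basal oxygen-consumption rate (mL/h) used as
#'   the pre-normalization scale (default 45).
#' @param circadian_amplitude fractional sinusoidal modulation of VO2 with
#'   peak mid-dark-phase, in [0, 1) (default 0.2).
#' @param activity_burst_rate_dark,activity_burst_rate_light Poisson rates
#'   (events/h) of activity bursts; each burst adds a proportional VO2
#'   increment and beam-break counts (defaults 8 and 2).
#' @param burst_vo2_gain fractional VO2 increase per burst event (0.3).
#' @param noise_cv multiplicative log-normal measurement noise CV on gas
#'   volumes (default 0.05; the instrument CV is not reported for this
#'   class of study, so 5% is a convention, flagged here).
#' @param light_on,light_off clock hours of the light phase (6 and 18).
#' @param rq_dark,rq_light phase respiratory quotients (0.97, 0.87).
#' @param diet_energy_density metabolizable energy density of the diet in
#'   kcal/g (default 3.64).
#' @param meals_per_day_dark,meals_per_day_light expected feeding events
#'   per phase (10 and 4).
#' @param spill_frac fraction of each meal spilled rather than eaten (0.05).
#' @param seed integer substream seed.
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(duration_h = 72, epoch_s = 90, basal_vo2 = 45,
                       circadian_amplitude = 0.2,
                       activity_burst_rate_dark = 8,
                       activity_burst_rate_light = 2,
                       burst_vo2_gain = 0.3,
                       noise_cv = 0.05,
                       light_on = 6, light_off = 18,
                       rq_dark = 0.97, rq_light = 0.87,
                       diet_energy_density = 3.64,
                       meals_per_day_dark = 10, meals_per_day_light = 4,
                       spill_frac = 0.05,
                       seed = 1L) {
  df_assert(86400 %% epoch_s == 0, "bad_epoch",
            "epoch_s (%s) must divide 86400", epoch_s)
  df_assert(duration_h > 0 && (duration_h * 3600) %% epoch_s == 0,
            "bad_epoch", "duration must be a whole number of epochs")
  df_assert(circadian_amplitude >= 0 && circadian_amplitude < 1,
            "bad_spec", "circadian_amplitude must be in [0, 1)")
  df_assert(noise_cv >= 0, "bad_spec", "noise_cv must be >= 0")
  structure(as.list(environment()), class = "trace_spec")
}

#' Simulate a gas-exchange/activity/feeder trace
#'
#' Forward model for one animal-cage session. VO2 follows a sinusoid with
#' peak mid-dark-phase (fractional amplitude `circadian_amplitude`) plus
#' Poisson activity bursts that add proportional VO2 increments and beam
#' breaks; VCO2 is VO2 times the phase respiratory quotient. Gas volumes
#' are renormalized per complete day (on the pre-noise signal) so that the
#' Weir-integrated daily energy expenditure of a noiseless trace equals
#' `truth_ee_kcal_d` exactly; multiplicative log-normal noise of CV
#' `noise_cv` is then applied. Feeding events are concentrated in the dark
#' phase; meal masses are scaled so eaten food equals
#' `truth_intake_kcal_d / diet_energy_density` per day, with a separately
#' recorded spillage mass exercising the intake correction.
#'
#' @param spec a [trace_spec()].
#' @param truth_ee_kcal_d true 24-h energy expenditure (kcal/d, > 0).
#' @param truth_intake_kcal_d true daily energy intake (kcal/d); defaults
#'   to `truth_ee_kcal_d` (zero balance).
#' @param animal_id identifier stored on the trace.
#' @param start trace start time (POSIXct, UTC); defaults to midnight so
#'   sessions span whole clock days.
#' @return data frame of class `gas_trace` with columns `timestamp`,
#'   `vo2_ml_h`, `vco2_ml_h`, `x_counts`, `z_counts`, `feeder_g`,
#'   `spill_g`, `refill`, and attributes `animal_id`, `epoch_s`,
#'   `light_on`, `light_off`, `truth`.
#' @examples
#' tr <- simulate_clams_trace(trace_spec(duration_h = 24, noise_cv = 0),
#'                            truth_ee_kcal_d = 11)
#' summarize_trace(tr, diet_energy_density = 3.64)$ee_24h
#' @export
simulate_clams_trace <- function(spec, truth_ee_kcal_d,
                                 truth_intake_kcal_d = NULL,
                                 animal_id = "A001",
                                 start = as.POSIXct("2023-01-02 00:00:00",
                                                    tz = "UTC")) {
  df_assert(inherits(spec, "trace_spec"), "bad_spec",
            "spec must be a trace_spec")
  df_assert(is_num1(truth_ee_kcal_d) && truth_ee_kcal_d > 0,
            "bad_truth", "truth_ee_kcal_d must be > 0")
  if (is.null(truth_intake_kcal_d)) truth_intake_kcal_d <- truth_ee_kcal_d
  df_assert(truth_intake_kcal_d >= 0, "bad_truth", "intake must be >= 0")

  n <- as.integer(spec$duration_h * 3600 / spec$epoch_s)
  epoch_h <- spec$epoch_s / 3600
  tstamp <- start + (seq_len(n) - 1L) * spec$epoch_s
  hour <- as.numeric(format(tstamp, "%H", tz = "UTC")) +
    as.numeric(format(tstamp, "%M", tz = "UTC")) / 60 +
    as.numeric(format(tstamp, "%S", tz = "UTC")) / 3600
  dark <- hour >= spec$light_off | hour < spec$light_on

  dark_len <- (spec$light_on - spec$light_off) %% 24
  mid_dark <- (spec$light_off + dark_len / 2) %% 24

  with_substream(spec$seed, 0L, {
    circ <- 1 + spec$circadian_amplitude *
      cos(2 * pi * (hour - mid_dark) / 24)
    burst_rate <- ifelse(dark, spec$activity_burst_rate_dark,
                         spec$activity_burst_rate_light)
    bursts <- rpois(n, burst_rate * epoch_h)
    signal <- spec$basal_vo2 * circ * (1 + spec$burst_vo2_gain * bursts)
    rq <- ifelse(dark, spec$rq_dark, spec$rq_light)

    # per-day renormalization of the pre-noise signal to the target EE
    day <- (seq_len(n) - 1L) %/% as.integer(86400 / spec$epoch_s)
    complete <- day %in% unique(day)[tabulate(day + 1L) ==
                                       86400 / spec$epoch_s]
    ee_rate <- (3.941 * signal + 1.106 * signal * rq) / 1000  # kcal/h
    for (d in unique(day)) {
      sel <- day == d
      day_kcal <- sum(ee_rate[sel]) * epoch_h
      frac_day <- sum(sel) * spec$epoch_s / 86400
      signal[sel] <- signal[sel] * truth_ee_kcal_d * frac_day / day_kcal
    }
    vo2 <- signal * lnorm_noise(n, spec$noise_cv)
    vco2 <- signal * rq * lnorm_noise(n, spec$noise_cv)

    # activity: baseline beam breaks plus burst-driven counts; rearing (Z)
    # is concentrated in the dark phase
    x_counts <- rpois(n, ifelse(dark, 8, 3)) + bursts * rpois(n, 30)
    z_counts <- rpois(n, ifelse(dark, 2, 0.5)) + bursts * rpois(n, 8)

    # feeder: meals mostly in the dark; per-day eaten mass exact
    feeder_drop <- numeric(n)
    spill_inc <- numeric(n)
    eaten_g_day <- truth_intake_kcal_d / spec$diet_energy_density
    for (d in unique(day)) {
      sel <- which(day == d)
      frac_day <- length(sel) * spec$epoch_s / 86400
      p_meal <- ifelse(dark[sel],
                       spec$meals_per_day_dark / sum(dark[sel] | TRUE),
                       NA)
      w_dark <- spec$meals_per_day_dark
      w_light <- spec$meals_per_day_light
      prob <- ifelse(dark[sel], w_dark, w_light)
      n_meals <- max(1L, rpois(1, (w_dark + w_light) * frac_day))
      at <- sample(sel, min(n_meals, length(sel)), prob = prob)
      w <- runif(length(at), 0.5, 1.5)
      meal_g <- w / sum(w) * eaten_g_day * frac_day
      feeder_drop[at] <- feeder_drop[at] + meal_g * (1 + spec$spill_frac)
      spill_inc[at] <- spill_inc[at] + meal_g * spec$spill_frac
    }
    feeder0 <- max(60, 2 * eaten_g_day * spec$duration_h / 24)
    feeder_g <- feeder0 - cumsum(feeder_drop)
    spill_g <- cumsum(spill_inc)

    out <- data.frame(timestamp = tstamp, vo2_ml_h = vo2,
                      vco2_ml_h = vco2, x_counts = x_counts,
                      z_counts = z_counts, feeder_g = feeder_g,
                      spill_g = spill_g, refill = 0L)
    attr(out, "animal_id") <- animal_id
    attr(out, "epoch_s") <- spec$epoch_s
    attr(out, "light_on") <- spec$light_on
    attr(out, "light_off") <- spec$light_off
    attr(out, "truth") <- list(ee_24h = truth_ee_kcal_d,
                               intake_kcal_d = truth_intake_kcal_d)
    class(out) <- c("gas_trace", "data.frame")
    out
  })
}

#' Ground truth for a tracer plateau simulation
#'
#' @param ra_phe_true,ra_tyr_true true tracee rates of appearance of
#'   phenylalanine and tyrosine (umol/kg/h, > 0).
#' @param hydroxylation_fraction_true fraction of the phenylalanine flux
#'   irreversibly hydroxylated to tyrosine, in [0, 1].
#' @param i_phe,i_tyr tracer infusion rates (umol/kg/h; defaults 16 and 11).
#' @param enrichment_noise_cv multiplicative noise CV on simulated plateau
#'   enrichments (default 0).
#' @param seed integer substream seed.
#' @return object of class `tracer_truth`.
#' @export
tracer_truth <- function(ra_phe_true, ra_tyr_true,
                         hydroxylation_fraction_true,
                         i_phe = 16, i_tyr = 11,
                         enrichment_noise_cv = 0, seed = 1L) {
  df_assert(all(c(ra_phe_true, ra_tyr_true, i_phe, i_tyr) > 0),
            "bad_truth", "all rates must be > 0")
  df_assert(hydroxylation_fraction_true >= 0 &&
              hydroxylation_fraction_true <= 1,
            "bad_truth", "hydroxylation fraction must be in [0, 1]")
  df_assert(enrichment_noise_cv >= 0, "bad_truth", "noise cv must be >= 0")
  structure(as.list(environment()), class = "tracer_truth")
}

#' Simulate plateau plasma enrichments
#'
#' Exact algebraic inverse of the steady-state flux estimators in the
#' tracer module: plateau enrichments are derived from the true rates of
#' appearance and hydroxylation fraction so that running
#' [estimate_fluxes()] on a noiseless output returns the truth to machine
#' precision. The `convention` and `thompson_correction` flags must match
#' the ones used at estimation.
#'
#' @param truth a [tracer_truth()].
#' @param n number of replicate animals to draw (default 1).
#' @param convention rate-of-appearance convention shared with the
#'   estimator: "tracee" (Ra = i(100/E - 1)) or "total" (Ra = 100 i/E).
#' @param thompson_correction logical; apply the phenylalanine-infusion
#'   correction factor (i_phe + Ra_phe)/i_phe in the hydroxylation model
#'   (default TRUE, matching the estimator default).
#' @return data frame with columns `animal_id`, `e_d5_phe_mpe`,
#'   `e_d4_tyr_mpe`, `e_d2_tyr_mpe`, `i_phe`, `i_tyr`.
#' @examples
#' tr <- tracer_truth(300, 80, 0.17)
#' enr <- simulate_tracer_plateau(tr)
#' estimate_fluxes(enr)$hydroxylation_fraction  # 0.17
#' @export
simulate_tracer_plateau <- function(truth, n = 1L,
                                    convention = c("tracee", "total"),
                                    thompson_correction = TRUE) {
  df_assert(inherits(truth, "tracer_truth"), "bad_truth",
            "truth must be a tracer_truth")
  convention <- match.arg(convention)
  with(truth, {
    if (convention == "tracee") {
      e5 <- 100 * i_phe / (i_phe + ra_phe_true)
      e2 <- 100 * i_tyr / (i_tyr + ra_tyr_true)
    } else {
      df_assert(ra_phe_true > i_phe && ra_tyr_true > i_tyr, "bad_truth",
                "total-flux convention needs Ra > infusion rate")
      e5 <- 100 * i_phe / ra_phe_true
      e2 <- 100 * i_tyr / ra_tyr_true
    }
    q_pt <- hydroxylation_fraction_true * ra_phe_true
    corr <- if (thompson_correction) (i_phe + ra_phe_true) / i_phe else 1
    e4 <- q_pt * e5 / (ra_tyr_true * corr)
    df_assert(e4 < 100, "bad_truth",
              "implied d4-tyr enrichment >= 100 mpe; truth inconsistent")
    with_substream(seed, 1L, {
      data.frame(
        animal_id = sprintf("T%03d", seq_len(n)),
        e_d5_phe_mpe = e5 * lnorm_noise(n, enrichment_noise_cv),
        e_d4_tyr_mpe = e4 * lnorm_noise(n, enrichment_noise_cv),
        e_d2_tyr_mpe = e2 * lnorm_noise(n, enrichment_noise_cv),
        i_phe = i_phe, i_tyr = i_tyr)
    })
  })
}

#' Ground truth for a flooding-dose simulation
#'
#' @param muscle muscle name(s).
#' @param fsr_true_tp,fsr_true_mp true fractional synthesis rates of the
#'   total and myofibrillar protein pools (%/d, >= 0), recycled over
#'   muscles.
#' @param s_a precursor-pool free phenylalanine specific radioactivity
#'   (dpm/nmol, default 15: a 250 uCi flooding dose distributed over a
#'   1.5 mmol/kg free pool in a ~25 g mouse).
#' @param t_label labelling time in minutes (> 0; default 15).
#' @param tp_conc_mg_g,muscle_mass_mg protein concentration and muscle wet
#'   mass used downstream to form TP mass.
#' @param rna_per_tp_mg_g translational capacity (mg RNA/g protein).
#' @param noise_cv multiplicative noise CV on specific radioactivities.
#' @param seed integer substream seed.
#' @return object of class `flooding_truth`.
#' @export
flooding_truth <- function(muscle = "gastrocnemius",
                           fsr_true_tp = 31.1, fsr_true_mp = 24.7,
                           s_a = 15, t_label = 15,
                           tp_conc_mg_g = 134, muscle_mass_mg = 83,
                           rna_per_tp_mg_g = 17.7,
                           noise_cv = 0, seed = 1L) {
  df_assert(all(fsr_true_tp >= 0) && all(fsr_true_mp >= 0),
            "bad_truth", "FSR truths must be >= 0")
  df_assert(all(s_a > 0), "bad_truth", "s_a must be > 0")
  df_assert(all(t_label > 0), "bad_truth", "t_label must be > 0")
  df_assert(noise_cv >= 0, "bad_truth", "noise_cv must be >= 0")
  structure(as.list(environment()), class = "flooding_truth")
}

#' Simulate flooding-dose specific radioactivities
#'
#' Inverse of the flooding-dose FSR estimator: the protein-bound specific
#' radioactivity is S_B = S_A x (FSR/100) x t_label/1440, so [fsr()] on a
#' noiseless output returns the truth to machine precision. Blood and
#' tissue precursor pools receive independent noise so the equilibration
#' check is exercisable.
#'
#' @param truth a [flooding_truth()]; vector fields are recycled across
#'   muscles.
#' @param n replicate animals (default 1).
#' @return data frame with one row per animal x muscle and columns
#'   `animal_id`, `muscle`, `s_a_blood`, `s_a_tissue`, `s_b_tp`, `s_b_mp`
#'   (dpm/nmol), `t_label_min`, `tp_conc_mg_g`, `muscle_mass_mg`,
#'   `rna_mass_mg`.
#' @examples
#' fl <- simulate_flooding_dose(flooding_truth(fsr_true_tp = 31.1))
#' fsr(fl$s_b_tp, fl$s_a_tissue, fl$t_label_min)  # 31.1
#' @export
simulate_flooding_dose <- function(truth, n = 1L) {
  df_assert(inherits(truth, "flooding_truth"), "bad_truth",
            "truth must be a flooding_truth")
  k <- length(truth$muscle)
  base <- data.frame(muscle = truth$muscle,
                     fsr_tp = rep_len(truth$fsr_true_tp, k),
                     fsr_mp = rep_len(truth$fsr_true_mp, k),
                     s_a = rep_len(truth$s_a, k),
                     t_label = rep_len(truth$t_label, k),
                     tp_conc = rep_len(truth$tp_conc_mg_g, k),
                     mass = rep_len(truth$muscle_mass_mg, k),
                     rna_per_tp = rep_len(truth$rna_per_tp_mg_g, k))
  rows <- lapply(seq_len(n), function(a) {
    with_substream(truth$seed, a, {
      m <- nrow(base)
      tp_mass <- base$tp_conc * base$mass / 1000
      data.frame(
        animal_id = sprintf("F%03d", a),
        muscle = base$muscle,
        s_a_blood = base$s_a * lnorm_noise(m, truth$noise_cv),
        s_a_tissue = base$s_a * lnorm_noise(m, truth$noise_cv),
        s_b_tp = base$s_a * (base$fsr_tp / 100) * base$t_label / 1440 *
          lnorm_noise(m, truth$noise_cv),
        s_b_mp = base$s_a * (base$fsr_mp / 100) * base$t_label / 1440 *
          lnorm_noise(m, truth$noise_cv),
        t_label_min = base$t_label,
        tp_conc_mg_g = base$tp_conc,
        muscle_mass_mg = base$mass,
        rna_mass_mg = base$rna_per_tp * tp_mass / 1000)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
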