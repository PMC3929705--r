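#' Specify a group-comparison model
#'
#' Names the outcome, the categorical factors (genotype and age group by
#' default), optional body-size covariates, and the interaction
#' thresholds: 0.10 for annotating factor interactions in reports and
#' 0.05 for triggering covariate x factor stratification.
#'
#' @param outcome outcome column name.
#' @param factors character vector of factor columns (default
#'   `c("genotype", "age_group")`).
#' @param covariates character vector of numeric covariate columns
#'   (default none).
#' @param interaction_threshold p-value for table annotation of factor
#'   interactions (default 0.10).
#' @param stratify_threshold p-value for covariate x factor stratification
#'   (default 0.05).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, factors = c("genotype", "age_group"),
                       covariates = character(),
                       interaction_threshold = 0.10,
                       stratify_threshold = 0.05) {
  df_assert(is.character(outcome) && length(outcome) == 1, "bad_spec",
            "outcome must be a single column name")
  df_assert(length(factors) >= 1, "bad_spec", "at least one factor needed")
  structure(list(outcome = outcome, factors = factors,
                 covariates = covariates,
                 interaction_threshold = interaction_threshold,
                 stratify_threshold = stratify_threshold),
            class = "model_spec")
}

# internal: validate and prepare the analysis frame; drops factors with a
# single observed level (degenerate designs, e.g. a juvenile-only cohort)
# and applies listwise deletion on missing values with a logged count.
prepare_frame <- function(table, spec, min_per_cell = 2) {
  cols <- c(spec$outcome, spec$factors, spec$covariates)
  miss <- setdiff(cols, names(table))
  df_assert(length(miss) == 0, "bad_table",
            "table missing column(s): %s", paste(miss, collapse = ", "))
  dat <- table[, cols, drop = FALSE]
  keep <- complete.cases(dat)
  if (any(!keep)) {
    message(sprintf("listwise deletion removed %d row(s) with missing values",
                    sum(!keep)))
  }
  dat <- dat[keep, , drop = FALSE]
  df_assert(is.numeric(dat[[spec$outcome]]), "bad_table",
            "outcome must be numeric")
  for (cv in spec$covariates) {
    df_assert(is.numeric(dat[[cv]]), "bad_table",
              "covariate %s must be numeric", cv)
  }
  active <- character()
  dropped <- character()
  for (f in spec$factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) >= 2) active <- c(active, f) else {
      dropped <- c(dropped, f)
      message(sprintf(
        "factor %s has a single level (%s); dropped from the design",
        f, levels(dat[[f]])[1]))
    }
  }
  df_assert(length(active) >= 1, "bad_design",
            "no factor with >= 2 levels in the table")
  cells <- interaction(dat[active], drop = FALSE)
  tab <- table(cells)
  df_assert(all(tab >= min_per_cell), "empty_cell",
            "design cell(s) with < %d animals: %s", min_per_cell,
            paste(names(tab)[tab < min_per_cell], collapse = ", "))
  list(data = dat, factors = active, dropped = dropped)
}

#' Two-way factorial ANOVA
#'
#' Fits the full factorial of the active factors on the outcome and
#' reports Type-II sums of squares (via `car::Anova`), F statistics and
#' p-values for the main effects and their interaction. Factors with a
#' single observed level are dropped with a note, so a one-age-group
#' design degrades gracefully to a one-way analysis.
#'
#' @param table data frame with the outcome and factor columns.
#' @param spec a [model_spec()] (covariates are ignored here).
#' @return list of class `anova_result`: `effects` (term, sumsq, df,
#'   statistic, p_value), `model` (the `lm` fit), `dropped_factors`.
#' @export
two_way_anova <- function(table, spec) {
  prep <- prepare_frame(table, spec)
  rhs <- paste(prep$factors, collapse = " * ")
  fit <- lm(as.formula(paste(spec$outcome, "~", rhs)), data = prep$data)
  a2 <- car::Anova(fit, type = 2)
  eff <- data.frame(term = rownames(a2),
                    sumsq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    statistic = a2[["F value"]],
                    p_value = a2[["Pr(>F)"]])
  eff <- eff[eff$term != "Residuals", ]
  rownames(eff) <- NULL
  structure(list(effects = eff, model = fit,
                 dropped_factors = prep$dropped),
            class = "anova_result")
}

#' ANCOVA with least-squares means
#'
#' Fits the factorial plus body-size covariates, reports Type-II effect
#' tests, covariate slopes, and least-squares (adjusted) group means
#' evaluated at the grand covariate mean via `emmeans`. When any
#' covariate x factor interaction is significant at the stratification
#' threshold, the `stratified` flag is set and per-stratum fits (the data
#' split on the other factor, mirroring a separate-analysis-by-age
#' design) are reported alongside.
#'
#' @param table data frame with outcome, factors and covariates.
#' @param spec a [model_spec()] with at least one covariate (an empty
#'   covariate list reduces exactly to [two_way_anova()] plus raw means).
#' @return list of class `lsmeans_result`: `lsmeans` (group levels,
#'   `emmean`, `SE`, confidence bounds), `effects`, `slopes`,
#'   `covariate_interactions`, `stratified`, `strata`, `model`,
#'   `dropped_factors`.
#' @export
ancova_lsmeans <- function(table, spec) {
  prep <- prepare_frame(table, spec)
  dat <- prep$data
  covs <- spec$covariates
  if (length(covs) > 0) {
    X <- as.matrix(dat[, covs, drop = FALSE])
    for (cv in covs) {
      grp <- interaction(dat[prep$factors])
      wvar <- tapply(dat[[cv]], grp, var)
      df_assert(any(wvar > 0, na.rm = TRUE), "degenerate_covariate",
                "covariate %s has zero variance within every group", cv)
    }
    df_assert(qr(cbind(1, X))$rank == ncol(X) + 1, "collinear_covariates",
              "covariates are collinear (rank-deficient design)")
  }

  rhs <- paste(c(paste(prep$factors, collapse = " * "), covs),
               collapse = " + ")
  fit <- lm(as.formula(paste(spec$outcome, "~", rhs)), data = dat)
  a2 <- car::Anova(fit, type = 2)
  eff <- data.frame(term = rownames(a2), sumsq = a2[["Sum Sq"]],
                    df = a2[["Df"]], statistic = a2[["F value"]],
                    p_value = a2[["Pr(>F)"]])
  eff <- eff[eff$term != "Residuals", ]
  rownames(eff) <- NULL

  em <- emmeans::emmeans(fit, specs = as.formula(
    paste("~", paste(prep$factors, collapse = " * "))))
  lsm <- as.data.frame(em)

  slopes <- if (length(covs) > 0) {
    setNames(coef(fit)[covs], covs)
  } else numeric()

  # covariate x factor interaction screen
  cov_int <- data.frame(covariate = character(), factor = character(),
                        p_value = numeric())
  if (length(covs) > 0) {
    for (cv in covs) {
      for (f in prep$factors) {
        rhs_i <- paste(c(paste(prep$factors, collapse = " * "), covs,
                         paste(cv, f, sep = ":")), collapse = " + ")
        fit_i <- lm(as.formula(paste(spec$outcome, "~", rhs_i)), data = dat)
        p <- anova(fit, fit_i)[2, "Pr(>F)"]
        cov_int <- rbind(cov_int, data.frame(
          covariate = cv, factor = f, p_value = p))
      }
    }
  }
  stratified <- nrow(cov_int) > 0 &&
    any(cov_int$p_value < spec$stratify_threshold, na.rm = TRUE)

  strata <- NULL
  if (stratified && length(prep$factors) >= 2) {
    # analyze each level of the second factor separately (the
    # separate-by-age design used when covariate slopes differ)
    split_by <- prep$factors[2]
    strata <- lapply(split(dat, dat[[split_by]]), function(d) {
      sub_spec <- model_spec(spec$outcome, factors = prep$factors[1],
                             covariates = covs,
                             stratify_threshold = spec$stratify_threshold)
      sub_fit <- lm(as.formula(paste(
        spec$outcome, "~",
        paste(c(prep$factors[1], covs), collapse = " + "))), data = d)
      list(lsmeans = as.data.frame(emmeans::emmeans(
        sub_fit, specs = as.formula(paste("~", prep$factors[1])))),
        model = sub_fit)
    })
  }

  structure(list(lsmeans = lsm, effects = eff, slopes = slopes,
                 covariate_interactions = cov_int,
                 stratified = stratified, strata = strata,
                 model = fit, dropped_factors = prep$dropped,
                 factors = prep$factors),
            class = "lsmeans_result")
}

#' Tukey-adjusted pairwise comparisons
#'
#' Pairwise comparisons of all design cells with studentized-range
#' (Tukey) adjustment, computed through `emmeans`. Adjusted p-values are
#' monotone in the absolute mean difference at fixed standard error and
#' never smaller than the unadjusted t-test p-values.
#'
#' @param table data frame with outcome and factor columns.
#' @param spec a [model_spec()]; covariates, if any, are included in the
#'   underlying model.
#' @return data frame with `contrast`, `estimate`, `SE`, `df`,
#'   `statistic`, `p_value` (Tukey-adjusted).
#' @export
tukey_posthoc <- function(table, spec) {
  prep <- prepare_frame(table, spec)
  df_assert(nlevels(interaction(prep$data[prep$factors], drop = TRUE)) >= 2,
            "bad_design", "post hoc testing needs >= 2 groups")
  rhs <- paste(c(paste(prep$factors, collapse = " * "), spec$covariates),
               collapse = " + ")
  fit <- lm(as.formula(paste(spec$outcome, "~", rhs)), data = prep$data)
  em <- emmeans::emmeans(fit, specs = as.formula(
    paste("~", paste(prep$factors, collapse = " * "))))
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             df = pr$df, statistic = pr$t.ratio, p_value = pr$p.value)
}
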