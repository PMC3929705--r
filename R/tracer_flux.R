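#' Tracer infusion protocol
#'
#' Primed-continuous infusion constants for the phenylalanine/tyrosine
#' steady-state protocol. Defaults: prime 16 and 11 umol/kg, continuous
#' 16 and 11 umol/kg/h for L-[ring-2H5]phenylalanine and
#' L-[ring-3,5-2H2]tyrosine respectively, and an assumed average
#' phenylalanine content of body protein of 4% for conversion of molar
#' fluxes to protein-equivalent rates.
#'
#' @param i_phe,i_tyr continuous infusion rates (umol/kg/h, > 0).
#' @param prime_phe,prime_tyr priming doses (umol/kg).
#' @param phe_protein_content phenylalanine mass fraction of body protein,
#'   in (0, 0.1] (default 0.04).
#' @param phe_molar_mass g/mol (default 165.19).
#' @return object of class `tracer_protocol`.
#' @export
tracer_protocol <- function(i_phe = 16, i_tyr = 11,
                            prime_phe = 16, prime_tyr = 11,
                            phe_protein_content = 0.04,
                            phe_molar_mass = 165.19) {
  df_assert(i_phe > 0 && i_tyr > 0, "bad_protocol",
            "infusion rates must be > 0")
  df_assert(phe_protein_content > 0 && phe_protein_content <= 0.1,
            "bad_protocol", "phe_protein_content must be in (0, 0.1]")
  structure(as.list(environment()), class = "tracer_protocol")
}

#' Steady-state rate of appearance by isotope dilution
#'
#' At plateau, the tracee rate of appearance follows from the dilution of
#' the infused tracer: Ra = i x (100/E - 1) with E in mole percent excess
#' (mpe). The alternative "total" convention Ra = i x 100/E (total flux
#' including the tracer) is exposed because published renderings of the
#' dilution equation vary; simulators and estimators in this package
#' always share the convention.
#'
#' @param i tracer infusion rate (umol/kg/h).
#' @param e_plateau plateau enrichment in mpe, in (0, 100).
#' @param convention "tracee" (default) or "total".
#' @return rate of appearance, umol/kg/h; strictly decreasing in
#'   `e_plateau`.
#' @examples
#' ra_steady_state(16, 50)  # 16
#' ra_steady_state(16, 4)   # 384
#' @export
ra_steady_state <- function(i, e_plateau, convention = c("tracee", "total")) {
  convention <- match.arg(convention)
  df_assert(all(i > 0), "bad_infusion", "infusion rate must be > 0")
  df_assert(all(e_plateau > 0) && all(e_plateau < 100), "bad_enrichment",
            "plateau enrichment must lie in (0, 100) mpe")
  if (convention == "tracee") i * (100 / e_plateau - 1) else
    i * 100 / e_plateau
}

#' Phenylalanine-to-tyrosine hydroxylation flux
#'
#' Thompson-style estimator of the irreversible conversion of
#' phenylalanine to tyrosine from the transfer of ring-label into the
#' tyrosine pool:
#' `Q_pt = Ra_tyr x (E_d4_tyr / E_d5_phe) x (i_phe + Ra_phe)/i_phe`,
#' where the final phenylalanine-infusion correction factor is applied by
#' default and can be disabled (`correction = FALSE`). Q_pt is zero if and
#' only if no label appears in tyrosine, and can never exceed the
#' phenylalanine flux; estimates violating that bound indicate
#' inconsistent enrichments and are rejected.
#'
#' @param ra_tyr tyrosine rate of appearance (umol/kg/h).
#' @param e_d4_tyr plateau d4-tyrosine enrichment (mpe, >= 0).
#' @param e_d5_phe plateau d5-phenylalanine enrichment (mpe, > 0).
#' @param i_phe phenylalanine tracer infusion rate (umol/kg/h).
#' @param ra_phe phenylalanine rate of appearance (umol/kg/h).
#' @param correction apply the infusion correction factor (default TRUE).
#' @return hydroxylation flux Q_pt, umol/kg/h.
#' @export
hydroxylation_flux <- function(ra_tyr, e_d4_tyr, e_d5_phe, i_phe, ra_phe,
                               correction = TRUE) {
  df_assert(all(e_d5_phe > 0), "bad_enrichment", "E_d5_phe must be > 0")
  df_assert(all(e_d4_tyr >= 0), "bad_enrichment", "E_d4_tyr must be >= 0")
  df_assert(all(c(ra_tyr, i_phe, ra_phe) > 0), "bad_flux",
            "rates must be > 0")
  corr <- if (correction) (i_phe + ra_phe) / i_phe else 1
  q_pt <- ra_tyr * (e_d4_tyr / e_d5_phe) * corr
  df_assert(all(q_pt <= ra_phe * (1 + 1e-9)), "inconsistent_enrichments",
            "estimated hydroxylation flux exceeds the phenylalanine flux")
  pmin(q_pt, ra_phe)
}

#' Partition the phenylalanine flux
#'
#' In the postabsorptive state the phenylalanine rate of appearance
#' reflects release from protein degradation; it is either reincorporated
#' by protein synthesis (PS_phe = Ra_phe - Q_pt) or irreversibly
#' hydroxylated to tyrosine (Q_pt), which therefore equals the net
#' phenylalanine loss (balance = -Q_pt). Molar fluxes are converted to
#' protein-equivalent rates via the phenylalanine molar mass and the
#' assumed 4% phenylalanine content of body protein.
#'
#' @param ra_phe phenylalanine rate of appearance (umol/kg/h).
#' @param q_pt hydroxylation flux (umol/kg/h), <= `ra_phe`.
#' @param protocol a [tracer_protocol()].
#' @return one-row data frame of class `flux_result` with `ra_phe`,
#'   `q_pt`, `ps_phe`, `net_balance` (umol/kg/h),
#'   `hydroxylation_fraction`, and `protein_breakdown`,
#'   `protein_synthesis`, `protein_balance` (g protein/kg/h).
#' @examples
#' partition_flux(100, 17)$ps_phe  # 83
#' @export
partition_flux <- function(ra_phe, q_pt, protocol = tracer_protocol()) {
  df_assert(all(ra_phe > 0) && all(q_pt >= 0), "bad_flux",
            "need ra_phe > 0 and q_pt >= 0")
  df_assert(all(q_pt <= ra_phe), "bad_flux",
            "q_pt must not exceed ra_phe")
  ps <- ra_phe - q_pt
  to_protein <- protocol$phe_molar_mass / protocol$phe_protein_content / 1e6
  out <- data.frame(
    ra_phe = ra_phe, q_pt = q_pt, ps_phe = ps, net_balance = -q_pt,
    hydroxylation_fraction = q_pt / ra_phe,
    protein_breakdown = ra_phe * to_protein,
    protein_synthesis = ps * to_protein,
    protein_balance = -q_pt * to_protein)
  class(out) <- c("flux_result", "data.frame")
  out
}

#' Estimate whole-body fluxes from a plateau enrichment table
#'
#' Runs the full steady-state pipeline per animal: rates of appearance of
#' phenylalanine and tyrosine from [ra_steady_state()], the hydroxylation
#' flux from [hydroxylation_flux()], and the postabsorptive partition
#' from [partition_flux()]. Enrichments below the instrument floor are
#' treated as missing (the whole animal is dropped with a message), not
#' as zero.
#'
#' @param enrichments data frame with columns `e_d5_phe_mpe`,
#'   `e_d4_tyr_mpe`, `e_d2_tyr_mpe` and optionally `i_phe`, `i_tyr`
#'   (falling back to the protocol) plus an `animal_id` and any carried
#'   covariate columns (e.g. `ffm_g`).
#' @param protocol a [tracer_protocol()].
#' @param convention passed to [ra_steady_state()].
#' @param correction passed to [hydroxylation_flux()].
#' @param enrichment_floor_mpe smallest quantifiable enrichment (default
#'   0.05 mpe) for the precursor tracers; lower d5-phe or d2-tyr values
#'   are missing.
#' @return data frame: `animal_id`, `ra_tyr`, all [partition_flux()]
#'   fields, and any carried columns.
#' @export
estimate_fluxes <- function(enrichments, protocol = tracer_protocol(),
                            convention = c("tracee", "total"),
                            correction = TRUE,
                            enrichment_floor_mpe = 0.05) {
  convention <- match.arg(convention)
  need <- c("e_d5_phe_mpe", "e_d4_tyr_mpe", "e_d2_tyr_mpe")
  miss <- setdiff(need, names(enrichments))
  df_assert(length(miss) == 0, "bad_table",
            "enrichments missing column(s): %s", paste(miss, collapse = ", "))
  i_phe <- if ("i_phe" %in% names(enrichments)) enrichments$i_phe else
    protocol$i_phe
  i_tyr <- if ("i_tyr" %in% names(enrichments)) enrichments$i_tyr else
    protocol$i_tyr

  # sub-floor enrichments are missing, not zero (an exact 0 for the d4-tyr
  # product is legitimate: no detectable conversion)
  below <- function(e, allow_zero = FALSE) {
    e < enrichment_floor_mpe & !(allow_zero & e == 0)
  }
  low <- below(enrichments$e_d5_phe_mpe) |
    below(enrichments$e_d2_tyr_mpe) |
    below(enrichments$e_d4_tyr_mpe, allow_zero = TRUE)
  if (any(low)) {
    message(sprintf(
      "%d animal(s) below the %.2f mpe enrichment floor treated as missing",
      sum(low), enrichment_floor_mpe))
  }
  keep <- which(!low)
  df_assert(length(keep) > 0, "bad_table", "no quantifiable enrichments")
  e5 <- enrichments$e_d5_phe_mpe[keep]
  e4 <- enrichments$e_d4_tyr_mpe[keep]
  e2 <- enrichments$e_d2_tyr_mpe[keep]

  ra_phe <- ra_steady_state(i_phe[keep], e5, convention)
  ra_tyr <- ra_steady_state(i_tyr[keep], e2, convention)
  q_pt <- hydroxylation_flux(ra_tyr, e4, e5, i_phe[keep], ra_phe,
                             correction)
  res <- partition_flux(ra_phe, q_pt, protocol)
  carried <- setdiff(names(enrichments),
                     c(need, "i_phe", "i_tyr"))
  out <- cbind(enrichments[keep, carried, drop = FALSE],
               data.frame(ra_tyr = ra_tyr), res)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted flux comparison
#'
#' Convenience wrapper around [ancova_lsmeans()] with fat-free mass as
#' the body-size covariate, the adjustment used for whole-body flux
#' outcomes.
#'
#' @param flux_table output of [estimate_fluxes()] joined to cohort
#'   covariates.
#' @param outcome outcome column name (default "ra_phe").
#' @param ffm_column covariate column name (default "ffm_g").
#' @param factors grouping factors present in the table.
#' @return an [ancova_lsmeans()] result.
#' @export
adjust_for_ffm <- function(flux_table, outcome = "ra_phe",
                           ffm_column = "ffm_g",
                           factors = c("genotype", "age_group")) {
  ancova_lsmeans(flux_table,
                 model_spec(outcome, factors = factors,
                            covariates = ffm_column))
}
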