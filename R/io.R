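# Table schemas: required columns and row-level invariant checks.
# Units are encoded in column names (e.g. vo2_ml_h).
pipeline_schemas <- function() {
  list(
    cohort = list(
      required = c("animal_id", "genotype", "age_group"),
      check = function(df) {
        bad <- which(!df$genotype %in% c("mdx", "control"))
        if (length(bad)) return(sprintf("invalid genotype at row %s",
                                        paste(bad, collapse = ", ")))
        bad <- which(!df$age_group %in% c("juvenile", "adult"))
        if (length(bad)) return(sprintf("invalid age_group at row %s",
                                        paste(bad, collapse = ", ")))
        num <- names(df)[vapply(df, is.numeric, logical(1))]
        for (v in num) {
          bad <- which(df[[v]] < 0)
          if (length(bad)) return(sprintf("negative %s at row %s", v,
                                          paste(bad, collapse = ", ")))
        }
        NULL
      }),
    trace = list(
      required = c("timestamp", "vo2_ml_h", "vco2_ml_h", "x_counts",
                   "z_counts", "feeder_g", "spill_g"),
      check = function(df) {
        for (v in c("vo2_ml_h", "vco2_ml_h", "x_counts", "z_counts")) {
          bad <- which(df[[v]] < 0)
          if (length(bad)) return(sprintf("negative %s at row %s", v,
                                          paste(bad, collapse = ", ")))
        }
        refill <- if ("refill" %in% names(df)) df$refill else
          rep(0, nrow(df))
        jumps <- which(diff(df$feeder_g) > 1e-9)
        bad <- jumps[refill[jumps + 1L] == 0]
        if (length(bad)) {
          return(sprintf("feeder refill without flag at %s",
                         paste(df$timestamp[bad + 1L], collapse = ", ")))
        }
        NULL
      }),
    enrichments = list(
      required = c("animal_id", "e_d5_phe_mpe", "e_d4_tyr_mpe",
                   "e_d2_tyr_mpe"),
      check = function(df) {
        for (v in c("e_d5_phe_mpe", "e_d2_tyr_mpe")) {
          bad <- which(df[[v]] <= 0 | df[[v]] >= 100)
          if (length(bad)) return(sprintf(
            "%s outside (0, 100) mpe at row %s", v,
            paste(bad, collapse = ", ")))
        }
        bad <- which(df$e_d4_tyr_mpe < 0 | df$e_d4_tyr_mpe >= 100)
        if (length(bad)) return(sprintf(
          "e_d4_tyr_mpe outside [0, 100) at row %s",
          paste(bad, collapse = ", ")))
        NULL
      }),
    flooding = list(
      required = c("animal_id", "muscle", "s_a_blood", "s_a_tissue",
                   "s_b_tp", "s_b_mp", "t_label_min", "tp_conc_mg_g",
                   "muscle_mass_mg", "rna_mass_mg"),
      check = function(df) {
        for (v in c("s_a_blood", "s_a_tissue", "t_label_min")) {
          bad <- which(df[[v]] <= 0)
          if (length(bad)) return(sprintf("nonpositive %s at row %s", v,
                                          paste(bad, collapse = ", ")))
        }
        for (v in c("s_b_tp", "s_b_mp")) {
          bad <- which(df[[v]] < 0)
          if (length(bad)) return(sprintf("negative %s at row %s", v,
                                          paste(bad, collapse = ", ")))
        }
        NULL
      }))
}

#' Validate a pipeline table
#'
#' Checks that a CSV file (or in-memory data frame) matches one of the
#' pipeline schemas: every required column present and parseable, and all
#' row-level invariants satisfied. Violations are rejected with the
#' offending columns, row numbers or timestamps named.
#'
#' @param x path to a CSV file (metadata header lines starting with `#`
#'   are ignored) or a data frame.
#' @param schema one of "cohort", "trace", "enrichments", "flooding".
#' @return the validated data frame, invisibly classed by schema.
#' @export
validate_table <- function(x, schema = c("cohort", "trace", "enrichments",
                                         "flooding")) {
  schema <- match.arg(schema)
  sch <- pipeline_schemas()[[schema]]
  df <- if (is.character(x)) {
    df_assert(file.exists(x), "missing_file", "no such file: %s", x)
    read_pipeline_csv(x)
  } else x
  miss <- setdiff(sch$required, names(df))
  df_assert(length(miss) == 0, "schema_mismatch",
            "%s table missing column(s): %s", schema,
            paste(miss, collapse = ", "))
  numeric_cols <- setdiff(sch$required,
                          c("animal_id", "genotype", "age_group",
                            "muscle", "timestamp"))
  for (v in numeric_cols) {
    df_assert(is.numeric(df[[v]]), "schema_mismatch",
              "column %s is not numeric", v)
  }
  problem <- sch$check(df)
  df_assert(is.null(problem), "invalid_rows", "%s", problem)
  invisible(df)
}

#' Write a pipeline CSV with a metadata header
#'
#' RFC-4180 CSV (UTF-8, one header row) preceded by `#`-prefixed metadata
#' lines recording the tool version, seed and configuration hash, so
#' every output is self-describing and byte-reproducible under a fixed
#' seed.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param config_hash optional configuration digest string.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(df, path, seed = NA, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tool: dystroflux %s",
                     as.character(packageVersion("dystroflux"))), con)
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  }
  if (inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_csv
#' @param path CSV path to read; `#` metadata lines are skipped and
#'   ISO-8601 `timestamp` columns are parsed to POSIXct (UTC).
#' @export
read_pipeline_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("timestamp" %in% names(df) && is.character(df$timestamp)) {
    df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
  }
  df
}

# internal: stable digest of a configuration (md5 of its deparsed form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[sort(names(config))]), tmp)
  unname(md5sum(tmp))
}
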