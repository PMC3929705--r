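# Shared fixture builders and independent oracles used across test files.

# Minimal hand-built gas trace: vectors of instantaneous VO2/VCO2 (mL/h)
# at a fixed epoch, starting at midnight UTC, with inert feeder/activity
# columns unless supplied.
make_trace <- function(vo2_ml_h, vco2_ml_h = vo2_ml_h, epoch_s = 90,
                       x_counts = 0, z_counts = 0,
                       feeder_g = 50, spill_g = 0, refill = 0L,
                       light_on = 6, light_off = 18,
                       start = as.POSIXct("2023-01-02 00:00:00",
                                          tz = "UTC")) {
  n <- length(vo2_ml_h)
  tr <- data.frame(
    timestamp = start + (seq_len(n) - 1L) * epoch_s,
    vo2_ml_h = vo2_ml_h,
    vco2_ml_h = rep_len(vco2_ml_h, n),
    x_counts = rep_len(x_counts, n),
    z_counts = rep_len(z_counts, n),
    feeder_g = rep_len(feeder_g, n),
    spill_g = rep_len(spill_g, n),
    refill = rep_len(refill, n))
  attr(tr, "animal_id") <- "T001"
  attr(tr, "epoch_s") <- epoch_s
  attr(tr, "light_on") <- light_on
  attr(tr, "light_off") <- light_off
  class(tr) <- c("gas_trace", "data.frame")
  tr
}

# VO2 rate (mL/h) producing a given per-epoch EE (kcal) at RQ = 1
vo2_for_epoch_kcal <- function(kcal, epoch_s = 90) {
  kcal / 5.047 * 1000 * 3600 / epoch_s
}

# Balanced 2x2 cohort outcome table
make_cell_table <- function(values_by_cell) {
  do.call(rbind, lapply(names(values_by_cell), function(k) {
    parts <- strsplit(k, "\\.")[[1]]
    data.frame(genotype = parts[1], age_group = parts[2],
               y = values_by_cell[[k]])
  }))
}

# Independent Type-II ANOVA oracle from explicit least-squares fits:
# SS(A | B) and SS(A:B | A, B), F against the full-model residual MS.
anova_type2_oracle <- function(tab, outcome = "y",
                               factors = c("genotype", "age_group")) {
  y <- tab[[outcome]]
  A <- factor(tab[[factors[1]]])
  B <- factor(tab[[factors[2]]])
  rss <- function(X) {
    fit <- qr(X)
    sum(qr.resid(fit, y)^2)
  }
  mm <- function(formula) model.matrix(formula, data.frame(A = A, B = B))
  rss_full <- rss(mm(~ A * B))
  df_full <- length(y) - qr(mm(~ A * B))$rank
  ss <- c(A = rss(mm(~ B)) - rss(mm(~ A + B)),
          B = rss(mm(~ A)) - rss(mm(~ A + B)),
          AB = rss(mm(~ A + B)) - rss_full)
  dfs <- c(A = nlevels(A) - 1, B = nlevels(B) - 1,
           AB = (nlevels(A) - 1) * (nlevels(B) - 1))
  f <- (ss / dfs) / (rss_full / df_full)
  p <- pf(f, dfs, df_full, lower.tail = FALSE)
  data.frame(term = names(ss), sumsq = unname(ss), df = unname(dfs),
             statistic = unname(f), p_value = unname(p))
}

# Independent Tukey studentized-range oracle for a one-way layout
tukey_oracle <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  df_res <- length(y) - k
  mse <- sum((y - ave(y, g))^2) / df_res
  pairs <- combn(levels(g), 2)
  data.frame(
    g1 = pairs[1, ], g2 = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      d <- abs(mi[pr[1]] - mi[pr[2]])
      se <- sqrt(mse / 2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
      ptukey(d / se, nmeans = k, df = df_res, lower.tail = FALSE)
    }))
}
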