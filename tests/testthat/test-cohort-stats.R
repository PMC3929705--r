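test_that("identical groups yield null F statistics", {
  cell <- c(1, 2, 3, 4, 5)
  tab <- make_cell_table(list(mdx.juvenile = cell, control.juvenile = cell,
                              mdx.adult = cell, control.adult = cell))
  res <- two_way_anova(tab, model_spec("y"))
  expect_true(all(res$effects$p_value > 0.999))
  expect_true(all(abs(res$effects$statistic) < 1e-10))
})

test_that("a pure genotype shift is detected without spurious interaction", {
  set.seed(101)
  p_geno <- p_int <- numeric(25)
  for (i in 1:25) {
    tab <- make_cell_table(list(
      mdx.juvenile = rnorm(20, 3), control.juvenile = rnorm(20, 0),
      mdx.adult = rnorm(20, 3), control.adult = rnorm(20, 0)))
    eff <- two_way_anova(tab, model_spec("y"))$effects
    p_geno[i] <- eff$p_value[eff$term == "genotype"]
    p_int[i] <- eff$p_value[eff$term == "genotype:age_group"]
  }
  expect_true(all(p_geno < 0.001))
  expect_gt(mean(p_int > 0.05), 0.9)
})

test_that("Type-II effects match a brute-force least-squares oracle", {
  set.seed(55)
  tab <- make_cell_table(list(
    mdx.juvenile = rnorm(3, 10), control.juvenile = rnorm(3, 12),
    mdx.adult = rnorm(3, 11), control.adult = rnorm(3, 14.5)))
  got <- two_way_anova(tab, model_spec("y"))$effects
  want <- anova_type2_oracle(tab)
  # car reports terms in the same A, B, A:B order
  expect_equal(got$sumsq, want$sumsq, tolerance = 1e-10)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
})

test_that("empty and underfilled design cells are rejected", {
  tab <- make_cell_table(list(mdx.juvenile = rnorm(4),
                              control.juvenile = rnorm(4),
                              mdx.adult = rnorm(4),
                              control.adult = rnorm(1)))
  expect_error(two_way_anova(tab, model_spec("y")), "empty_cell")
})

test_that("single-level factors are dropped with a note", {
  tab <- make_cell_table(list(mdx.juvenile = rnorm(6, 1),
                              control.juvenile = rnorm(6)))
  expect_message(res <- two_way_anova(tab, model_spec("y")),
                 "single level")
  expect_equal(res$dropped_factors, "age_group")
  expect_equal(res$effects$term, "genotype")
})

test_that("an outcome-orthogonal covariate leaves group means unchanged", {
  set.seed(9)
  tab <- make_cell_table(list(
    mdx.juvenile = rnorm(8, 10), control.juvenile = rnorm(8, 12),
    mdx.adult = rnorm(8, 11), control.adult = rnorm(8, 13)))
  # construct a covariate with exactly zero partial association: residuals
  # of a random vector on the outcome and the design
  X <- model.matrix(~ genotype * age_group + y, tab)
  tab$cov <- qr.resid(qr(X), rnorm(nrow(tab))) + 5
  res <- ancova_lsmeans(tab, model_spec("y", covariates = "cov"))
  raw <- aggregate(y ~ genotype + age_group, tab, mean)
  merged <- merge(res$lsmeans, raw, by = c("genotype", "age_group"))
  expect_equal(merged$emmean, merged$y, tolerance = 1e-8)
  expect_lt(abs(res$slopes[["cov"]]), 1e-8)
})

test_that("ANCOVA recovers an injected covariate slope and group effect", {
  set.seed(12)
  n <- 30
  tab <- rbind(
    data.frame(genotype = "mdx", age_group = "juvenile",
               ffm_g = rnorm(n, 14.6, 1)),
    data.frame(genotype = "control", age_group = "juvenile",
               ffm_g = rnorm(n, 18, 1)))
  effect <- 1.5
  tab$y <- ifelse(tab$genotype == "mdx", effect, 0) + 2 * tab$ffm_g +
    rnorm(2 * n, sd = 0.4)
  res <- ancova_lsmeans(tab, model_spec("y", covariates = "ffm_g"))
  expect_equal(unname(res$slopes[["ffm_g"]]), 2, tolerance = 0.1)
  lsm <- res$lsmeans
  diff_adj <- lsm$emmean[lsm$genotype == "mdx"] -
    lsm$emmean[lsm$genotype == "control"]
  expect_equal(diff_adj, effect, tolerance = 0.3)
  # the unadjusted difference is badly confounded by the FFM gap
  raw_diff <- mean(tab$y[tab$genotype == "mdx"]) -
    mean(tab$y[tab$genotype == "control"])
  expect_lt(raw_diff, 0)
})

test_that("LS-means are invariant to affine covariate rescaling", {
  set.seed(13)
  tab <- make_cell_table(list(
    mdx.juvenile = rnorm(8, 10), control.juvenile = rnorm(8, 12),
    mdx.adult = rnorm(8, 11), control.adult = rnorm(8, 13)))
  tab$cov <- rnorm(nrow(tab), 20, 3)
  a <- ancova_lsmeans(tab, model_spec("y", covariates = "cov"))
  tab$cov <- 100 + 7 * tab$cov
  b <- ancova_lsmeans(tab, model_spec("y", covariates = "cov"))
  expect_equal(a$lsmeans$emmean, b$lsmeans$emmean, tolerance = 1e-8)
  expect_equal(a$lsmeans$SE, b$lsmeans$SE, tolerance = 1e-8)
})

test_that("covariate-by-factor interactions trigger stratified reporting", {
  set.seed(14)
  n <- 25
  tab <- rbind(
    data.frame(genotype = "mdx", age_group = rep(c("juvenile", "adult"),
                                                 each = n)),
    data.frame(genotype = "control", age_group = rep(c("juvenile", "adult"),
                                                     each = n)))
  tab$cov <- rnorm(nrow(tab), 10, 2)
  slope <- ifelse(tab$genotype == "mdx", 3, -3)  # opposing slopes
  tab$y <- slope * tab$cov + rnorm(nrow(tab), sd = 0.5)
  res <- ancova_lsmeans(tab, model_spec("y", covariates = "cov"))
  expect_true(res$stratified)
  expect_true(any(res$covariate_interactions$p_value < 0.05))
  expect_named(res$strata, c("adult", "juvenile"), ignore.order = TRUE)

  # homogeneous slopes do not stratify
  tab$y <- 2 * tab$cov + rnorm(nrow(tab), sd = 0.5)
  res2 <- ancova_lsmeans(tab, model_spec("y", covariates = "cov"))
  expect_false(res2$stratified)
})

test_that("collinear covariates are rejected with a message", {
  set.seed(15)
  tab <- make_cell_table(list(mdx.juvenile = rnorm(6),
                              control.juvenile = rnorm(6)))
  tab$c1 <- rnorm(nrow(tab))
  tab$c2 <- 2 * tab$c1 + 1
  expect_error(
    ancova_lsmeans(tab, model_spec("y", covariates = c("c1", "c2"))),
    "collinear")
})

test_that("Tukey post hoc matches the studentized-range oracle", {
  set.seed(16)
  tab <- data.frame(genotype = rep(c("mdx", "control"), each = 9),
                    age_group = "juvenile",
                    y = c(rnorm(9, 0), rnorm(9, 1.2)))
  tab3 <- data.frame(
    g = rep(c("a", "b", "c"), each = 7),
    y = c(rnorm(7, 0), rnorm(7, 0.8), rnorm(7, 2)))
  # one-way three-group toy against the direct ptukey computation
  suppressMessages({
    got <- tukey_posthoc(cbind(tab3, genotype = tab3$g,
                               age_group = "juvenile"),
                         model_spec("y", factors = "g"))
  })
  want <- tukey_oracle(tab3$y, tab3$g)
  expect_equal(sort(got$p_value), sort(want$p_value), tolerance = 1e-8)

  # adjusted p never below the unadjusted two-sample t-test p
  suppressMessages({
    got2 <- tukey_posthoc(tab, model_spec("y"))
  })
  raw_p <- t.test(y ~ genotype, tab, var.equal = TRUE)$p.value
  expect_gte(got2$p_value[1], raw_p - 1e-12)

  # identical groups: all adjusted p ~ 1
  same <- make_cell_table(list(mdx.juvenile = 1:5, control.juvenile = 1:5,
                               mdx.adult = 1:5, control.adult = 1:5))
  suppressMessages(got3 <- tukey_posthoc(same, model_spec("y")))
  expect_true(all(got3$p_value > 0.999))
})

test_that("simulated juvenile cohorts reproduce the size correlation", {
  cohort <- simulate_cohort(default_cohort_spec(
    seed = 33, n_per_group = c(30, 30, 1, 1)))
  juv <- cohort[cohort$age_group == "juvenile", ]
  expect_gt(cor(juv$ffm_g, juv$body_length_mm), 0.85)
})
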