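## Statistics layer: pairwise tests, Holm-Sidak, multigroup designs,
## correlation with missing data, 4PL fits.

test_that("pairwise tests reproduce their reference behaviours", {
  ## identical samples: t = 0, p = 1
  tr <- pairwise_tests(c(1, 2, 3), c(1, 2, 3), method = "welch_t")
  expect_equal(tr$statistic, 0)
  expect_equal(tr$p, 1)
  ## exact Mann-Whitney against the enumeration oracle
  expect_equal(pairwise_tests(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")$p,
               mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(31)
  x <- rnorm(6); y <- rnorm(7, 0.5)
  expect_equal(pairwise_tests(x, y, method = "mann_whitney")$p,
               mw_exact_oracle(x, y))
  ## Welch reduces to Student at equal n and variance
  set.seed(5); a <- rnorm(12); b <- a[sample(12)] + 1
  pw <- pairwise_tests(a, b, method = "welch_t")
  ps <- pairwise_tests(a, b, method = "student_t")
  expect_equal(pw$p, ps$p, tolerance = 1e-12)
  ## log transform guards positivity
  expect_error(pairwise_tests(c(-1, 2, 3), c(1, 2, 3), method = "welch_t",
                              log_transform = TRUE),
               class = "cm_validation_error")
  ## one-sample t
  t1 <- pairwise_tests(c(1.1, 0.9, 1.05, 0.95), method = "one_sample_t", mu = 1)
  expect_equal(t1$p, t.test(c(1.1, 0.9, 1.05, 0.95), mu = 1)$p.value)
})

test_that("Holm-Sidak matches the closed form and is monotone", {
  adj <- adjust_holm_sidak(c(0.01, 0.2, 0.3, 0.4, 0.5))
  expect_equal(adj[1], 1 - (1 - 0.01)^5, tolerance = 1e-12)
  expect_equal(adjust_holm_sidak(0.037), 0.037)
  for (s in 1:20) {
    set.seed(s)
    p <- runif(8)
    a <- adjust_holm_sidak(p)
    expect_true(all(a >= p))                      # never decreases
    expect_true(all(diff(a[order(p)]) >= -1e-12)) # monotone in sorted order
  }
  expect_error(adjust_holm_sidak(c(0.5, 1.2)), class = "cm_validation_error")
})

test_that("multigroup designs handle degenerate and well-separated groups", {
  g <- rep(c("ctrl", "a", "b"), each = 5)
  const <- rep(2, 15)
  kw <- multigroup_tests(const, g, design = "kruskal_dunn", control = "ctrl")
  expect_equal(kw$omnibus$statistic, 0)
  av <- multigroup_tests(const, g, design = "anova_dunnett", control = "ctrl")
  expect_equal(av$omnibus$statistic, 0)
  expect_true(av$omnibus$zero_variance)

  hits <- vapply(1:100, function(s) {
    set.seed(s)
    v <- c(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
    gg <- rep(c("ctrl", "a", "b"), each = 10)
    multigroup_tests(v, gg, design = "kruskal_dunn", control = "ctrl")$omnibus$p < 0.001
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("Dunnett with two groups reduces to the two-sided t-test", {
  set.seed(11)
  v <- c(rnorm(10), rnorm(10, 1))
  g <- rep(c("ctrl", "t1"), each = 10)
  mg <- multigroup_tests(v, g, design = "anova_dunnett", control = "ctrl")
  tt <- t.test(v[g == "t1"], v[g == "ctrl"], var.equal = TRUE)
  expect_equal(mg$comparisons[[1]]$p_adjusted, tt$p.value, tolerance = 1e-6)
})

test_that("Dunnett adjusted p-values agree with the multcomp reference", {
  set.seed(21)
  v <- c(rnorm(8), rnorm(8, 0.8), rnorm(8, 0.2), rnorm(10, -0.5))  # unbalanced
  g <- relevel(factor(rep(c("ctrl", "a", "b", "c"), c(8, 8, 8, 10))), "ctrl")
  mg <- multigroup_tests(v, g, design = "anova_dunnett", control = "ctrl")
  ref <- summary(multcomp::glht(aov(v ~ g),
                                linfct = multcomp::mcp(g = "Dunnett")))
  p_ref <- as.numeric(ref$test$pvalues)
  p_ours <- vapply(mg$comparisons, `[[`, numeric(1), "p_adjusted")
  expect_equal(unname(p_ours), p_ref, tolerance = 5e-3)
  ## adjusted p never falls below raw p, including in far tails
  set.seed(2)
  v2 <- c(rnorm(6), rnorm(6, 8), rnorm(6, 0.5), rnorm(6, -8))
  g2 <- relevel(factor(rep(c("ctrl", "a", "b", "c"), each = 6)), "ctrl")
  mg2 <- multigroup_tests(v2, g2, design = "anova_dunnett", control = "ctrl")
  for (cc in mg2$comparisons) expect_gte(cc$p_adjusted, cc$p)
})

test_that("Dunnett family-wise error is controlled at the null", {
  fwer <- vapply(1:2000, function(s) {
    set.seed(s)
    v <- rnorm(30)
    g <- rep(c("ctrl", "a", "b"), each = 10)
    any(vapply(multigroup_tests(v, g, design = "anova_dunnett",
                                control = "ctrl")$comparisons,
               `[[`, numeric(1), "p_adjusted") < 0.05)
  }, logical(1))
  expect_lte(mean(fwer), 0.05 + 2.6 * sqrt(0.05 * 0.95 / 2000))
})

test_that("repeated-measures design needs complete blocks and matches donors", {
  d <- expand.grid(donor = c("d1", "d2", "d3"), dose = c("0", "1", "10"))
  set.seed(3)
  d$y <- rnorm(9, mean = as.numeric(as.character(d$dose)))
  res <- multigroup_tests(d$y, d$dose, design = "rm_anova_dunnett",
                          control = "0", blocks = d$donor)
  expect_length(res$comparisons, 2)
  expect_error(multigroup_tests(d$y[-1], d$dose[-1], design = "rm_anova_dunnett",
                                control = "0", blocks = d$donor[-1]),
               class = "cm_incomplete_blocks")
})

test_that("missing control labels are reported by name", {
  err <- tryCatch(multigroup_tests(rnorm(9), rep(c("a", "b", "c"), 3),
                                   design = "anova_dunnett", control = "vehicle"),
                  error = identity)
  expect_s3_class(err, "cm_missing_control")
  expect_match(conditionMessage(err), "vehicle")
})

test_that("correlations reduce correctly and respect monotone transforms", {
  set.seed(9)
  X <- MASS::mvrnorm(60, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  tab <- data.frame(a = X[, 1], b = X[, 2])
  r_em <- correlation_matrix(tab, "em_mvn")$r[1, 2]
  expect_equal(r_em, cor(X)[1, 2], tolerance = 1e-8)
  ## strictly monotone pairs: Spearman r = 1, invariant to transforms
  mono <- data.frame(a = 1:20, b = exp(seq(0.1, 2, length.out = 20)))
  expect_equal(correlation_matrix(mono, "spearman")$r[1, 2], 1)
  tab2 <- tab; tab2$b <- exp(tab2$b)
  expect_equal(correlation_matrix(tab2, "spearman")$r[1, 2],
               correlation_matrix(tab, "spearman")$r[1, 2])
  ## sparse variables are dropped with a warning
  tab3 <- cbind(tab, c = c(1, 2, rep(NA, 58)))
  expect_warning(cr3 <- correlation_matrix(tab3, "pearson"), "dropping")
  expect_equal(cr3$variables, c("a", "b"))
})

test_that("EM correlation matrices are symmetric positive semi-definite", {
  for (s in 1:10) {
    set.seed(s)
    S <- matrix(0.5, 4, 4); diag(S) <- 1
    X <- MASS::mvrnorm(80, rep(0, 4), S)
    X[matrix(runif(320) < 0.25, 80, 4)] <- NA
    cr <- correlation_matrix(as.data.frame(X), "em_mvn")
    expect_equal(cr$r, t(cr$r))
    expect_gte(min(eigen(cr$r, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_true(all(diag(cr$r) == 1))
  }
})

test_that("4PL fits recover generating parameters and reject flat data", {
  dr <- synth_dose_response(0.005, hill = 1.2,
                            protocol = synth_protocol(seed = 4, noise_sd = 0))
  fit <- fit_dose_response(dr$dose_um, dr$activity_pct)
  expect_equal(fit$ic50, 0.005, tolerance = 1e-3)
  expect_equal(fit$hill, 1.2, tolerance = 1e-3)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_error(fit_dose_response(c(1, 2, 4, 8), rep(50, 4)), class = "cm_no_fit")

  ## at 2% activity noise the IC50 is recovered to within 10% on average
  ## (per-seed spread is wider because all four parameters are free)
  errs <- vapply(1:100, function(s) {
    dr <- synth_dose_response(0.005, protocol = synth_protocol(seed = s, noise_sd = 2))
    abs(fit_dose_response(dr$dose_um, dr$activity_pct)$ic50 - 0.005) / 0.005
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})
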