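## Generator contracts: determinism, closed-form forward models, protocol
## structure, and the statistical structure of synthetic cohorts.

sphere <- indenter_spec("sphere", radius_um = 7.5, nu = 0.5)

test_that("generators are byte-identical under a fixed seed and vary across seeds", {
  p1 <- synth_protocol(seed = 42, noise_sd = 0.5)
  p2 <- synth_protocol(seed = 43, noise_sd = 0.5)
  expect_identical(synth_indentation_curve(10, sphere, p1),
                   synth_indentation_curve(10, sphere, p1))
  expect_false(identical(synth_indentation_curve(10, sphere, p1)$d,
                         synth_indentation_curve(10, sphere, p2)$d))
  expect_identical(synth_fibril_topography(protocol = p1),
                   synth_fibril_topography(protocol = p1))
  expect_identical(synth_compression_test(5, protocol = synth_protocol(seed = 7, noise_sd = 1, sampling_step = 0.05)),
                   synth_compression_test(5, protocol = synth_protocol(seed = 7, noise_sd = 1, sampling_step = 0.05)))
  expect_identical(synth_cohort(protocol = p1), synth_cohort(protocol = p1))
  expect_identical(synth_dose_response(0.005, protocol = p1),
                   synth_dose_response(0.005, protocol = p1))
  expect_identical(synth_invitro_study(p1), synth_invitro_study(p1))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(synth_cohort(protocol = synth_protocol(seed = 9)))
  expect_identical(rnorm(1), before)
})

test_that("noiseless indentation curve matches the closed-form Hertz force", {
  cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = 1, noise_sd = 0),
                                 depth_max = 1000)
  fi <- to_force_indentation(cur)
  expect_equal(max(fi$F), hertz_force_nN(10, 0.5, 7.5, 1000), tolerance = 1e-3)

  zero <- synth_indentation_curve(0, sphere, synth_protocol(seed = 1, noise_sd = 0))
  expect_true(all(zero$d == 0))
  expect_error(synth_indentation_curve(-1, sphere), class = "cm_validation_error")
  expect_error(synth_indentation_curve(10, sphere, depth_max = 0),
               class = "cm_validation_error")
})

test_that("fibril topography bands at the requested period", {
  topo <- synth_fibril_topography(period = 67, protocol = synth_protocol(seed = 1, noise_sd = 0))
  prof <- extract_long_axis_profile(topo, crest_polyline(topo))
  ## independent check: direct autocorrelation of the detrended profile
  ac <- stats::acf(stats::resid(stats::lm(prof$height ~ prof$s)),
                   lag.max = 150, plot = FALSE)$acf[-1]
  peaks <- which(diff(sign(diff(ac))) == -2) + 1
  expect_equal(peaks[1], 67, tolerance = 0.02)

  ## resampling at 2 nm pixels halves the lag index; physical period unchanged
  topo2 <- synth_fibril_topography(period = 67,
                                   protocol = synth_protocol(seed = 1, noise_sd = 0,
                                                             sampling_step = 2))
  prof2 <- extract_long_axis_profile(topo2, crest_polyline(topo2))
  ac2 <- stats::acf(stats::resid(stats::lm(prof2$height ~ prof2$s)),
                    lag.max = 80, plot = FALSE)$acf[-1]
  peaks2 <- which(diff(sign(diff(ac2))) == -2) + 1
  expect_equal(peaks2[1], round(peaks[1] / 2), tolerance = 0.05)
  expect_equal(peaks2[1] * 2, peaks[1], tolerance = 0.05)

  expect_error(synth_fibril_topography(period = 1.5,
                                       protocol = synth_protocol(seed = 1)),
               class = "cm_aliasing_error")
})

test_that("compression generator honours the five-cycle 25%-strain protocol", {
  ct <- synth_compression_test(5, protocol = synth_protocol(seed = 3, sampling_step = 0.05))
  cyc <- segment_cycles(ct)
  expect_length(cyc, 5)
  for (cc in cyc) {
    expect_equal(cc$peak_strain, 0.25, tolerance = 1e-10)
    durations <- tapply(cc$time, cc$phase, function(t) diff(range(t)))
    expect_equal(unname(durations["compress"]), 15, tolerance = 0.11)
    expect_equal(unname(durations["hold"]), 2, tolerance = 0.11)
    expect_equal(unname(durations["recover"]), 15, tolerance = 0.11)
  }
  ## noiseless round trip through the analysis inversion
  ym <- young_modulus_sphere(ct)
  expect_equal(ym$E_kpa, 5, tolerance = 0.01)
})

test_that("cohort generator imposes the requested stiffness-crosslink correlation", {
  ## group effects removed so the pooled correlation isolates the copula
  vars_null <- list(
    stiffness_kpa = list(control = c(2.5, 1.0), case = c(2.5, 1.0)),
    mature_crosslinks = list(control = c(0.2, 0.08), case = c(0.2, 0.08)))
  spec <- cohort_spec(16, 16, variables = vars_null, target_corr = 0.72,
                      extra_corr = data.frame(var1 = character(), var2 = character(),
                                              r = numeric()))
  rs <- vapply(1:100, function(s) {
    co <- synth_cohort(spec, synth_protocol(seed = s))
    cor(co$stiffness_kpa, co$mature_crosslinks, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.72), 0.15)
  expect_gt(min(rs), 0.2)
})

test_that("null cohorts give nominal Welch type-I error", {
  vars_null <- list(stiffness_kpa = list(control = c(2.5, 1.0), case = c(2.5, 1.0)))
  spec <- cohort_spec(16, 16, variables = vars_null, target_corr = 0,
                      extra_corr = data.frame(var1 = character(), var2 = character(),
                                              r = numeric()))
  rej <- vapply(1:2000, function(s) {
    co <- synth_cohort(spec, synth_protocol(seed = s))
    pairwise_tests(co$stiffness_kpa[co$group == "case"],
                   co$stiffness_kpa[co$group == "control"],
                   method = "welch_t", log_transform = TRUE)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("MCAR missingness lands at the requested rate", {
  spec <- cohort_spec(100, 100, missing_rate = 0.2)
  co <- synth_cohort(spec, synth_protocol(seed = 5))
  cells <- as.matrix(co[, !(names(co) %in% c("donor", "group"))])
  n_cells <- length(cells)
  bounds <- qbinom(c(0.005, 0.995), n_cells, 0.2) / n_cells
  frac <- mean(is.na(cells))
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  ## donor and group are never blanked
  expect_false(anyNA(co$donor) || anyNA(co$group))
})

test_that("infeasible correlation structures are rejected", {
  bad <- cohort_spec(10, 10, target_corr = 0.95,
                     extra_corr = data.frame(
                       var1 = c("stiffness_kpa", "immature_crosslinks"),
                       var2 = c("immature_crosslinks", "mature_crosslinks"),
                       r = c(0.9, -0.9)))
  expect_error(synth_cohort(bad, synth_protocol(seed = 1)),
               class = "cm_not_positive_definite")
})

test_that("dose-response generator is anchored at its IC50 midpoint", {
  dr <- synth_dose_response(0.005, doses = c(1e-4, 1e-3, 0.005, 0.05, 0.5),
                            protocol = synth_protocol(seed = 1, noise_sd = 0))
  expect_equal(dr$activity_pct[dr$dose_um == 0.005], 50)
  ## dose -> 0 approaches the top plateau
  lo <- synth_dose_response(0.005, doses = 1e-8,
                            protocol = synth_protocol(seed = 1, noise_sd = 0))
  expect_equal(lo$activity_pct, 100, tolerance = 1e-4)
  expect_error(synth_dose_response(0), class = "cm_validation_error")
})
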