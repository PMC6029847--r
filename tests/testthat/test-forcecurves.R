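## Force-curve analysis: contact detection, force-indentation conversion,
## Hertz and Oliver-Pharr fits, aggregation and elastograph statistics.

sphere <- indenter_spec("sphere", radius_um = 7.5, nu = 0.5)
cone <- indenter_spec("cone", half_angle_deg = 20, nu = 0.5)

test_that("contact point is located within 3 samples of the true contact", {
  for (s in 1:5) {
    cur <- synth_indentation_curve(10, sphere,
                                   synth_protocol(seed = s, noise_sd = 0.3))
    cp <- detect_contact_point(cur)
    expect_lte(abs(cp$contact_index - attr(cur, "truth")$contact_index), 3)
  }
})

test_that("contact detection is invariant to a constant deflection offset", {
  cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = 2, noise_sd = 0.3))
  cp0 <- detect_contact_point(cur)
  shifted <- force_curve(cur$z, cur$d + 25, cur$k, cur$segments)
  cp1 <- detect_contact_point(shifted)
  expect_identical(cp1$contact_index, cp0$contact_index)
})

test_that("a flat curve raises NoContact", {
  flat <- force_curve(z = seq(0, 1000, length.out = 200),
                      d = rep(0, 200), k = 0.48)
  expect_error(detect_contact_point(flat), class = "cm_no_contact")
})

test_that("force-indentation conversion follows F = k d and delta = dz - dd", {
  z <- seq(0, 100, length.out = 50)
  contact <- list(contact_index = 1L, z_c = 0, d_c = 0)
  ## constant 10 nm deflection at k = 0.48 N/m -> 4.8 nN
  cur <- force_curve(z, rep(10, 50), k = 0.48)
  fi <- to_force_indentation(cur, contact)
  expect_equal(fi$F, rep(4.8, 50))
  ## zero deflection: F = 0, delta = z - z_c
  cur0 <- force_curve(z, rep(0, 50), k = 0.48)
  fi0 <- to_force_indentation(cur0, contact)
  expect_equal(fi0$F, rep(0, 50))
  expect_equal(fi0$delta, z)
  ## rigid-sample limit d = z - z_c: delta = 0 everywhere
  curR <- force_curve(z, z, k = 0.48)
  fiR <- to_force_indentation(curR, contact)
  expect_equal(fiR$delta, rep(0, 50))
})

test_that("Hertz sphere fit recovers the generating modulus and scales correctly", {
  cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = 1, noise_sd = 0))
  fi <- to_force_indentation(cur)
  fit <- fit_hertz_sphere(fi$delta, fi$F, sphere)
  expect_equal(fit$modulus, 10, tolerance = 0.01)
  ## linear in force amplitude
  fit2 <- fit_hertz_sphere(fi$delta, 2 * fi$F, sphere)
  expect_equal(fit2$modulus, 2 * fit$modulus, tolerance = 1e-10)
  ## E scales as R^(-1/2) in the assumed radius
  wrongR <- indenter_spec("sphere", radius_um = 30, nu = 0.5)
  fit3 <- fit_hertz_sphere(fi$delta, fi$F, wrongR)
  expect_equal(fit3$modulus / fit$modulus, sqrt(7.5 / 30), tolerance = 1e-8)
  expect_error(fit_hertz_sphere(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), sphere),
               class = "cm_insufficient_data")
})

test_that("fitted modulus is invariant to piezo translation and baseline offset", {
  cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = 6, noise_sd = 0.2))
  fitE <- function(curve) {
    fi <- to_force_indentation(curve)
    fit_hertz_sphere(fi$delta, fi$F, sphere)$modulus
  }
  E0 <- fitE(cur)
  shifted <- force_curve(cur$z + 500, cur$d + 12, cur$k, cur$segments)
  expect_equal(fitE(shifted), E0, tolerance = 1e-6)
})

test_that("Oliver-Pharr recovers unloading stiffness and plane-strain modulus", {
  cur <- synth_indentation_curve(5000, cone, synth_protocol(seed = 2, noise_sd = 0))
  op <- fit_oliver_pharr(cur, cone)
  tr <- attr(cur, "truth")
  S_closed <- tr$unload$alpha * tr$unload$m *
    (tr$depth_max - tr$unload$h_f)^(tr$unload$m - 1)
  expect_equal(op$S_nN_per_nm, S_closed, tolerance = 0.01)
  M_true <- 5000 / (1 - 0.5^2)
  expect_equal(op$modulus, M_true, tolerance = 0.05)
  expect_false(op$m_flagged)
})

test_that("Oliver-Pharr flags pathological unloading exponents and short segments", {
  cur <- synth_indentation_curve(5000, cone, synth_protocol(seed = 3, noise_sd = 0),
                                 unload = list(m = 3.5))
  op <- fit_oliver_pharr(cur, cone)
  expect_true(op$m_flagged)

  short <- synth_indentation_curve(5000, cone,
                                   synth_protocol(seed = 3, noise_sd = 0, n_points = 20))
  ## rebuild with an 8-point retract
  ret <- which(short$segments == "retract")
  keep <- c(which(short$segments == "approach"), ret[seq_len(8)])
  cur8 <- force_curve(short$z[keep], short$d[keep], short$k, short$segments[keep])
  expect_error(fit_oliver_pharr(cur8, cone), class = "cm_insufficient_data")
})

test_that("modulus aggregation reports mean/sem/n with protocol flags", {
  agg <- aggregate_modulus(rep(3.2, 30), level = "fibril")
  expect_equal(agg$mean, 3.2)
  expect_equal(agg$sem, 0)
  expect_false(agg$below_protocol)
  expect_equal(aggregate_modulus(c(1, 2, 3), level = "fibril")$mean, 2)
  expect_true(aggregate_modulus(rep(1, 20), level = "fibril")$below_protocol)
  expect_true(aggregate_modulus(rep(1, 79), level = "donor")$below_protocol)
  expect_error(aggregate_modulus(numeric(0)), class = "cm_validation_error")
})

test_that("elastograph CV is the sample SD over the mean and scale-invariant", {
  m <- elasto_map(x = c(0, 1, 2), y = c(0, 0, 0), modulus = c(1, 2, 3))
  st <- elastograph_stats(m)
  expect_equal(st$cv_pct, 50)
  expect_equal(st$mean_kpa, 2)
  m3 <- elasto_map(x = c(0, 1, 2), y = c(0, 0, 0), modulus = 3 * c(1, 2, 3))
  expect_equal(elastograph_stats(m3)$cv_pct, 50)
  const <- elasto_map(x = 1:4, y = rep(0, 4), modulus = rep(2, 4))
  expect_equal(elastograph_stats(const)$cv_pct, 0)
  zero <- elasto_map(x = 1:3, y = rep(0, 3), modulus = rep(0, 3))
  expect_error(elastograph_stats(zero), class = "cm_undefined_error")
})
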