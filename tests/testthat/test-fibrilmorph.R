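## Fibril morphometry: profiles, D-period, diameter, swelling, population
## statistics and shortest-axis measurement.

test_that("profiles along grid rows reproduce the row heights and arc length", {
  h <- matrix(rnorm(20 * 50), 20, 50)
  topo <- topography(h, pixel_nm = 2)
  prof <- extract_long_axis_profile(topo, cbind(x = c(1, 50), y = c(7, 7)))
  expect_equal(prof$height, h[7, ], tolerance = 1e-12)
  expect_equal(max(prof$s), 49 * 2, tolerance = 2)  # within one pixel
  expect_error(extract_long_axis_profile(topo, cbind(x = c(1, 60), y = c(7, 7))),
               class = "cm_validation_error")
})

test_that("D-period estimation hits the banding period and detrends tilt", {
  topo <- synth_fibril_topography(period = 67, protocol = synth_protocol(seed = 1, noise_sd = 0))
  prof <- extract_long_axis_profile(topo, crest_polyline(topo))
  p0 <- estimate_d_period(prof)
  expect_equal(as.numeric(p0), 67, tolerance = 0.5 / 67)

  tilted <- prof
  tilted$height <- prof$height + 0.01 * prof$s + 40   # tilt + offset
  expect_equal(as.numeric(estimate_d_period(tilted)), as.numeric(p0),
               tolerance = 1e-6)

  ## amplitude scaling leaves the estimate unchanged
  scaled <- prof
  scaled$height <- 3.7 * prof$height
  expect_equal(as.numeric(estimate_d_period(scaled)), as.numeric(p0),
               tolerance = 1e-9)

  flat <- prof
  flat$height <- rep(5, length(prof$s))
  expect_error(estimate_d_period(flat), class = "cm_no_period")
})

test_that("banding-free noisy fibrils yield no period", {
  topo <- synth_fibril_topography(band_depth = 0,
                                  protocol = synth_protocol(seed = 2, noise_sd = 0.8))
  prof <- extract_long_axis_profile(topo, crest_polyline(topo))
  expect_error(estimate_d_period(prof), class = "cm_no_period")
})

test_that("period error stays below half a pixel down to SNR 5", {
  errs <- vapply(1:10, function(s) {
    topo <- synth_fibril_topography(period = 67,
                                    protocol = synth_protocol(seed = s, noise_sd = 8 / 5))
    prof <- extract_long_axis_profile(topo, crest_polyline(topo))
    abs(as.numeric(estimate_d_period(prof)) - 67)
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("fibril diameter is the background-corrected height, offset-invariant", {
  ## half-cylinder ridge of height 100 nm on a 10 nm background
  ny <- 81; nx <- 40
  y <- seq_len(ny); y0 <- 41; hw <- 25
  t_y <- ifelse(abs(y - y0) < hw, sqrt(pmax(1 - ((y - y0) / hw)^2, 0)), 0)
  h <- outer(t_y * 100, rep(1, nx)) + 10
  topo <- topography(h, pixel_nm = 1)
  d <- fibril_diameter(topo, sections = c(10, 20, 30))
  expect_equal(as.numeric(d), 100, tolerance = 0.01)
  topo2 <- topography(h + 5, pixel_nm = 1)
  expect_equal(as.numeric(fibril_diameter(topo2, sections = c(10, 20, 30))),
               as.numeric(d), tolerance = 1e-12)
  expect_error(fibril_diameter(topo, sections = integer(0)),
               class = "cm_validation_error")
})

test_that("swelling ratio is a plain diameter ratio with guarded input", {
  expect_equal(swelling_ratio(100, 80), 1.25)
  expect_equal(swelling_ratio(73.2, 73.2), 1)
  expect_equal(swelling_ratio(2 * 100, 80), 2 * swelling_ratio(100, 80))
  expect_error(swelling_ratio(100, 0), class = "cm_validation_error")
})

test_that("diameter distributions summarise groups and detect the median shift", {
  set.seed(77)
  sym <- rnorm(500, 100, 10)
  dd <- diameter_distribution(list(ctrl = sym), bin_width = 5)
  expect_lt(abs(dd$summary$skewness), 0.2)
  expect_equal(diameter_distribution(list(a = c(50, 60, 70)))$summary$median, 60)
  expect_error(diameter_distribution(list(a = c(1, 2))),
               class = "cm_insufficient_data")
  ## shared bins are anchored at zero with the stated width
  expect_true(all(diff(sort(unique(dd$histogram$bin_mid))) == 5))

  ## power: case median 18% below control, n = 42 vs 57
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    ctrl <- rlnorm(42, log(100), 0.25)
    case <- rlnorm(57, log(82), 0.25)
    dd <- diameter_distribution(list(control = ctrl, case = case))
    dd$test$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("shortest axis matches brute-force caliper widths per component", {
  ## disc of diameter 50 px
  g <- expand.grid(r = 1:60, c = 1:60)
  disc <- matrix(as.integer((g$r - 30)^2 + (g$c - 30)^2 <= 24.5^2), 60, 60)
  sa <- shortest_axis(disc, pixel_nm = 1)
  expect_lt(abs(as.numeric(sa) - 50), 1.1)   # within one pixel

  ## 40 x 80 px ellipse vs the rotation oracle
  ell <- matrix(as.integer(((g$r - 30) / 19.5)^2 + ((g$c - 30) / 39.5)^2 <= 1), 60, 60)
  sa_e <- shortest_axis(ell, pixel_nm = 1)
  idx <- which(ell == 1)
  pts <- cbind((idx - 1) %/% 60 + 1, (idx - 1) %% 60 + 1)
  expect_equal(as.numeric(sa_e), brute_caliper(pts) + 1, tolerance = 1 / 40)
  expect_equal(as.numeric(sa_e), 40, tolerance = 1.5 / 40)

  ## two components, ordered by discovery; each min width <= max width
  two <- matrix(0L, 30, 30)
  two[2:6, 2:20] <- 1L      # 5 x 19 bar
  two[15:26, 15:26] <- 1L   # 12 x 12 square
  sa2 <- shortest_axis(two, pixel_nm = 2)
  expect_length(sa2, 2)
  expect_equal(as.numeric(sa2[1]), 5 * 2, tolerance = 0.25)
  expect_equal(as.numeric(sa2[2]), 12 * 2, tolerance = 0.25)
  expect_error(shortest_axis(matrix(0L, 5, 5)), class = "cm_validation_error")
})
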