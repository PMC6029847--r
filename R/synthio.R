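## Seeded synthetic-data generators. Every generator draws under its
## protocol seed (caller RNG untouched), emits a ground-truth sidecar in
## attr(x, "truth"), and is exactly invertible by the matching analysis
## operation in the noiseless limit.

#' Synthesis protocol
#'
#' Bundles the reproducibility and discretisation settings shared by all
#' generators: the RNG seed, the additive noise level (in the units of the
#' generated signal), the number of samples per generated segment, and the
#' physical sampling step of the generated axis (nm for AFM data, seconds
#' for compression traces).
#'
#' @param seed Integer RNG seed. A fixed seed gives byte-identical output.
#' @param noise_sd Additive Gaussian noise SD, same units as the signal
#'   the generator produces (deflection nm, height nm, force uN, activity %).
#' @param n_points Samples per generated segment.
#' @param sampling_step Physical step of the generated axis.
#' @return An object of class `synth_protocol`.
#' @export
synth_protocol <- function(seed = 1L, noise_sd = 0, n_points = 500L,
                           sampling_step = 1) {
  cm_check(is_scalar_number(seed), "cm_validation_error", "seed must be a single number")
  cm_check(is_scalar_number(noise_sd) && noise_sd >= 0, "cm_validation_error",
           "noise_sd must be a single non-negative number")
  cm_check(is_scalar_number(n_points) && n_points >= 2, "cm_validation_error",
           "n_points must be >= 2")
  cm_check(is_scalar_number(sampling_step) && sampling_step > 0, "cm_validation_error",
           "sampling_step must be > 0")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 n_points = as.integer(n_points), sampling_step = sampling_step),
            class = "synth_protocol")
}

## Contact-law force (nN) at indentation depth delta (nm) for an indenter.
## Sphere: Hertz F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2).
## Cone:   Sneddon F = (2/pi) E/(1-nu^2) tan(theta) delta^2.
contact_force <- function(delta, modulus_kpa, indenter) {
  Estar <- modulus_kpa / (1 - indenter$nu^2)
  if (indenter$shape == "sphere") {
    .F_UNIT_NM_KPA * (4 / 3) * Estar * sqrt(indenter$radius_um * 1e3) *
      pmax(delta, 0)^1.5
  } else {
    .F_UNIT_NM_KPA * (2 / pi) * Estar * tan(indenter$half_angle_deg * pi / 180) *
      pmax(delta, 0)^2
  }
}

#' Simulate an AFM indentation force curve
#'
#' Generates one indentation cycle (approach + retract) of piezo displacement
#' and cantilever deflection for a sample of known elastic modulus. The
#' approach follows the indenter's contact law (Hertz sphere or Sneddon cone)
#' after a flat pre-contact baseline; the unloading branch is a power law
#' `P = alpha (h - h_f)^m` matched to the peak load.
#'
#' @param modulus_true Sample Young's modulus E in kPa (>= 0).
#' @param indenter An [indenter_spec()].
#' @param protocol A [synth_protocol()]; `noise_sd` is deflection noise in nm.
#' @param depth_max Maximum indentation depth in nm (> 0).
#' @param k Cantilever spring constant in N/m; defaults to the nominal
#'   constants of the microsphere (0.03) and conical (0.48) cantilevers.
#' @param unload Optional list overriding unloading parameters `m` (exponent,
#'   default 1.5 sphere / 2 cone), `h_f` (residual depth nm, default 0) and
#'   `alpha` (default set by continuity with the peak load).
#' @param pre_contact_frac Fraction of samples in the pre-contact baseline.
#' @return A [force_curve()] with a `truth` attribute recording the modulus,
#'   true contact index/offsets and unloading parameters.
#' @export
synth_indentation_curve <- function(modulus_true, indenter,
                                    protocol = synth_protocol(),
                                    depth_max = 1000, k = NULL,
                                    unload = list(), pre_contact_frac = 0.6) {
  cm_check(is_scalar_number(modulus_true) && modulus_true >= 0,
           "cm_validation_error", "modulus_true must be >= 0")
  cm_check(is_scalar_number(depth_max) && depth_max > 0,
           "cm_validation_error", "depth_max must be > 0")
  stopifnot(inherits(indenter, "indenter_spec"), inherits(protocol, "synth_protocol"))
  if (is.null(k)) k <- if (indenter$shape == "sphere") 0.03 else 0.48

  n_post <- max(10L, round(protocol$n_points * (1 - pre_contact_frac)))
  n_pre <- max(5L, protocol$n_points - n_post)

  ## Approach, parametrised by depth: z = z_c + delta + d (d = F/k; nN/(N/m) = nm)
  delta_app <- seq(0, depth_max, length.out = n_post)
  F_app <- contact_force(delta_app, modulus_true, indenter)
  d_app <- F_app / k
  z_c <- 0.5 * depth_max
  z_pre <- seq(0, z_c, length.out = n_pre + 1L)[-(n_pre + 1L)]
  z_app <- z_c + delta_app + d_app

  ## Unloading power law, continuous with the peak load
  m_unl <- if (!is.null(unload$m)) unload$m else if (indenter$shape == "sphere") 1.5 else 2
  h_f <- if (!is.null(unload$h_f)) unload$h_f else 0
  cm_check(h_f >= 0 && h_f < depth_max, "cm_validation_error",
           "unloading residual depth h_f must lie in [0, depth_max)")
  P_max <- contact_force(depth_max, modulus_true, indenter)
  alpha <- if (!is.null(unload$alpha)) unload$alpha else
    if (P_max > 0) P_max / (depth_max - h_f)^m_unl else 0
  delta_ret <- seq(depth_max, h_f, length.out = n_post)
  F_ret <- alpha * pmax(delta_ret - h_f, 0)^m_unl
  d_ret <- F_ret / k
  z_ret <- z_c + delta_ret + d_ret

  z <- c(z_pre, z_app, z_ret)
  d <- c(rep(0, n_pre), d_app, d_ret)
  segments <- rep(c("approach", "retract"), c(n_pre + n_post, n_post))
  d <- with_seed(protocol$seed, d + stats::rnorm(length(d), 0, protocol$noise_sd))

  curve <- force_curve(z = z, d = d, k = k, segments = segments,
                       medium = "hydrated",
                       meta = list(seed = protocol$seed, indenter = indenter))
  attr(curve, "truth") <- list(
    modulus_true = modulus_true, contact_index = n_pre + 1L, z_c = z_c, d_c = 0,
    depth_max = depth_max,
    unload = list(alpha = alpha, m = m_unl, h_f = h_f, P_max = P_max))
  curve
}

#' Simulate a collagen fibril height topography
#'
#' Builds a straight fibril ridge on a flat background: an elliptical
#' transverse cross-profile modulated axially by the D-band repeat
#' (raised sinusoid by default, a square-ish gap/overlap waveform on
#' request). Defaults follow the canonical type-I collagen axial repeat
#' of ~67 nm. The banding signal-to-noise ratio is
#' `band_depth / protocol$noise_sd`.
#'
#' @param period Axial repeat in nm; must exceed twice the pixel size.
#' @param peak_height Crest height of the fibril above background, nm.
#' @param length Axial extent of the grid, nm.
#' @param protocol A [synth_protocol()]; `sampling_step` is the pixel size in
#'   nm and `noise_sd` the additive height noise in nm.
#' @param band_depth Peak-to-trough depth of the axial banding, nm
#'   (0 switches banding off).
#' @param fibril_width Transverse extent of the ridge, nm.
#' @param grid_width Transverse extent of the grid, nm.
#' @param waveform `"sine"` (raised sinusoid) or `"square"` (saturated,
#'   gap/overlap-like).
#' @param medium Hydration state tag carried in the topography.
#' @return A [topography()] with `truth` attribute (period, band depth,
#'   crest row index, pixel size).
#' @export
synth_fibril_topography <- function(period = 67, peak_height = 100,
                                    length = 2010,
                                    protocol = synth_protocol(),
                                    band_depth = 8, fibril_width = 80,
                                    grid_width = 120,
                                    waveform = c("sine", "square"),
                                    medium = "hydrated") {
  waveform <- match.arg(waveform)
  stopifnot(inherits(protocol, "synth_protocol"))
  px <- protocol$sampling_step
  cm_check(period > 2 * px, "cm_aliasing_error",
           sprintf("period (%g nm) must exceed twice the pixel size (%g nm)", period, px))
  cm_check(peak_height > 0 && band_depth >= 0 && band_depth <= peak_height,
           "cm_validation_error", "need 0 <= band_depth <= peak_height")

  nx <- max(3L, round(length / px))
  ny <- max(3L, round(grid_width / px))
  x <- (seq_len(nx) - 1L) * px
  y <- (seq_len(ny) - 1L) * px

  w <- sin(2 * pi * x / period)
  if (waveform == "square") w <- tanh(3 * w) / tanh(3)
  crest <- peak_height - band_depth * (1 - w) / 2     # in [peak - band, peak]

  y0 <- stats::median(y)
  hw <- fibril_width / 2
  t_y <- ifelse(abs(y - y0) < hw, sqrt(pmax(1 - ((y - y0) / hw)^2, 0)), 0)

  height <- outer(t_y, crest)                          # ny x nx
  height <- with_seed(protocol$seed,
                      height + matrix(stats::rnorm(ny * nx, 0, protocol$noise_sd), ny, nx))
  topo <- topography(height, pixel_nm = px, medium = medium)
  attr(topo, "truth") <- list(period = period, band_depth = band_depth,
                              peak_height = peak_height,
                              crest_row = which.min(abs(y - y0)), pixel_nm = px)
  topo
}

#' Simulate a parallel-plate compression test
#'
#' Generates the five-cycle compression protocol applied to quasi-spherical
#' 3D cultures: each cycle ramps to 25% engineering strain over 15 s, holds
#' 2 s, recovers over 15 s and rests 2 s. Force follows the same
#' sphere-between-plates Hertz model the analysis inverts (total platen
#' displacement split equally between the two contacts), multiplied by a
#' smooth toe ramp that saturates below the 10--20% strain analysis window,
#' so the noiseless trace is exactly invertible there.
#'
#' @param E_true Young's modulus in kPa.
#' @param radii Named vector `c(horizontal =, vertical =)` in um.
#' @param protocol A [synth_protocol()]; `sampling_step` is the time step in
#'   seconds and `noise_sd` additive force noise in uN.
#' @param nu Poisson's ratio used in the forward model.
#' @param d0 Undeformed horizontal cross-sectional diameter, um.
#' @param n_cycles,phases Cycle count and phase durations (s).
#' @param strain_max Peak engineering strain per cycle.
#' @param toe_strain Strain at which the toe ramp saturates; kept below the
#'   linear-analysis window.
#' @param noise_rel Multiplicative force noise SD (fractional).
#' @return A [compression_test()] with `truth` attribute.
#' @export
synth_compression_test <- function(E_true, radii = c(horizontal = 400, vertical = 380),
                                   protocol = synth_protocol(sampling_step = 0.05),
                                   nu = 0.5, d0 = NULL, n_cycles = 5L,
                                   phases = c(compress = 15, hold = 2, recover = 15, rest = 2),
                                   strain_max = 0.25, toe_strain = 0.08,
                                   noise_rel = 0) {
  cm_check(is_scalar_number(E_true) && E_true >= 0, "cm_validation_error",
           "E_true must be >= 0")
  cm_check(all(radii > 0) && length(radii) == 2L, "cm_validation_error",
           "radii must be two positive numbers (horizontal, vertical)")
  stopifnot(inherits(protocol, "synth_protocol"))
  R_h <- unname(radii[["horizontal"]]); R_v <- unname(radii[["vertical"]])
  if (is.null(d0)) d0 <- 2 * R_h
  dt <- protocol$sampling_step
  cycle_T <- sum(phases)

  t_cycle <- seq(0, cycle_T, by = dt)
  disp_cycle <- vapply(t_cycle, function(tt) {
    if (tt <= phases[["compress"]]) tt / phases[["compress"]]
    else if (tt <= phases[["compress"]] + phases[["hold"]]) 1
    else if (tt <= phases[["compress"]] + phases[["hold"]] + phases[["recover"]])
      1 - (tt - phases[["compress"]] - phases[["hold"]]) / phases[["recover"]]
    else 0
  }, numeric(1)) * strain_max * d0

  time <- numeric(0); disp <- numeric(0)
  for (i in seq_len(n_cycles)) {
    keep <- if (i == 1L) seq_along(t_cycle) else -1L    # drop duplicated boundary
    time <- c(time, (i - 1L) * cycle_T + t_cycle[keep])
    disp <- c(disp, disp_cycle[keep])
  }

  sqrtR_eff <- (sqrt(R_h) + sqrt(R_v)) / 2
  eps <- disp / d0
  F_hertz <- (4 / 3) * (E_true / (1 - nu^2)) * sqrtR_eff * (disp / 2)^1.5 / 1e3  # uN
  s <- pmin(pmax(eps / toe_strain, 0), 1)
  toe <- s^2 * (3 - 2 * s)                              # smoothstep, 1 for eps >= toe_strain
  force <- F_hertz * toe
  force <- with_seed(protocol$seed, {
    f <- force * (1 + stats::rnorm(length(force), 0, noise_rel))
    f + stats::rnorm(length(f), 0, protocol$noise_sd)
  })

  test <- compression_test(time = time, force = force, displacement = disp,
                           R_h_um = R_h, R_v_um = R_v, d0_um = d0,
                           protocol = list(n_cycles = n_cycles, phases = phases,
                                           strain_max = strain_max,
                                           seed = protocol$seed))
  attr(test, "truth") <- list(E_true = E_true, nu = nu, toe_strain = toe_strain,
                              strain_max = strain_max, d0_um = d0)
  test
}

#' Cohort specification for the two-group synthetic study
#'
#' Defines donor counts, per-variable natural-scale means/SDs per group, the
#' target log-scale correlation between tissue stiffness and mature cross-link
#' density, and the MCAR missingness rate. Default effect structure mirrors
#' the fibrotic-lung study design: stiffness roughly doubled in the case
#' group, collagen concentration unchanged, immature and mature cross-link
#' densities increased, fibril diameters smaller and right-skewed, swelling
#' ratio reduced.
#'
#' @param n_control,n_case Donor counts (>= 0).
#' @param variables Named list; each element is
#'   `list(control = c(mean, sd), case = c(mean, sd))` on the natural scale.
#'   All variables are generated log-normally.
#' @param target_corr Desired log-scale correlation between
#'   `stiffness_kpa` and `mature_crosslinks` (|r| <= 1).
#' @param extra_corr Optional 3-column data.frame (`var1`, `var2`, `r`) of
#'   additional log-scale correlations; defaults couple stiffness weakly to
#'   immature cross-links (0.36) and immature to mature (0.45).
#' @param missing_rate MCAR per-cell missingness fraction in [0, 1);
#'   applied to measurement columns only, never to donor id or group.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 15L, n_case = 17L,
                        variables = NULL, target_corr = 0.72,
                        extra_corr = NULL, missing_rate = 0) {
  cm_check(n_control >= 0 && n_case >= 0, "cm_validation_error", "counts must be >= 0")
  cm_check(abs(target_corr) <= 1, "cm_validation_error", "|target_corr| must be <= 1")
  cm_check(missing_rate >= 0 && missing_rate < 1, "cm_validation_error",
           "missing_rate must lie in [0, 1)")
  if (is.null(variables)) {
    variables <- list(
      stiffness_kpa       = list(control = c(2.0, 0.8),   case = c(3.9, 1.8)),
      collagen_ug_mg      = list(control = c(65, 18),     case = c(68, 20)),
      immature_crosslinks = list(control = c(0.45, 0.15), case = c(0.85, 0.30)),
      mature_crosslinks   = list(control = c(0.12, 0.05), case = c(0.28, 0.11)),
      diameter_nm         = list(control = c(100, 25),    case = c(82, 28)),
      swelling_ratio      = list(control = c(1.6, 0.35),  case = c(1.25, 0.30)))
  }
  if (is.null(extra_corr)) {
    extra_corr <- data.frame(
      var1 = c("stiffness_kpa", "immature_crosslinks"),
      var2 = c("immature_crosslinks", "mature_crosslinks"),
      r = c(0.36, 0.45))
  }
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 variables = variables, target_corr = target_corr,
                 extra_corr = extra_corr, missing_rate = missing_rate),
            class = "cohort_spec")
}

## Log-normal parameters from natural-scale mean and sd.
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Simulate a two-group donor cohort
#'
#' Draws per-donor measurements from a multivariate log-normal: the named
#' variables are jointly Gaussian on the log scale with the requested
#' correlation structure (imposed via Cholesky factorisation), then
#' exponentiated. Missing cells are inserted completely at random at the
#' specified rate (measurement columns only).
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [synth_protocol()] (only the seed is used).
#' @return A data.frame (`donor`, `group`, one column per variable) with a
#'   `truth` attribute carrying the cohort specification and the log-scale
#'   correlation matrix.
#' @export
synth_cohort <- function(spec = cohort_spec(), protocol = synth_protocol()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(protocol, "synth_protocol"))
  vars <- names(spec$variables)
  p <- length(vars)
  C <- diag(p); dimnames(C) <- list(vars, vars)
  set_r <- function(a, b, r) {
    if (a %in% vars && b %in% vars) {
      C[a, b] <<- r; C[b, a] <<- r
    }
  }
  set_r("stiffness_kpa", "mature_crosslinks", spec$target_corr)
  if (!is.null(spec$extra_corr) && nrow(spec$extra_corr))
    for (i in seq_len(nrow(spec$extra_corr)))
      set_r(spec$extra_corr$var1[i], spec$extra_corr$var2[i], spec$extra_corr$r[i])
  L <- tryCatch(chol(C), error = function(e)
    cm_stop("cm_not_positive_definite",
            "requested correlation structure is not positive definite"))

  n <- spec$n_control + spec$n_case
  cm_check(n > 0, "cm_validation_error", "cohort has zero donors")
  group <- rep(c("control", "case"), c(spec$n_control, spec$n_case))

  with_seed(protocol$seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L     # rows ~ N(0, C)
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
    for (j in seq_len(p)) {
      for (g in c("control", "case")) {
        ms <- spec$variables[[j]][[g]]
        lp <- lnorm_params(ms[1], ms[2])
        rows <- group == g
        X[rows, j] <- exp(lp["mu"] + lp["sigma"] * Z[rows, j])
      }
    }
    if (spec$missing_rate > 0)
      X[matrix(stats::runif(n * p) < spec$missing_rate, n, p)] <- NA_real_
    out <- data.frame(donor = sprintf("D%02d", seq_len(n)), group = group, X,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(spec = spec, log_corr = C, seed = protocol$seed)
    out
  })
}

#' Simulate a 4PL enzyme-inhibition dose-response table
#'
#' Residual enzyme activity follows the four-parameter logistic
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` with additive Gaussian
#' noise; by construction activity at `dose == ic50` is the midpoint of
#' `top` and `bottom`.
#'
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill slope.
#' @param doses Dose levels, uM (> 0).
#' @param protocol A [synth_protocol()]; `noise_sd` in activity % units.
#' @param top,bottom Plateaus in % activity.
#' @return A data.frame (`dose_um`, `activity_pct`) with `truth` attribute.
#' @export
synth_dose_response <- function(ic50, hill = 1,
                                doses = 10^seq(-4, 1, by = 0.5),
                                protocol = synth_protocol(),
                                top = 100, bottom = 0) {
  cm_check(is_scalar_number(ic50) && ic50 > 0, "cm_validation_error", "ic50 must be > 0")
  cm_check(all(doses > 0), "cm_validation_error", "doses must be > 0")
  act <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
  act <- with_seed(protocol$seed, act + stats::rnorm(length(act), 0, protocol$noise_sd))
  out <- data.frame(dose_um = doses, activity_pct = act)
  attr(out, "truth") <- list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                             seed = protocol$seed)
  out
}

#' Simulate a dose-ranging 3D-culture stiffness study
#'
#' Emulates the in vitro inhibitor design: spheroid cultures from several
#' donors, replicated, treated across inhibitor doses (vehicle = dose 0),
#' with Young's modulus declining along a saturating dose-inhibition curve.
#' Donor and replicate variation are log-normal, so the randomized-block
#' analysis on the log scale is exact.
#'
#' @param protocol A [synth_protocol()] (seed only).
#' @param doses Dose levels in uM; 0 is the vehicle control.
#' @param n_donors,n_replicates Design size.
#' @param E0 Vehicle-level Young's modulus, kPa.
#' @param emax Maximal fractional stiffness reduction at saturating dose.
#' @param ed50,hill Dose-inhibition midpoint (uM) and slope.
#' @param donor_cv,rep_cv Log-normal coefficients of variation for donor and
#'   replicate effects.
#' @return Long data.frame (`donor`, `replicate`, `dose_um`,
#'   `youngs_modulus_kpa`) with `truth` attribute.
#' @export
synth_invitro_study <- function(protocol = synth_protocol(),
                                doses = c(0, 0.01, 0.1, 1, 10),
                                n_donors = 3L, n_replicates = 2L,
                                E0 = 5, emax = 0.5, ed50 = 0.05, hill = 1,
                                donor_cv = 0.3, rep_cv = 0.08) {
  cm_check(0 %in% doses, "cm_validation_error", "doses must include vehicle (0)")
  inhib <- ifelse(doses > 0, emax * doses^hill / (doses^hill + ed50^hill), 0)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose_um = doses, donor = sprintf("F%d", seq_len(n_donors)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(protocol$seed, {
    donor_eff <- stats::rnorm(n_donors, 0, sqrt(log(1 + donor_cv^2)))
    names(donor_eff) <- sprintf("F%d", seq_len(n_donors))
    mu <- log(E0) + donor_eff[grid$donor] +
      log(1 - inhib[match(grid$dose_um, doses)])
    grid$youngs_modulus_kpa <-
      exp(mu + stats::rnorm(nrow(grid), 0, sqrt(log(1 + rep_cv^2))))
    out <- grid[, c("donor", "replicate", "dose_um", "youngs_modulus_kpa")]
    attr(out, "truth") <- list(E0 = E0, emax = emax, ed50 = ed50, hill = hill,
                               doses = doses, seed = protocol$seed)
    out
  })
}
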