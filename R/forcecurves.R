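## AFM force-curve analysis: contact detection, force-indentation
## conversion, Hertz sphere and Oliver-Pharr modulus estimation,
## per-fibril/per-donor aggregation and elastograph statistics.
## Internal units: nm (lengths), nN (forces), kPa (moduli).

#' Force curve container
#'
#' One indentation cycle: piezo displacement `z` (nm), cantilever deflection
#' `d` (nm), spring constant `k` (N/m) and a per-sample segment label.
#' Force in nN is `k * d` (1 nN / (N/m) = 1 nm of deflection).
#'
#' @param z,d Equal-length numeric vectors, nm.
#' @param k Spring constant, N/m (> 0).
#' @param segments Character vector of labels in
#'   `{"approach", "dwell", "retract"}`, one per sample.
#' @param medium `"hydrated"` or `"dry"`.
#' @param meta Optional metadata list.
#' @export
force_curve <- function(z, d, k, segments = rep("approach", length(z)),
                        medium = "hydrated", meta = list()) {
  cm_check(length(z) == length(d) && length(z) >= 2, "cm_validation_error",
           "z and d must be equal-length vectors of length >= 2")
  cm_check(is_scalar_number(k) && k > 0, "cm_validation_error",
           "spring constant k must be a single positive number")
  cm_check(length(segments) == length(z) &&
             all(segments %in% c("approach", "dwell", "retract")),
           "cm_validation_error", "segments must label every sample")
  structure(list(z = as.numeric(z), d = as.numeric(d), k = k,
                 segments = segments, medium = medium, meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples (%s), k = %g N/m, %s\n",
              length(x$z), paste(names(table(x$segments)), collapse = "/"),
              x$k, x$medium))
  invisible(x)
}

#' Indenter geometry
#'
#' Spherical (microindentation) or conical (nanoindentation) tip plus the
#' sample Poisson ratio. Defaults mirror the study instruments: a 15 um
#' diameter microsphere (radius 7.5 um) and a conical tip of 7--10 nm
#' radius (midpoint 8.5 nm used for the blunted-cone area function).
#'
#' @param shape `"sphere"` or `"cone"`.
#' @param radius_um Sphere radius, um (sphere only).
#' @param half_angle_deg Cone half-angle from the axis, degrees (cone only).
#' @param tip_radius_nm Cone apex radius, nm (blunted-cone area function).
#' @param nu Sample Poisson ratio in [0, 0.5] (0.5 = incompressible).
#' @export
indenter_spec <- function(shape = c("sphere", "cone"), radius_um = 7.5,
                          half_angle_deg = 20, tip_radius_nm = 8.5, nu = 0.5) {
  shape <- match.arg(shape)
  if (shape == "sphere")
    cm_check(radius_um > 0, "cm_validation_error", "sphere radius must be > 0")
  else
    cm_check(half_angle_deg > 0 && half_angle_deg < 90, "cm_validation_error",
             "cone half-angle must lie in (0, 90) degrees")
  cm_check(nu >= 0 && nu <= 0.5, "cm_validation_error", "nu must lie in [0, 0.5]")
  structure(list(shape = shape, radius_um = radius_um,
                 half_angle_deg = half_angle_deg,
                 tip_radius_nm = tip_radius_nm, nu = nu),
            class = "indenter_spec")
}

modulus_result <- function(modulus, model, contact_index = NA_integer_,
                           fit_window = c(NA_real_, NA_real_),
                           residual_norm = NA_real_, n_points = NA_integer_,
                           extra = list()) {
  cm_check(is.na(modulus) || modulus >= 0, "cm_validation_error",
           "modulus must be >= 0")
  structure(c(list(modulus = modulus, model = model,
                   contact_index = contact_index, fit_window = fit_window,
                   residual_norm = residual_norm, n_points = n_points),
              extra),
            class = "modulus_result")
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("<modulus_result> %s: %.4g kPa (n = %d, resid = %.3g)\n",
              x$model, x$modulus, x$n_points, x$residual_norm))
  invisible(x)
}

#' Detect the tip-sample contact point on the approach segment
#'
#' Fits a robust line to the first half of the approach deflection (the
#' pre-contact baseline), then takes the first sample of the last run where
#' the baseline-corrected deflection exceeds `threshold_mads` times the
#' robust residual scale and stays above it; the index is then walked back
#' to the first sample above zero. Baseline offsets `z_c`, `d_c` at contact
#' are returned for force-indentation conversion.
#'
#' @param curve A [force_curve()].
#' @param baseline_frac Fraction of the approach used for the baseline fit.
#' @param threshold_mads Detection threshold in units of residual MAD.
#' @return List `contact_index` (into the approach segment), `z_c`, `d_c`,
#'   `baseline` (intercept/slope), `noise_mad`.
#' @export
detect_contact_point <- function(curve, baseline_frac = 0.5, threshold_mads = 5) {
  stopifnot(inherits(curve, "force_curve"))
  app <- which(curve$segments == "approach")
  cm_check(length(app) >= 10, "cm_insufficient_data",
           "approach segment with >= 10 samples required")
  z <- curve$z[app]; d <- curve$d[app]
  nb <- max(5L, floor(length(app) * baseline_frac))
  fit <- MASS::rlm(d[seq_len(nb)] ~ z[seq_len(nb)], maxit = 50)
  co <- stats::coef(fit)
  resid <- d[seq_len(nb)] - (co[1] + co[2] * z[seq_len(nb)])
  noise <- max(stats::mad(resid), 1e-12)
  excess <- d - (co[1] + co[2] * z)
  above <- excess > threshold_mads * noise
  if (!any(above))
    cm_stop("cm_no_contact", "no deflection exceeds the contact threshold")
  ## last run of consecutive above-threshold samples reaching the curve end
  idx <- length(above)
  while (idx > 1L && above[idx - 1L]) idx <- idx - 1L
  if (!above[length(above)] || idx == length(above))
    idx <- which(above)[1]
  ## walk back to the last sample at or below the noise level
  while (idx > 1L && excess[idx - 1L] > noise) idx <- idx - 1L
  if (idx > 1L) idx <- idx - 1L
  list(contact_index = app[idx], z_c = z[idx],
       d_c = co[1] + co[2] * z[idx],
       baseline = unname(co), noise_mad = noise)
}

#' Convert a force curve to force-indentation data
#'
#' With spring constant `k` and contact offsets `(z_c, d_c)`, force is
#' `F = k (d - d_c)` (nN) and indentation `delta = (z - z_c) - (d - d_c)`
#' (nm): the piezo travel beyond contact minus the cantilever bending.
#'
#' @param curve A [force_curve()].
#' @param contact Result of [detect_contact_point()]; detected if `NULL`.
#' @param segment Which segment to convert.
#' @return List with `delta` (nm, >= 0 range), `F` (nN) and the contact used.
#' @export
to_force_indentation <- function(curve, contact = NULL,
                                 segment = c("approach", "retract")) {
  stopifnot(inherits(curve, "force_curve"))
  segment <- match.arg(segment)
  cm_check(is_scalar_number(curve$k) && curve$k > 0, "cm_configuration_error",
           "spring constant k is not set")
  if (is.null(contact)) contact <- detect_contact_point(curve)
  sel <- which(curve$segments == segment)
  cm_check(length(sel) > 0, "cm_validation_error",
           sprintf("curve has no %s segment", segment))
  d_corr <- curve$d[sel] - contact$d_c
  delta <- (curve$z[sel] - contact$z_c) - d_corr
  keep <- (curve$z[sel] - contact$z_c) >= 0
  list(delta = delta[keep], F = curve$k * d_corr[keep], contact = contact)
}

#' Fit the Hertz sphere contact model
#'
#' Least-squares fit of `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`
#' to force-indentation data from a spherical microindenter, linear in E.
#'
#' @param delta Indentation depths, nm.
#' @param F Forces, nN.
#' @param indenter An [indenter_spec()] with `shape = "sphere"`.
#' @return A `modulus_result` with the sample Young's modulus E in kPa.
#' @export
fit_hertz_sphere <- function(delta, F, indenter = indenter_spec("sphere")) {
  stopifnot(inherits(indenter, "indenter_spec"))
  cm_check(indenter$shape == "sphere", "cm_validation_error",
           "Hertz sphere fit needs a spherical indenter")
  keep <- is.finite(delta) & is.finite(F) & delta > 0
  cm_check(sum(keep) >= 10, "cm_insufficient_data",
           "need >= 10 points with positive indentation")
  x <- delta[keep]^1.5; y <- F[keep]
  geom <- .F_UNIT_NM_KPA * (4 / 3) * sqrt(indenter$radius_um * 1e3) /
    (1 - indenter$nu^2)
  slope <- sum(x * y) / sum(x * x)
  E <- max(slope / geom, 0)
  rn <- sqrt(sum((y - slope * x)^2))
  modulus_result(E, "hertz_sphere", fit_window = range(delta[keep]),
                 residual_norm = rn, n_points = sum(keep),
                 extra = list(nu = indenter$nu, radius_um = indenter$radius_um))
}

## Contact radius (nm) of a sphero-conical (blunted) tip at contact depth
## h_c: spherical cap of radius R_t up to the tangency depth R_t (1 - sin
## theta), then the tangent cone a = tan(theta) (h_c + R_t (1/sin(theta) - 1)).
blunted_cone_radius <- function(h_c, half_angle_deg, tip_radius_nm) {
  th <- half_angle_deg * pi / 180
  h_t <- tip_radius_nm * (1 - sin(th))
  ifelse(h_c <= h_t,
         sqrt(pmax(2 * tip_radius_nm * h_c - h_c^2, 0)),
         tan(th) * (h_c + tip_radius_nm * (1 / sin(th) - 1)))
}

#' Oliver-Pharr analysis of an unloading curve
#'
#' Fits the power law `P = alpha (h - h_f)^m` to the upper portion of the
#' unloading branch, evaluates the unloading stiffness `S = dP/dh` at
#' `h_max`, the contact depth `h_c = h_max - eps P_max / S`, and the
#' indentation (plane-strain) modulus
#' `M = sqrt(pi) S / (2 beta sqrt(A(h_c)))` using the blunted-cone contact
#' area `A(h_c)`.
#'
#' @param curve A [force_curve()] with approach and retract segments.
#' @param indenter An [indenter_spec()] (cone for the default area function).
#' @param eps Oliver-Pharr intercept factor (0.75).
#' @param beta Geometry correction factor (1).
#' @param fit_fraction Load window of the unloading fit as fractions of
#'   `P_max` (default top 75--95%).
#' @param contact Optional precomputed contact point.
#' @return A `modulus_result` with `modulus` = M in kPa and extras
#'   `S_nN_per_nm`, `h_max`, `h_f`, `h_c`, `alpha`, `m`, `area_nm2`,
#'   `m_flagged` (`TRUE` when m falls outside [1, 3]).
#' @export
fit_oliver_pharr <- function(curve, indenter = indenter_spec("cone"),
                             eps = 0.75, beta = 1,
                             fit_fraction = c(0.75, 0.95), contact = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  n_ret <- sum(curve$segments == "retract")
  cm_check(n_ret >= 10, "cm_insufficient_data",
           sprintf("unloading segment has %d points; >= 10 required", n_ret))
  fi <- to_force_indentation(curve, contact = contact, segment = "retract")
  h <- fi$delta; P <- fi$F
  ord <- order(h)
  h <- h[ord]; P <- P[ord]
  P_max <- max(P); h_max <- h[which.max(P)]
  cm_check(P_max > 0, "cm_fit_error", "unloading branch carries no load")

  ## monotonicity check: P must decrease with decreasing h beyond noise
  noise <- stats::mad(diff(P))
  viol <- mean(diff(P) < -max(6 * noise, 1e-9 * P_max))
  if (viol > 0.1)
    cm_stop("cm_fit_error", "unloading branch is non-monotone beyond noise tolerance")

  win <- which(P >= fit_fraction[1] * P_max & P <= fit_fraction[2] * P_max)
  cm_check(length(win) >= 5, "cm_insufficient_data",
           "fewer than 5 unloading points in the fit window")
  hw <- h[win]; Pw <- P[win]

  cm_check(all(Pw > 0), "cm_fit_error", "non-positive loads in the fit window")
  ## Profiled power-law fit: for fixed h_f the model is log-linear in
  ## (log alpha, m); h_f is found by 1-D minimisation of the RSS profile.
  ## Far better conditioned than a joint 3-parameter descent on the narrow
  ## upper-unloading window.
  h_f_max <- min(hw) * 0.9999
  rss_at <- function(h_f) {
    lx <- log(hw - h_f)
    fit <- stats::lm.fit(cbind(1, lx), log(Pw))
    sum((Pw - exp(fit$fitted.values))^2)
  }
  grid <- seq(-0.5 * h_max, h_f_max, length.out = 101L)
  r <- vapply(grid, rss_at, numeric(1))
  i0 <- which.min(r)
  lo <- grid[max(i0 - 1L, 1L)]; hi <- grid[min(i0 + 1L, length(grid))]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10 * max(h_max, 1))
  h_f <- if (opt$objective < r[i0]) opt$minimum else grid[i0]
  co <- unname(stats::lm.fit(cbind(1, log(hw - h_f)), log(Pw))$coefficients)
  alpha <- exp(co[1]); m <- co[2]; h_f <- unname(h_f)
  resid_w <- Pw - alpha * (hw - h_f)^m
  S <- alpha * m * (h_max - h_f)^(m - 1)          # nN/nm
  h_c <- h_max - eps * P_max / S
  a_c <- blunted_cone_radius(max(h_c, 0), indenter$half_angle_deg,
                             indenter$tip_radius_nm)
  A <- pi * a_c^2                                  # nm^2
  cm_check(A > 0, "cm_fit_error", "contact area is zero")
  ## units: S [nN/nm] / sqrt(A) [nm] = nN/nm^2 = 1e-9 N / 1e-18 m^2 = 1e9 Pa,
  ## so the numeric value converts to kPa with a factor 1e6.
  M <- sqrt(pi) * S / (2 * beta * sqrt(A)) * 1e6
  rn <- sqrt(sum(resid_w^2))
  modulus_result(max(M, 0), "oliver_pharr",
                 fit_window = range(hw), residual_norm = rn,
                 n_points = length(win),
                 extra = list(S_nN_per_nm = S, h_max = h_max, h_f = h_f,
                              h_c = h_c, alpha = alpha, m = m,
                              area_nm2 = A, eps = eps, beta = beta,
                              m_flagged = (m < 1 || m > 3)))
}

#' Aggregate modulus results
#'
#' Mean, standard error and count over a set of modulus estimates, with a
#' below-protocol flag when the count falls under the study minima
#' (30 curves per fibril, 80 per donor).
#'
#' @param results List of `modulus_result` objects or a numeric vector of
#'   moduli in kPa.
#' @param level `"fibril"` or `"donor"` (sets the protocol minimum).
#' @return List `mean`, `sem`, `n`, `level`, `below_protocol`.
#' @export
aggregate_modulus <- function(results, level = c("fibril", "donor")) {
  level <- match.arg(level)
  vals <- if (is.numeric(results)) results
  else vapply(results, function(r) r$modulus, numeric(1))
  cm_check(length(vals) > 0, "cm_validation_error", "no modulus results supplied")
  minimum <- c(fibril = 30L, donor = 80L)[[level]]
  list(mean = mean(vals), sem = if (length(vals) > 1) sem(vals) else 0,
       n = length(vals), level = level,
       below_protocol = length(vals) < minimum)
}

#' Elastograph (stiffness map) container
#'
#' @param x,y Grid positions, um.
#' @param modulus Moduli, kPa (>= 0), one per position.
#' @param meta Optional donor/site identifiers.
#' @export
elasto_map <- function(x, y, modulus, meta = list()) {
  cm_check(length(x) == length(y) && length(x) == length(modulus),
           "cm_validation_error", "x, y, modulus must have equal length")
  cm_check(!anyDuplicated(paste(x, y)), "cm_validation_error",
           "grid positions must be unique")
  cm_check(all(modulus >= 0), "cm_validation_error", "moduli must be >= 0")
  structure(list(x = x, y = y, modulus = modulus, meta = meta),
            class = "elasto_map")
}

#' Elastograph summary statistics
#'
#' Mean modulus and coefficient of variation
#' `CV = 100 * sample SD / mean` (%), plus the map rendered to a dense grid
#' matrix for export.
#'
#' @param map An [elasto_map()].
#' @return List `mean_kpa`, `cv_pct`, `n`, `grid` (matrix with unique x/y as
#'   dimnames, NA where unsampled).
#' @export
elastograph_stats <- function(map) {
  stopifnot(inherits(map, "elasto_map"))
  cm_check(length(map$modulus) >= 2, "cm_insufficient_data",
           "need >= 2 map points")
  m <- mean(map$modulus)
  cm_check(m > 0, "cm_undefined_error", "CV undefined for non-positive mean")
  xs <- sort(unique(map$x)); ys <- sort(unique(map$y))
  grid <- matrix(NA_real_, length(ys), length(xs),
                 dimnames = list(as.character(ys), as.character(xs)))
  grid[cbind(match(map$y, ys), match(map$x, xs))] <- map$modulus
  list(mean_kpa = m, cv_pct = 100 * stats::sd(map$modulus) / m,
       n = length(map$modulus), grid = grid)
}
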