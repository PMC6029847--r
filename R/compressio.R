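## Parallel-plate compression analysis of quasi-spherical 3D cultures:
## cycle segmentation, engineering stress/strain, linear-window selection
## and Young's modulus by the sphere-between-plates Hertz model.
## Units: s, uN, um in; stress Pa, modulus kPa out.

#' Compression test container
#'
#' @param time Time, s (monotone non-decreasing).
#' @param force Plate force, uN.
#' @param displacement Total platen displacement, um.
#' @param R_h_um,R_v_um Horizontal and vertical sample radii, um.
#' @param d0_um Horizontal cross-sectional diameter immediately before the
#'   test, um.
#' @param protocol List describing the cycle protocol; defaults to five
#'   cycles of 15 s compression / 2 s hold / 15 s recovery / 2 s rest at
#'   25% peak engineering strain.
#' @export
compression_test <- function(time, force, displacement, R_h_um, R_v_um, d0_um,
                             protocol = list(n_cycles = 5L,
                                             phases = c(compress = 15, hold = 2,
                                                        recover = 15, rest = 2),
                                             strain_max = 0.25)) {
  cm_check(length(time) == length(force) && length(time) == length(displacement),
           "cm_validation_error", "time, force, displacement must align")
  cm_check(all(diff(time) >= 0), "cm_validation_error", "time must be monotone")
  cm_check(R_h_um > 0 && R_v_um > 0 && d0_um > 0, "cm_validation_error",
           "radii and d0 must be > 0")
  structure(list(time = time, force = force, displacement = displacement,
                 R_h_um = R_h_um, R_v_um = R_v_um, d0_um = d0_um,
                 protocol = protocol),
            class = "compression_test")
}

#' @export
print.compression_test <- function(x, ...) {
  cat(sprintf("<compression_test> %d samples over %.1f s, R = %g/%g um, d0 = %g um\n",
              length(x$time), diff(range(x$time)), x$R_h_um, x$R_v_um, x$d0_um))
  invisible(x)
}

#' Segment a compression trace into protocol cycles
#'
#' Cycles are located as contiguous runs of non-zero displacement
#' (compress + hold + recover) separated by rest phases; phase labels are
#' assigned from the protocol durations, measured from each run's start.
#' The analysis cycle is the fifth (preconditioning stabilises by then).
#'
#' @param test A [compression_test()].
#' @param disp_tol Displacement threshold as a fraction of peak displacement.
#' @return List of cycles; each has `indices`, `time`, `force`,
#'   `displacement`, `phase` (per-sample label) and `peak_strain`.
#' @export
segment_cycles <- function(test, disp_tol = 1e-6) {
  stopifnot(inherits(test, "compression_test"))
  ph <- test$protocol$phases
  n_req <- test$protocol$n_cycles %||% 5L
  thr <- disp_tol * max(test$displacement)
  active <- test$displacement > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) < n_req)
    cm_stop("cm_cycle_error",
            sprintf("detected %d cycles; %d required", length(runs), n_req),
            n_detected = length(runs))
  lapply(seq_along(runs), function(ci) {
    ## include the bracketing zero-displacement samples so the ramp starts at 0
    i0 <- max(starts[runs[ci]] - 1L, 1L)
    i1 <- min(ends[runs[ci]] + 1L, length(test$time))
    idx <- i0:i1
    trel <- test$time[idx] - test$time[idx[1]]
    phase <- cut(trel,
                 breaks = c(-Inf, ph[["compress"]],
                            ph[["compress"]] + ph[["hold"]],
                            ph[["compress"]] + ph[["hold"]] + ph[["recover"]], Inf),
                 labels = c("compress", "hold", "recover", "rest"))
    list(indices = idx, time = test$time[idx], force = test$force[idx],
         displacement = test$displacement[idx], phase = as.character(phase),
         peak_strain = max(test$displacement[idx]) / test$d0_um)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Engineering stress and strain of a cycle
#'
#' `sigma = F / (pi d0^2 / 4)` (Pa) and `eps = displacement / d0`, using the
#' undeformed horizontal cross-sectional diameter.
#'
#' @param cycle One cycle from [segment_cycles()].
#' @param d0_um Undeformed horizontal diameter, um (> 0).
#' @return A `stress_strain`: data.frame with `stress_pa`, `strain`,
#'   `phase`, `time`.
#' @export
engineering_stress_strain <- function(cycle, d0_um) {
  cm_check(is_scalar_number(d0_um) && d0_um > 0, "cm_validation_error",
           "d0 must be > 0")
  ## uN / um^2 = 1e-6 N / 1e-12 m^2 = 1e6 Pa
  stress <- cycle$force / (pi * d0_um^2 / 4) * 1e6
  ss <- data.frame(stress_pa = stress, strain = cycle$displacement / d0_um,
                   phase = cycle$phase, time = cycle$time)
  class(ss) <- c("stress_strain", "data.frame")
  ss
}

#' Select the linear analysis window of a stress-strain curve
#'
#' The toe region (slowly rising stress at small strain) is excluded by
#' construction: the window is all compression-phase samples with
#' engineering strain in `bounds` (default 10--20%).
#'
#' @param ss A `stress_strain` from [engineering_stress_strain()].
#' @param bounds Strain bounds of the linear region.
#' @return Integer row indices into `ss`.
#' @export
select_linear_region <- function(ss, bounds = c(0.10, 0.20)) {
  stopifnot(inherits(ss, "stress_strain"))
  comp <- ss$phase == "compress"
  cm_check(max(ss$strain[comp]) >= bounds[2], "cm_insufficient_data",
           sprintf("maximum compression strain %.3f below the window upper bound %.2f",
                   max(ss$strain[comp]), bounds[2]))
  which(comp & ss$strain >= bounds[1] & ss$strain <= bounds[2])
}

#' Young's modulus by the sphere-between-plates Hertz model
#'
#' For each sample in the linear window, E is inverted from
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R_axis) (delta/2)^(3/2)` -- the total
#' platen displacement splits equally between the two plate contacts --
#' separately for the horizontal and vertical radii. E per axis is the mean
#' over the window (optionally a single 3/2-power-law fit), and the
#' reported E is the mean of the two axis values.
#'
#' @param test A [compression_test()], or a single cycle from
#'   [segment_cycles()] together with explicit radii/`d0_um`.
#' @param nu Poisson's ratio (0.5 = incompressible, the default).
#' @param cycle Which cycle to analyse (default 5).
#' @param window Strain bounds of the linear region.
#' @param method `"pointwise"` (mean of per-sample inversions) or
#'   `"powerfit"` (least-squares 3/2-power amplitude over the window).
#' @return A `youngs_modulus_result`: list `E_kpa`, `E_axis_kpa` (named h/v),
#'   `nu`, `window`, `n_points`, `negative_flagged`, `stabilisation`
#'   (relative peak-force drift of cycles 4 to 5 when a full test is given).
#' @export
young_modulus_sphere <- function(test, nu = 0.5, cycle = 5L,
                                 window = c(0.10, 0.20),
                                 method = c("pointwise", "powerfit")) {
  method <- match.arg(method)
  stopifnot(inherits(test, "compression_test"))
  cycles <- segment_cycles(test)
  cyc <- cycles[[cycle]]
  ss <- engineering_stress_strain(cyc, test$d0_um)
  win <- select_linear_region(ss, bounds = window)
  cm_check(length(win) >= 2, "cm_insufficient_data", "empty linear window")

  delta <- cyc$displacement[win]      # um
  Fw <- cyc$force[win]                # uN
  ## E[kPa] = 1e3 * F[uN] (1-nu^2) / ((4/3) sqrt(R[um]) (delta[um]/2)^1.5)
  invert <- function(R) {
    geom <- (4 / 3) * sqrt(R) * (delta / 2)^1.5 / (1 - nu^2)
    if (method == "pointwise") mean(1e3 * Fw / geom)
    else 1e3 * sum(Fw * geom) / sum(geom^2)
  }
  E_axis <- c(h = invert(test$R_h_um), v = invert(test$R_v_um))
  neg <- any(E_axis < 0) || any(Fw < 0)

  peak_forces <- vapply(cycles, function(cc) max(cc$force), numeric(1))
  stab <- if (length(peak_forces) >= 2)
    abs(diff(utils::tail(peak_forces, 2))) / utils::tail(peak_forces, 1)
  else NA_real_

  structure(list(E_kpa = mean(E_axis), E_axis_kpa = E_axis, nu = nu,
                 window = window, n_points = length(win),
                 negative_flagged = neg, method = method,
                 stabilisation = stab, peak_forces = peak_forces),
            class = "youngs_modulus_result")
}

#' @export
print.youngs_modulus_result <- function(x, ...) {
  cat(sprintf("<youngs_modulus_result> E = %.4g kPa (h %.4g / v %.4g), nu = %g, window %g-%g strain, n = %d\n",
              x$E_kpa, x$E_axis_kpa[["h"]], x$E_axis_kpa[["v"]], x$nu,
              x$window[1], x$window[2], x$n_points))
  invisible(x)
}
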