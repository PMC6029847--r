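## Independent oracles used across tests; deliberately brute-force and
## separate from the implementation paths they check.

## Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    rk <- rank(pooled)
    sum(rk[ix]) - m * (m + 1) / 2
  }
  u_obs <- u_stat(seq_len(m))
  combs <- utils::combn(m + n, m)
  u_null <- apply(combs, 2, u_stat)
  u_lo <- min(u_obs, m * n - u_obs)
  mean(u_null <= u_lo) + mean(u_null >= m * n - u_lo)
}

## Brute-force minimum caliper width of a point set over rotations.
brute_caliper <- function(pts, n_angles = 360) {
  angles <- seq(0, pi, length.out = n_angles)
  min(vapply(angles, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    diff(range(proj))
  }, numeric(1)))
}

## Long-axis polyline along the crest row of a synthetic fibril topography.
crest_polyline <- function(topo) {
  row <- attr(topo, "truth")$crest_row
  cbind(x = c(1, ncol(topo$height)), y = c(row, row))
}

## Closed-form Hertz sphere force in nN (E kPa, R um, delta nm).
hertz_force_nN <- function(E_kpa, nu, R_um, delta_nm) {
  (4 / 3) * (E_kpa * 1e3 / (1 - nu^2)) * sqrt(R_um * 1e-6) *
    (delta_nm * 1e-9)^1.5 * 1e9
}
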