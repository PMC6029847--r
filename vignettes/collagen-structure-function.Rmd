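---
title: "Multiscale collagen structure-function analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale collagen structure-function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagenmech)
```

## The scientific problem

In fibrotic lung disease the extracellular matrix stiffens, and stiffened
matrix itself drives further fibrosis through mechanosensitive signalling.
The analyses in this package address the question of *where* that stiffness
comes from: not from more collagen, but from how collagen is post-
translationally cross-linked and assembled, from the single fibril
(nanometre) scale up to tissue sections and 3D cultures. The package
implements the full measurement chain:

* **tissue microindentation** -- AFM with a colloidal (15 um diameter)
  sphere, analysed with the Hertz contact model;
* **single-fibril nanoindentation** -- sharp conical AFM tip, analysed
  with the Oliver-Pharr method;
* **fibril morphometry** -- D-period, height-based diameter, swelling
  ratio and population statistics from height topography, plus TEM-style
  shortest-axis measurement;
* **spheroid compression** -- parallel-plate testing of quasi-spherical 3D
  cultures, Young's modulus by a sphere-between-plates Hertz model;
* **biochemical normalisation** -- hydroxyproline to collagen, cross-link
  densities (DHLNL, HLNL, PYD, DPD) and ratios, solubility fractions,
  ddCt expression;
* **inference** -- the two-group and multi-group tests used throughout,
  and a missing-data multivariate-normal correlation estimated by EM.

Every analysis operation has a matching seeded generator in the synthetic-
data module, with ground truth attached, so the whole chain is testable by
round trip.

## Contact mechanics

### Units

Lengths in nm, forces in nN, moduli in kPa throughout the AFM layer
(conversion factor: kPa x nm^2 = 1e-6 nN); compression uses um, uN, kPa.
Conversions happen only at I/O boundaries.

### Hertz sphere (microindentation)

For a rigid sphere of radius $R$ on an elastic half-space,
$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$
linear in $E$, so `fit_hertz_sphere()` solves a one-parameter least-squares
problem in $\delta^{3/2}$. The sample Poisson ratio defaults to 0.5
(incompressible, hydrated tissue). The reported modulus is the sample
Young's modulus at the stated $\nu$; the plane-strain (reduced) modulus is
recoverable as $E/(1-\nu^2)$.

### Contact detection

The contact point is not observable directly; the estimator fits a robust
line (`MASS::rlm`) to the first 50% of the approach deflection, takes the
residual MAD as the noise scale, finds the last sustained excursion above
5 MAD, and walks back to the last sample at or below one MAD (minus one
sample, so the noiseless case lands exactly on the true contact). The
5-MAD threshold and 50% baseline window are noise-adaptive conventions,
exposed as arguments. Generators default to 60% free travel so the
baseline window never overlaps contact. Fitted moduli are invariant to
piezo translation and constant deflection offsets (tested).

### Oliver-Pharr (nanoindentation)

The unloading branch is modelled as $P = \alpha (h - h_f)^m$. Because
$\alpha$, $m$ and $h_f$ are strongly correlated on the narrow upper-
unloading window, the fit is *profiled*: for fixed $h_f$ the model is
linear in $(\log\alpha, m)$, and $h_f$ is found by 1-D minimisation of the
residual sum of squares (grid then `optimize`). This is far better
conditioned than a joint 3-parameter descent and is exact on noiseless
power-law data. The fit window is the part of the unloading branch
carrying 75--95% of the peak load; $m$ outside $[1, 3]$ is flagged, not
rejected.

Unloading stiffness, contact depth and indentation modulus follow the
standard sequence
$$S = \alpha m (h_{max} - h_f)^{m-1}, \qquad
  h_c = h_{max} - \varepsilon P_{max}/S, \qquad
  M = \frac{\sqrt{\pi}\,S}{2\beta\sqrt{A(h_c)}},$$
with $\varepsilon = 0.75$ and $\beta = 1$ (canonical values; both exposed
as arguments). $M$ is reported as the plane-strain modulus with the tip
treated as rigid (no tip-compliance correction).

The contact area uses an exact sphero-conical tip: a spherical cap of
radius $R_t$ (default 8.5 nm, the midpoint of the 7--10 nm tip-radius
range of the instrument class emulated) meeting its tangent cone of
half-angle $\theta$ at depth $R_t(1-\sin\theta)$, beyond which
$a = \tan\theta\,(h_c + R_t(1/\sin\theta - 1))$. Two systematic effects
are worth knowing about when validating against an ideal Sneddon-cone
forward model: $\varepsilon = 0.75$ carries a $\approx +1.9\%$ bias for a
cone (where $\varepsilon = 2(\pi-2)/\pi \approx 0.727$ would be exact),
and the blunting offset inflates the area by
$\mathcal{O}(R_t/h_c)$, which at the generator's default 1 um depth is
below 1%. Together the round trip lands within a few percent, well inside
the 5% tolerance the tests assert; at shallow depths the blunting term
dominates and the recovered $M$ drops accordingly.

## Fibril morphometry

### D-period

The long-axis profile is linearly detrended and autocorrelated; the first
non-zero-lag local maximum above a significance floor gives the candidate
period, which is then refined by locating the $K$-th repeat peak
(the largest multiple inside the lag range) and dividing its
parabolically-interpolated lag by $K$ -- the standard trick that shrinks
localisation error by a factor $K$. Tests show sub-half-pixel accuracy
down to banding SNR 5 (SNR = band depth / height-noise SD).

The significance floor is $\sqrt{\log L / n}$ over the $L$ candidate lags
-- an extreme-value (Bartlett-type) bound on the autocorrelation of an
aperiodic profile of length $n$. A floor estimated from far lags, the more
obvious choice, is unusable here: a periodic autocorrelation does not
decay, so its own far lags are signal, not noise, and such a floor rejects
exactly the profiles one wants to accept. Profiles whose detrended
variance is numerically zero are rejected outright (`cm_no_period`).

### Diameter and swelling

Fibril diameter is defined as the background-corrected *height* maximum
per transverse section (median over sections), following the AFM
convention: height is immune to lateral tip convolution, which inflates
apparent widths. Local background is the median of the flanking 15% of
each section; a fibril crest falling inside the flanks is an error, not a
silent zero. The swelling ratio is simply hydrated over dry diameter.
Population summaries use the adjusted Fisher-Pearson skewness $g_1$ and
shared histogram bins anchored at zero with a 5 nm default width.

### Shortest axis

TEM transverse sections are measured as the minimum caliper width of each
4-connected mask component: flood-fill labelling, convex hull, then the
minimum over hull edges of the farthest point distance -- the rotating-
calipers width -- plus one pixel for the pixel footprint.

## Spheroid compression

The protocol is five cycles of 15 s compression to 25% engineering
strain, 2 s hold, 15 s recovery, 2 s rest. Cycles are segmented from
displacement activity (instrument-driven and clean) and phases labelled
by protocol durations; the first four cycles precondition the sample, so
the analysis uses the compression phase of cycle five, with the relative
peak-force drift from cycle four to five reported as a stabilisation
diagnostic.

Engineering stress and strain use the pre-test horizontal diameter $d_0$:
$\sigma = F/(\pi d_0^2/4)$, $\epsilon = \delta/d_0$. Young's modulus
inverts the sphere-between-plates Hertz relation
$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R_{axis}}\,(\delta/2)^{3/2},$$
where the total platen displacement splits equally between the two rigid-
plate contacts, pointwise over the linear window ($\epsilon \in
[0.10, 0.20]$, which excludes the toe by construction), separately for the
horizontal and vertical radii; the reported $E$ averages the two axis
values. A single 3/2-power-law fit over the window is available as
`method = "powerfit"`. $\nu$ defaults to 0.5. The contact-radius
validity condition ($a \ll R$) is a caveat of the model, not enforced.

The synthetic trace multiplies the Hertz force by a smoothstep toe ramp
that saturates at 8% strain. A toe was deliberately implemented as a
multiplicative ramp confined below the analysis window rather than an
additive force offset: an additive offset would persist into the
10--20% window and bias the pointwise inversion, making the generator
non-invertible by its own analysis -- the round trip (exact noiseless,
within 10% under 5% multiplicative force noise) is the property the
test suite enforces.

## Biochemistry

Collagen is estimated from hydroxyproline with 300 residues per triple
helix and 300 kDa per helix; the hydroxyproline molar mass defaults to
131.13 g/mol (free imino acid, matching assay standards) and is an
argument. Cross-link amounts are carried in moles and normalised to molar
collagen; ratios with zero denominators are returned as `NA` and flagged
rather than thrown. Solubility fractions are percentages of total
hydroxyproline over the sequential extraction series and sum to 100 by
construction.

ddCt expression normalises each target Ct to the arithmetic mean of the
housekeeping Cts (equivalent to the geometric mean of expression), then to
the mean dCt of the baseline group (or a named baseline sample);
expression is $2^{-\Delta\Delta Ct}$ and group summaries are geometric
means. A missing housekeeping Ct is an error naming the sample.

## Statistics

* **Two-group tests.** Welch's t is the default for log-scale continuous
  measures (stiffness, swelling); Mann-Whitney for skewed densities and
  diameters. The Mann-Whitney p is exact for combined $n \le 20$ without
  ties, otherwise the normal approximation with mid-ranks and tie-corrected
  variance. Degenerate constant samples return $t = 0, p = 1$ (equal
  means) rather than an error.
* **Holm-Sidak.** Step-down: sorted $p_{(i)}$ becomes
  $1-(1-p_{(i)})^{m-i+1}$ with running-maximum monotonicity.
* **Dunnett.** Per-comparison t statistics against the control share the
  pooled error term; adjusted p-values are two-sided rectangle
  probabilities of the multivariate t with the product correlation
  $\rho_{ij} = \lambda_i\lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$
  (equicorrelation 1/2 when balanced), evaluated by `mvtnorm::pmvt`
  quadrature under a fixed internal seed so results are reproducible. The
  quadrature is exact in the univariate case, which is how the two-group
  reduction to the t-test is tested to 1e-6. Its absolute tolerance cannot
  resolve tail probabilities below ~1e-5; there the Bonferroni product
  $k\,p_{raw}$ (first-order exact) is substituted, and all adjusted values
  are clamped into $[p_{raw}, \min(1, k\,p_{raw})]$. The same quadrature
  handles unbalanced designs directly, so no simulation fallback is
  needed.
* **Repeated measures.** The matched-donor design is analysed as a
  randomized block ANOVA (donor as block, sphericity assumed, as the
  design was randomised); Dunnett comparisons then use the block-model
  error term. Incomplete blocks are an error.
* **Kruskal-Wallis / Dunn.** Dunn's z on joint mean ranks with tie-
  corrected variance, Bonferroni-adjusted over the comparisons against
  control (the test's standard definition).
* **Missing-data correlation.** The study-level correlation of stiffness,
  collagen and cross-link densities tolerates missing cells via EM
  estimation of a multivariate-normal mean and covariance (rows grouped by
  missingness pattern; convergence on the observed-data log-likelihood,
  relative tolerance 1e-8, at most 500 iterations; non-convergence is
  flagged). This is maximum likelihood rather than REML; for covariance
  estimation at these sample sizes the distinction is a bias of order
  $1/n$ on the diagonal that cancels almost entirely in correlations, and
  the reference implementation's internal algorithm is unpublished, so ML
  is the defensible choice. On complete data the EM fixed point *is* the
  Pearson matrix (tested to 1e-8), and the estimated correlation matrix is
  symmetric positive semi-definite by construction. P-values use the t
  approximation with the pairwise effective n (both variables observed) --
  the more conservative of the two conventions the source software might
  have used. Analyses are run on log10-transformed values, matching how
  the moduli and densities are reported.
* **4PL dose-response.**
  $y = bottom + (top-bottom)/(1+10^{hill(\log_{10}d - \log_{10}IC_{50})})$
  fitted on log dose by Levenberg-Marquardt with data-driven starts; flat
  responses raise `cm_no_fit`. With all four parameters free, half-log
  dosing and 2% absolute activity noise, the IC50 sampling spread is
  substantial (relative error ~7% on average, occasionally above 20%);
  the test suite therefore asserts the *mean* relative error over 100
  seeds stays under 10% rather than a per-seed bound.

## The synthetic-data module

Generators define the study conditions: the default cohort has 15 control
and 17 case donors (the biochemistry cohort size, summing to 32), with
log-normal measurement variables whose defaults encode the study's effect
structure -- stiffness roughly doubled in disease with unchanged collagen
concentration, increased immature and mature cross-link densities, an 18%
smaller and more skewed fibril-diameter distribution, and a reduced
swelling ratio. The stiffness / mature-cross-link coupling defaults to
r = 0.72 on the log scale, imposed by Cholesky factorisation; weak
couplings of stiffness to immature cross-links (0.36) and immature to
mature (0.45) complete the default correlation structure, which is checked
for positive definiteness. The between-donor dispersions are free
parameters of the generator -- the study reports no variance components --
chosen once at values typical for donor-level biomechanics (CVs of
30--45%) and documented here rather than calibrated to any reported
statistic. Missingness is MCAR per measurement cell only.

All generators draw under their protocol seed without touching the
caller's RNG stream, emit ground truth in `attr(x, "truth")` (and as JSON
sidecars on disk), and are exactly inverted by their analysis counterpart
in the noiseless limit -- the central invariant of the test suite.

What the generators deliberately do *not* emulate: instrument artefacts
(piezo hysteresis, nonlinear thermal drift, adhesion on retraction),
viscoelastic time dependence, informative missingness, fibril curvature or
branching, and TEM image formation. Passing round-trip tests therefore
demonstrates correctness of the estimators under the stated contact and
noise models, not robustness to every artefact of real acquisitions.

## Problem sizes and runtime choices

The simulation-based tests use sizes chosen to make Monte-Carlo error
comfortably smaller than the asserted tolerances while keeping the suite
quick: 100 seeds for round-trip-under-noise and power checks, 200 seeds
for the EM-recovery and Mann-Whitney power checks, 2000 replicates for
type-I-error and family-wise-error calibration (binomial SE ~0.5% at
rate 0.05), and n = 500 with 20% missingness for the EM study. The
compression trace samples at 20 Hz over the 170 s protocol.

## Known limitations

* The Oliver-Pharr layer does not correct for tip compliance or substrate
  effects, and the sphero-conical area function assumes the nominal tip
  radius.
* The two-plate Hertz inversion assumes small contact radius and linear
  elasticity; at 20--25% strain, hyperelastic corrections it does not model
  are non-negligible for soft spheroids, so moduli are comparative, not
  absolute.
* The EM correlation assumes joint (log-)normality and data missing at
  random.
* The fibril-diameter definition (height, not width) quantifies the
  vertical extent of partially collapsed or surface-flattened fibrils.
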