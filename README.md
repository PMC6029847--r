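# collagenmech

Multiscale collagen structure-function analysis for fibrotic tissue
biomechanics.

In fibrotic lung disease, tissue stiffening feeds back into disease
progression through mechanosensitive signalling, yet the stiffness
increase is driven by post-translational collagen cross-linking rather
than collagen amount, with individual fibrils abnormal at the nanometre
scale. `collagenmech` implements the complete measurement and inference
chain used to establish that kind of structure-function result, as a
tested, reusable R package for researchers working on ECM mechanobiology
with AFM, parallel-plate compression and collagen biochemistry:

* **AFM microindentation** (colloidal sphere): contact-point detection,
  force-indentation conversion, Hertz fit
  `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`, donor-level aggregation and
  elastograph (stiffness-map) statistics including the CV.
* **AFM nanoindentation** (sharp cone, single collagen fibrils):
  Oliver-Pharr analysis -- unloading power law `P = alpha (h-h_f)^m`,
  stiffness `S = dP/dh`, contact depth `h_c = h_max - eps P_max/S`, and
  plane-strain indentation modulus
  `M = sqrt(pi) S / (2 beta sqrt(A(h_c)))` with a sphero-conical
  (blunted-tip) area function.
* **Fibril morphometry** from height topography: ~67 nm D-period by
  autocorrelation with harmonic refinement, height-based diameter,
  hydrated/dry swelling ratio, distribution statistics, and TEM-style
  minimum-caliper (shortest-axis) measurement.
* **Spheroid compression**: five-cycle protocol segmentation, engineering
  stress/strain, toe exclusion via the 10-20% strain linear window, and
  Young's modulus from the sphere-between-plates Hertz model
  `F = (4/3) E/(1-nu^2) sqrt(R_axis) (delta/2)^(3/2)`, averaged over the
  horizontal and vertical radii.
* **Biochemistry**: hydroxyproline-to-collagen conversion (300 residues /
  300 kDa per triple helix), cross-link densities and ratios
  (DHLNL, HLNL, PYD, DPD), sequential-extraction solubility fractions,
  and ddCt relative expression.
* **Statistics**: Welch/Student/Mann-Whitney/one-sample tests, Holm-Sidak
  adjustment, ANOVA / repeated-measures ANOVA with Dunnett and
  Kruskal-Wallis with Dunn post hoc comparisons, missing-data
  multivariate-normal correlation by EM, and 4PL IC50 fitting.
* **Synthetic data**: seeded generators for every input class with ground
  truth attached, so each estimator is validated by round trip.

See `vignettes/collagen-structure-function.Rmd` for the models,
estimators, defaults and design decisions in full.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; `Rscript analysis/01_simulate.R` writes the seeded inputs and the
later scripts analyse them. A condensed session:

```r
library(collagenmech)

## Tissue-scale: Hertz microindentation (15 um sphere, nu = 0.5)
sphere <- indenter_spec("sphere", radius_um = 7.5, nu = 0.5)
cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = 1, noise_sd = 0.3))
fi  <- to_force_indentation(cur)
fit_hertz_sphere(fi$delta, fi$F, sphere)
#> <modulus_result> hertz_sphere: 9.968 kPa (n = 201, resid = 0.546)

## Fibril-scale: D-period of a banded topography at SNR 10
topo <- synth_fibril_topography(protocol = synth_protocol(seed = 1, noise_sd = 0.8))
prof <- extract_long_axis_profile(topo,
          cbind(x = c(1, ncol(topo$height)),
                y = rep(attr(topo, "truth")$crest_row, 2)))
estimate_d_period(prof)
#> [1] 66.9978

## Culture-scale: Young's modulus from a five-cycle compression trace
ct <- synth_compression_test(5, protocol = synth_protocol(seed = 3, sampling_step = 0.05))
young_modulus_sphere(ct)
#> <youngs_modulus_result> E = 5.001 kPa (h 4.937 / v 5.065), nu = 0.5,
#>   window 0.1-0.2 strain, n = 121

## Study-level inference on a 32-donor cohort with 5% missing cells
res <- run_cohort_analysis(study_config(cohort = cohort_spec(missing_rate = 0.05),
                                        seed = 20260926))
res$correlation$r["stiffness_kpa", "mature_crosslinks"]
#> [1] 0.8132049
res$correlation$p["stiffness_kpa", "mature_crosslinks"]
#> [1] 4.726233e-08
```

Read: the Hertz fit recovers the generating 10 kPa modulus; the
D-period estimator returns the canonical ~67 nm collagen repeat within a
few hundredths of a nanometre; the compression inversion recovers the
generating 5 kPa Young's modulus within 0.1%; and on a cohort generated
with a log-scale stiffness / mature-cross-link correlation of 0.72, the
EM missing-data correlation reports a strong positive, significant
association (while stiffness-collagen stays null).

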