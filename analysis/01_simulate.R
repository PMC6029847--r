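#!/usr/bin/env Rscript
## Generate the synthetic study inputs consumed by the downstream analysis
## scripts: a two-group donor cohort, AFM indentation curves, a banded
## fibril topography, a five-cycle compression trace and enzyme-inhibition
## dose-response tables. Every artefact is seeded and carries a JSON
## ground-truth sidecar.

suppressPackageStartupMessages(library(collagenmech))
seed <- 20260926L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Donor cohort: 15 control / 17 fibrotic donors, stiffness coupled to
## mature cross-link density at r = 0.72 on the log scale, 5% missing cells
co <- synth_cohort(cohort_spec(missing_rate = 0.05), synth_protocol(seed = seed))
write_cohort(co, file.path(out, "cohort.tsv"))
write_truth_json(co, file.path(out, "cohort.truth.json"))
cat(sprintf("cohort: %d donors (%s)\n", nrow(co),
            paste(names(table(co$group)), table(co$group), collapse = ", ",
                  sep = " = ")))

## Microindentation curve: 15 um microsphere on 10 kPa tissue
sphere <- indenter_spec("sphere", radius_um = 7.5, nu = 0.5)
cur <- synth_indentation_curve(10, sphere, synth_protocol(seed = seed, noise_sd = 0.3))
write_force_curve(cur, file.path(out, "microindentation_curve.tsv"))
write_truth_json(cur, file.path(out, "microindentation_curve.truth.json"))

## Nanoindentation curve: conical tip on an extracted fibril (M ~ MPa scale)
cone <- indenter_spec("cone", half_angle_deg = 20, nu = 0.5)
nano <- synth_indentation_curve(5000, cone, synth_protocol(seed = seed + 1L, noise_sd = 0.2))
write_force_curve(nano, file.path(out, "nanoindentation_curve.tsv"))
write_truth_json(nano, file.path(out, "nanoindentation_curve.truth.json"))

## Fibril topography with canonical ~67 nm banding at SNR 10; a compact
## grid (15 repeats, narrow transverse margin) keeps the stored file small,
## and heights are rounded to 1 pm -- far below the 0.8 nm noise floor
topo <- synth_fibril_topography(length = 1005, grid_width = 40, fibril_width = 24,
                                protocol = synth_protocol(seed = seed, noise_sd = 0.8))
topo$height <- round(topo$height, 3)
write_topography(topo, file.path(out, "fibril_topography.txt"))
write_truth_json(topo, file.path(out, "fibril_topography.truth.json"))

## Five-cycle spheroid compression trace, E = 5 kPa, 2% force noise
ct <- synth_compression_test(5, protocol = synth_protocol(seed = seed, sampling_step = 0.05),
                             noise_rel = 0.02)
write_compression_test(ct, file.path(out, "compression_trace.tsv"))
write_truth_json(ct, file.path(out, "compression_trace.truth.json"))

## Enzyme-inhibition curves for the two targeted amine oxidases
for (enz in c("LOXL2", "LOXL3")) {
  ic50 <- c(LOXL2 = 0.005, LOXL3 = 0.016)[[enz]]
  dr <- synth_dose_response(ic50, protocol = synth_protocol(seed = seed + match(enz, c("LOXL2", "LOXL3")),
                                                            noise_sd = 2))
  utils::write.table(dr, file.path(out, sprintf("dose_response_%s.tsv", enz)),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_truth_json(dr, file.path(out, sprintf("dose_response_%s.truth.json", enz)))
}
cat("synthetic inputs written to", out, "\n")
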