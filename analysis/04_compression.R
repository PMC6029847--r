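#!/usr/bin/env Rscript
## Spheroid compression: segment the five-cycle trace, check
## preconditioning stabilisation, transform the fifth compression phase to
## engineering stress-strain and invert the sphere-between-plates Hertz
## model over the 10-20% strain linear window.

suppressPackageStartupMessages(library(collagenmech))
sim <- "results/sim"; out <- "results"

ct <- read_compression_test(file.path(sim, "compression_trace.tsv"))
truth <- jsonlite::read_json(file.path(sim, "compression_trace.truth.json"))
cycles <- segment_cycles(ct)
cat(sprintf("segmented %d cycles; peak strains: %s\n", length(cycles),
            paste(sprintf("%.3f", vapply(cycles, `[[`, numeric(1), "peak_strain")),
                  collapse = " ")))

ym <- young_modulus_sphere(ct)
cat(sprintf("Young's modulus: %.3f kPa (horizontal %.3f / vertical %.3f; generated at %.1f kPa)\n",
            ym$E_kpa, ym$E_axis_kpa[["h"]], ym$E_axis_kpa[["v"]], truth$E_true))
cat(sprintf("preconditioning: relative peak-force drift cycle 4 -> 5 = %.3g\n",
            ym$stabilisation))

ss <- engineering_stress_strain(cycles[[5]], ct$d0_um)
utils::write.table(ss, file.path(out, "stress_strain_cycle5.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("fifth-cycle stress-strain written to results/stress_strain_cycle5.tsv\n")
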