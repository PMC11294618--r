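#!/usr/bin/env Rscript
# Hydrochemical characterisation of the simulated survey: facies,
# controlling mechanism, origin, ion-exchange direction and mineral
# saturation state.

suppressPackageStartupMessages(library(aquarisk))
samples <- read_samples("results/samples.csv")

hydro <- classify_hydrochem(samples)
write.csv(hydro, "results/hydrochem.csv", row.names = FALSE)

cat("Piper facies:\n"); print(table(hydro$piper_facies))
cat("Gibbs zone:\n"); print(table(hydro$gibbs_zone))
cat("Sulin origin:\n"); print(table(hydro$sulin_origin))
cat(sprintf("reverse ion exchange (CAI-I > 0): %d of %d samples\n",
            sum(hydro$CAI_I > 0, na.rm = TRUE), nrow(hydro)))
cat(sprintf("median SI: calcite %+.2f, dolomite %+.2f, gypsum %+.2f, ",
            median(hydro$SI_calcite), median(hydro$SI_dolomite),
            median(hydro$SI_gypsum)))
cat(sprintf("halite %+.2f\n", median(hydro$SI_halite)))
cat("carbonates supersaturated, evaporites undersaturated -> water can\n")
cat("precipitate calcite/dolomite but keeps dissolving gypsum/halite\n")
cat("wrote results/hydrochem.csv\n")
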