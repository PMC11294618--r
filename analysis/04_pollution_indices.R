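#!/usr/bin/env Rscript
# Heavy-metal pollution load (HPI, HMI) and Hakanson ecological risk.

suppressPackageStartupMessages(library(aquarisk))
samples <- read_samples("results/samples.csv")

hp <- hpi(samples)                       # Fe + Mn, the elevated pair
hm <- hmi(samples)                       # all four PTEs
ri <- ecological_ri(samples)
out <- data.frame(sample_id = hp$sample_id, hpi = hp$hpi,
                  hpi_class = hp$class, hmi = hm$hmi,
                  hmi_class = hm$class,
                  ri[, c("Er_Fe", "Er_Mn", "Er_Cr", "Er_Pb", "ri")],
                  ri_class = ri$class)
write.csv(out, "results/pollution_indices.csv", row.names = FALSE)

cat(sprintf("HPI: %.1f-%.1f, mean %.1f; %.0f%% of samples above 100\n",
            min(hp$hpi), max(hp$hpi), mean(hp$hpi),
            100 * mean(hp$hpi > 100)))
cat(sprintf("HMI: %.2f-%.2f, classes:\n", min(hm$hmi), max(hm$hmi)))
print(table(hm$class))
cat(sprintf("RI: %.2f-%.2f, mean %.2f; %.0f%% in the low-risk class\n",
            min(ri$ri), max(ri$ri), mean(ri$ri),
            100 * mean(ri$ri < 30)))
cat("wrote results/pollution_indices.csv\n")
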