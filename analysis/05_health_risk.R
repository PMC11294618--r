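#!/usr/bin/env Rscript
# Deterministic USEPA exposure risk: per-metal HQ, per-route HI and CR
# for adult and child receptors, plus the endpoint check at the survey
# concentration extremes.

suppressPackageStartupMessages(library(aquarisk))
samples <- read_samples("results/samples.csv")

hr <- health_risk(samples)
write.csv(hr$hq, "results/health_risk_hq.csv", row.names = FALSE)
write.csv(hr$hi, "results/health_risk_hi.csv", row.names = FALSE)

oral <- hr$hi[hr$hi$route == "oral", ]
for (g in c("adult", "child")) {
  v <- oral$HI[oral$group == g]
  cat(sprintf("oral HI (%s): %.3f-%.3f; HI > 1 in %d of %d samples\n",
              g, min(v), max(v), sum(v > 1), length(v)))
}
derm <- hr$hi[hr$hi$route == "dermal", ]
cat(sprintf("dermal HI: adult %.1e-%.1e, child %.1e-%.1e\n",
            min(derm$HI[derm$group == "adult"]),
            max(derm$HI[derm$group == "adult"]),
            min(derm$HI[derm$group == "child"]),
            max(derm$HI[derm$group == "child"])))

cr <- hr$hq[!is.na(hr$hq$CR) & hr$hq$route == "oral", ]
for (m in c("Cr", "Pb")) {
  v <- cr$CR[cr$metal == m]
  cat(sprintf("oral CR (%s): %.1e-%.1e; above 1e-4 in %.0f%% of cases\n",
              m, min(v), max(v), 100 * mean(v > 1e-4)))
}

# deterministic endpoints at the survey extremes (reference table)
tg <- survey_targets(); tox <- toxicology_table()
rows <- list()
for (g in c("adult", "child")) {
  prof <- exposure_profile(g)
  for (m in c("Fe", "Mn", "Cr", "Pb")) {
    rfd <- tox$RfD_oral[tox$metal == m]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, metal = m,
      hq_at_min = hazard_quotient(cdi_oral(tg$min[tg$analyte == m], prof),
                                  rfd),
      hq_at_max = hazard_quotient(cdi_oral(tg$max[tg$analyte == m], prof),
                                  rfd)
    )
  }
}
endpoints <- do.call(rbind, rows)
write.csv(endpoints, "results/hq_endpoints.csv", row.names = FALSE)
cat("wrote results/health_risk_{hq,hi}.csv and results/hq_endpoints.csv\n")
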