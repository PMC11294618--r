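#!/usr/bin/env Rscript
# Drinking-water suitability: entropy, CRITIC and integrated weights
# computed from the data themselves, the published-weight scoring for
# comparison, and the class breakdown.

suppressPackageStartupMessages(library(aquarisk))
samples <- read_samples("results/samples.csv")

std <- standards_table()
X <- as.matrix(samples[, std$parameter])
w1 <- entropy_weights(normalize_matrix(X))
w2 <- critic_weights(X)
W <- integrated_weights(w1, w2)
weights <- data.frame(parameter = std$parameter, entropy = w1[std$parameter],
                      critic = w2[std$parameter],
                      integrated = W[std$parameter],
                      published = std$Wj, row.names = NULL)
write.csv(weights, "results/weights.csv", row.names = FALSE)

scored <- iwqi(samples, weights = "integrated")
published <- iwqi(samples, weights = "published")
out <- data.frame(sample_id = scored$sample_id,
                  iwqi = scored$iwqi, class = scored$class,
                  iwqi_published_w = published$iwqi,
                  class_published_w = published$class)
write.csv(out, "results/iwqi.csv", row.names = FALSE)

cat("data-driven integrated weights (descending):\n")
print(round(sort(W, decreasing = TRUE), 4))
cat(sprintf("\nIWQI (integrated weights): %.1f-%.1f, mean %.1f\n",
            min(scored$iwqi), max(scored$iwqi), mean(scored$iwqi)))
print(table(scored$class))
cat(sprintf("IWQI (published weights): %.1f-%.1f, mean %.1f\n",
            min(published$iwqi), max(published$iwqi),
            mean(published$iwqi)))
cat("wrote results/weights.csv and results/iwqi.csv\n")
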