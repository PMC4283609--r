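#!/usr/bin/env Rscript
# Stage 3: nonmetric multidimensional scaling (two axes, 1000 random
# starts). With epoch turnover and province separation both active, the
# configuration spreads assemblages by age and biome.

library(gabifauna)

occ <- read_occurrences("results/data/occurrences.csv", "wide")
meta <- read_metadata("results/data/metadata.csv")

d <- pairwise_dissimilarity(occ)
fit <- nmds_fit(d, k = 2, n_starts = 1000, seed = 20260922L)
print(fit)

coords <- data.frame(assemblage = rownames(fit$points), fit$points,
                     biome = meta$biome[match(rownames(fit$points),
                                              meta$assemblage_id)],
                     epoch = meta$epoch[match(rownames(fit$points),
                                              meta$assemblage_id)])
write.csv(coords, "results/nmds_coordinates.csv", row.names = FALSE)

r_of <- function(axis, fac)
  abs(cor(fit$points[, axis], as.numeric(factor(fac))))
cat(sprintf("Point-biserial |r|: axis1~biome %.2f, axis2~biome %.2f\n",
            r_of(1, coords$biome), r_of(2, coords$biome)))
ep_num <- as.numeric(factor(coords$epoch,
                            levels = c("middle_miocene", "late_miocene",
                                       "pliocene")))
cat(sprintf("                    axis1~epoch %.2f, axis2~epoch %.2f\n",
            abs(cor(fit$points[, 1], ep_num)),
            abs(cor(fit$points[, 2], ep_num))))
cat("Coordinates written to results/nmds_coordinates.csv\n")
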