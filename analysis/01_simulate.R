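#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the structure of the thirteen-assemblage Neogene compilation:
# two biogeographic provinces (tropical / temperate) over three epochs,
# nearly disjoint genus pools (10% overlap), half of each pool turning
# over per epoch, and imperfect per-collection detection. Everything
# downstream runs off the files written here.

library(gabifauna)

seed <- 20260920L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_occurrences(province_model(), seed = seed)

write_occurrences(sim$occurrences, file.path(out, "occurrences.csv"),
                  layout = "wide")
write.csv(as.data.frame(sim$metadata), file.path(out, "metadata.csv"),
          row.names = FALSE)
for (lab in names(sim$collections)) {
  ci <- sim$collections[[lab]]
  idx <- which(unclass(ci) == 1L, arr.ind = TRUE)
  write.csv(data.frame(collection_id = rownames(ci)[idx[, 1]],
                       genus = colnames(ci)[idx[, 2]]),
            file.path(out, paste0("collections_", lab, ".csv")),
            row.names = FALSE)
}

cat("Simulated", nrow(sim$occurrences), "assemblages,",
    ncol(sim$occurrences), "observed genera\n")
cat("Richness range:",
    paste(range(rowSums(unclass(sim$occurrences))), collapse = "-"), "\n")
print(table(sim$metadata$biome, sim$metadata$epoch))
cat("Data written under", out, "\n")
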