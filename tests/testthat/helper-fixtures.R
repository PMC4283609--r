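# shared fixtures built in code

# random symmetric dissimilarity matrix; continuous values so that
# neither entries nor any between-cluster averages tie
random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  v <- runif(n * (n - 1) / 2, 0.05, 0.95)
  d <- matrix(0, n, n, dimnames = list(paste0("L", seq_len(n)),
                                       paste0("L", seq_len(n))))
  d[upper.tri(d)] <- v
  d <- d + t(d)
  dissimilarity_matrix(d)
}

# random binary occurrence matrix with no empty rows/columns
random_occurrences <- function(n_asm, n_gen, seed, p = 0.4) {
  set.seed(seed)
  repeat {
    inc <- matrix(rbinom(n_asm * n_gen, 1, p), n_asm,
                  dimnames = list(paste0("A", seq_len(n_asm)),
                                  paste0("G", seq_len(n_gen))))
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0))
      return(occurrence_matrix(inc))
  }
}

# small single-epoch two-province model for recovery checks
recovery_model <- function(overlap, n_per_province = 3,
                           detection_prob = 0.9) {
  province_model(pool_size = 60, overlap = overlap,
                 epochs = "middle_miocene", turnover = 0,
                 assemblages_per_province =
                   rbind(tropical = 1, temperate = 1) * n_per_province,
                 richness_range = c(10, 15),
                 collections_per_assemblage = 5,
                 detection_prob = detection_prob)
}

# point-biserial correlation between a numeric axis and a 2-level factor
point_biserial <- function(axis, labels) {
  stats::cor(axis, as.numeric(factor(labels)))
}
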