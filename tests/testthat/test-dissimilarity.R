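test_that("binary Bray-Curtis matches set arithmetic and its identities", {
  expect_equal(bray_curtis_binary(c("Ga", "Gb", "Gc"), c("Gb", "Gc", "Gd")),
               2 / 6)
  expect_equal(bray_curtis_binary(c("Ga", "Gb"), c("Ga", "Gb")), 0)
  expect_equal(bray_curtis_binary(c("Ga"), c("Gb", "Gc")), 1)
  expect_error(bray_curtis_binary(character(0), "Ga"), "non-empty")
  # algebraic identity 1 - 2a/(2a+b+c) on random set pairs
  set.seed(1)
  pool <- paste0("G", 1:30)
  for (i in 1:50) {
    x <- sample(pool, sample(1:20, 1))
    y <- sample(pool, sample(1:20, 1))
    a <- length(intersect(x, y))
    expect_equal(bray_curtis_binary(x, y),
                 1 - 2 * a / (length(x) + length(y)))
  }
})

test_that("pairwise dissimilarity agrees with vegan and per-pair values", {
  m <- random_occurrences(8, 25, seed = 3)
  d <- pairwise_dissimilarity(m)
  expect_s3_class(d, "dissimilarity_matrix")
  expect_true(isSymmetric(unclass(unname(d))))
  expect_equal(diag(unclass(d)), setNames(rep(0, 8), rownames(m)))
  for (i in 1:3) for (j in 6:8)
    expect_equal(d[i, j], bray_curtis_binary(genus_set(m, rownames(m)[i]),
                                             genus_set(m, rownames(m)[j])))
  skip_if_not_installed("vegan")
  dv <- as.matrix(vegan::vegdist(unclass(m), method = "bray",
                                 binary = TRUE))
  expect_equal(unclass(d), dv, tolerance = 1e-12, ignore_attr = TRUE)
  # identical rows -> 0; disjoint rows -> 1
  m2 <- occurrence_matrix(rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0),
                                C = c(0, 0, 1, 1)) |>
                            (\(x) {colnames(x) <- paste0("g", 1:4); x})())
  d2 <- pairwise_dissimilarity(m2)
  expect_equal(d2["A", "B"], 0)
  expect_equal(d2["A", "C"], 1)
})

test_that("UPGMA reproduces hand computations and hclust average linkage", {
  d <- dissimilarity_matrix(matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  t3 <- upgma(d)
  expect_equal(t3$height, c(0.2, 0.6))
  expect_setequal(first_bipartition(t3)[[1]], "C")
  d2 <- dissimilarity_matrix(matrix(c(0, .5, .5, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(upgma(d2)$height, 0.5)
  d0 <- dissimilarity_matrix(matrix(c(0, 0, 0, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(upgma(d0)$height, 0)
  # oracle: stats::hclust average linkage, cophenetic equivalence
  for (seed in 1:40) {
    n <- sample(3:12, 1)
    dr <- random_dissimilarity(n, seed)
    mine <- stats::cophenetic(upgma(dr))
    ref <- stats::cophenetic(stats::hclust(stats::as.dist(dr),
                                           method = "average"))
    expect_equal(as.matrix(mine)[rownames(dr), rownames(dr)],
                 as.matrix(ref)[rownames(dr), rownames(dr)],
                 tolerance = 1e-12)
  }
})

test_that("UPGMA cophenetic matrix is ultrametric and ties are deterministic", {
  for (seed in 1:10) {
    dr <- random_dissimilarity(sample(4:10, 1), seed + 100)
    cm <- as.matrix(stats::cophenetic(upgma(dr)))
    n <- nrow(cm)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-12)
  }
  # tie whose resolution changes the tree: d(A,B) = d(A,C) = 0.3;
  # lexicographic rule must pick A|B, and the result must not depend on
  # input row order
  lab <- c("A", "B", "C")
  d <- matrix(c(0, .3, .3, .3, 0, .5, .3, .5, 0), 3,
              dimnames = list(lab, lab))
  t1 <- upgma(dissimilarity_matrix(d))
  cm1 <- as.matrix(stats::cophenetic(t1))[lab, lab]
  expect_equal(cm1["A", "B"], 0.3)
  expect_equal(cm1["A", "C"], 0.4)
  expect_equal(cm1["B", "C"], 0.4)
  perm <- c(3, 1, 2)
  t2 <- upgma(dissimilarity_matrix(d[perm, perm]))
  expect_equal(as.matrix(stats::cophenetic(t2))[lab, lab], cm1)
})

test_that("Newick export uses half-height branch lengths and round-trips", {
  d2 <- dissimilarity_matrix(matrix(c(0, .5, .5, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B"))))
  expect_identical(to_newick(upgma(d2)), "(A:0.25,B:0.25);")
  d3 <- dissimilarity_matrix(matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  nwk <- to_newick(upgma(d3))
  ph <- ape::read.tree(text = nwk)
  # leaf-to-root path = cophenetic height / 2
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep(0.3, 3), tolerance = 1e-9)
  coph_tree <- as.matrix(ape::cophenetic.phylo(ph))
  coph_ref <- as.matrix(stats::cophenetic(upgma(d3)))
  expect_equal(coph_tree[rownames(coph_ref), colnames(coph_ref)],
               coph_ref, tolerance = 1e-9)
})

test_that("distance decay reports pair classes and a seeded Mantel test", {
  meta <- assemblage_metadata(data.frame(
    assemblage_id = c("P1", "P2", "P3", "P4"),
    latitude = c(0, 0, -10, -30), longitude = c(-70, -60, -65, -62),
    biome = c("tropical", "tropical", "tropical", "temperate"),
    epoch = "middle_miocene"))
  km <- matrix(0, 4, 4, dimnames = list(meta$assemblage_id,
                                        meta$assemblage_id))
  for (i in 1:3) for (j in (i + 1):4)
    km[i, j] <- km[j, i] <- great_circle_distance(
      c(meta$latitude[i], meta$longitude[i]),
      c(meta$latitude[j], meta$longitude[j]))
  d <- dissimilarity_matrix(km / max(km) * 0.9)
  dd <- distance_decay(d, meta, permutations = 999, seed = 9)
  expect_equal(dd$mantel_r, 1, tolerance = 1e-12)
  expect_lte(dd$mantel_p, 1 / 1000 + 1e-12)
  expect_equal(nrow(dd$pairs), 6)
  expect_setequal(unique(dd$pairs$pair_class),
                  c("tropical-tropical", "temperate-tropical"))
  # constant dissimilarity: degenerate, no crash
  dc <- dissimilarity_matrix({m <- matrix(0.5, 4, 4,
    dimnames = dimnames(km)); diag(m) <- 0; m})
  ddc <- distance_decay(dc, meta, permutations = 99, seed = 1)
  expect_true(ddc$degenerate)
  expect_true(is.na(ddc$mantel_r))
  # cross-epoch pairs excluded under within_epoch_only
  meta2 <- meta; meta2$epoch[4] <- "pliocene"
  dd2 <- distance_decay(d, meta2, within_epoch_only = TRUE,
                        permutations = 99, seed = 1)
  expect_equal(nrow(dd2$pairs), 3)
})

test_that("exact Mantel enumeration matches brute force over label orders", {
  set.seed(8)
  x <- random_dissimilarity(4, 11)
  y <- random_dissimilarity(4, 12)
  mt <- mantel_test(unclass(x), unclass(y), permutations = "exact")
  # independent brute force: all 24 label orders, plain loops
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_of <- function(p) {
    xp <- unclass(x)[p, p]
    stats::cor(xp[upper.tri(xp)], unclass(y)[upper.tri(y)])
  }
  rs <- apply(perms, 1, function(p) r_of(as.integer(p)))
  r_obs <- r_of(1:4)
  expect_equal(mt$mantel_r, r_obs)
  expect_equal(mt$mantel_p, mean(rs >= r_obs - 1e-12))
  # sampled permutation p approximates the exact enumeration p
  mts <- mantel_test(unclass(x), unclass(y), permutations = 999, seed = 2)
  expect_lt(abs(mts$mantel_p - mt$mantel_p), 0.08)
})
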