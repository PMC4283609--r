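test_that("rarefied pair dissimilarity honors set identities", {
  x <- paste0("g", 1:8)
  expect_equal(rarefied_pair_dissimilarity(x, x, 4, n_reps = 50, seed = 1),
               rep(0, 50))
  y <- paste0("h", 1:5)
  expect_equal(rarefied_pair_dissimilarity(x, y, 3, n_reps = 50, seed = 2),
               rep(1, 50))
  expect_error(rarefied_pair_dissimilarity(x, y, 0), "target_richness")
  # same seed, same replicates
  r1 <- rarefied_pair_dissimilarity(x, y[1:3], 5, n_reps = 100, seed = 7)
  r2 <- rarefied_pair_dissimilarity(x, y[1:3], 5, n_reps = 100, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("rarefied replicate mean matches exhaustive enumeration", {
  # x = {g1,g2}, y = {g1,g3}, target 2: each side has 4 equally likely
  # ordered draws; enumerate all 16 outcomes for the exact expectation
  x <- c("g1", "g2"); y <- c("g1", "g3")
  draws <- expand.grid(x1 = x, x2 = x, y1 = y, y2 = y,
                       stringsAsFactors = FALSE)
  exact <- mean(apply(draws, 1, function(r)
    bray_curtis_binary(unique(r[1:2]), unique(r[3:4]))))
  mc <- rarefied_pair_dissimilarity(x, y, 2, n_reps = 10000, seed = 11)
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - exact), 3 * se + 1e-12)
})

test_that("rarefied mean approaches the un-rarefied index at high target", {
  set.seed(3)
  x <- paste0("g", 1:12)
  y <- c(paste0("g", 1:5), paste0("h", 1:9))
  full <- bray_curtis_binary(x, y)
  reps <- rarefied_pair_dissimilarity(x, y, 50 * 14, n_reps = 300,
                                      seed = 5)
  expect_lt(abs(mean(reps) - full), 0.02)
})

test_that("group distributions pool pairs at the subgroup minimum richness", {
  inc <- rbind(A1 = c(1, 1, 1, 1, 0, 0, 0, 0),
               A2 = c(1, 1, 1, 1, 0, 0, 0, 0),
               B1 = c(0, 0, 0, 0, 1, 1, 1, 0),
               B2 = c(0, 0, 0, 0, 0, 1, 1, 1))
  colnames(inc) <- paste0("g", 1:8)
  m <- occurrence_matrix(inc)
  groups <- c(A1 = "north", A2 = "north", B1 = "south", B2 = "south")
  within_id <- group_dissimilarity_distribution(m, groups, "north",
                                                n_reps = 100, seed = 1)
  expect_equal(within_id$mean, 0)
  expect_equal(within_id$sd, 0)
  expect_equal(within_id$target_richness, 4)
  between <- group_dissimilarity_distribution(m, groups,
                                              c("north", "south"),
                                              n_reps = 100, seed = 2)
  expect_equal(between$mean, 1)
  expect_equal(nrow(between$pairs), 4)
  expect_equal(between$target_richness, 3)
  expect_equal(length(between$values), 400)
  expect_error(group_dissimilarity_distribution(m, groups["A1"], "north"),
               ">= 2 assemblages")
})

test_that("within-province dissimilarity is below between, gap closing in overlap", {
  gaps <- vapply(c(0.2, 0.6, 1.0), function(ov) {
    mean(vapply(31:33, function(s) {
      sim <- simulate_occurrences(recovery_model(ov), seed = s)
      grp <- setNames(sim$metadata$biome, sim$metadata$assemblage_id)
      w <- group_dissimilarity_distribution(sim$occurrences, grp,
                                            "tropical",
                                            n_reps = 100, seed = 5)
      b <- group_dissimilarity_distribution(sim$occurrences, grp,
                                            c("tropical", "temperate"),
                                            n_reps = 100, seed = 6)
      b$mean - w$mean
    }, 0))
  }, 0)
  expect_gt(gaps[1], 0)
  expect_gt(gaps[2], 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(gaps[3]), 0.05)
})

test_that("Mann-Whitney U matches enumeration, wilcox.test, and its identity", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4), "less")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 6)
  expect_identical(mw$method, "exact")
  # identical samples: U = n^2/2 and two-sided p at the boundary
  a <- 1:6
  mws <- mann_whitney_u(a, a)
  expect_equal(mws$U, 18)
  expect_gte(mws$p, 0.99)
  # U(a,b) + U(b,a) = na*nb over random inputs (with and without ties)
  set.seed(6)
  for (i in 1:20) {
    s1 <- sample(1:12, 7, replace = TRUE)
    s2 <- sample(1:12, 5, replace = TRUE)
    expect_equal(mann_whitney_u(s1, s2)$U + mann_whitney_u(s2, s1)$U, 35)
  }
  # agreement with stats::wilcox.test in both regimes
  set.seed(9)
  x <- rnorm(8); y <- rnorm(8) + 0.5
  expect_equal(mann_whitney_u(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value)
  xl <- rnorm(25); yl <- rnorm(25)
  expect_equal(mann_whitney_u(xl, yl)$p,
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("normal approximation tracks the exact null tail", {
  # tie-free samples just over the exact cutoff: the package takes the
  # normal path, the exact distribution (pwilcox) is the oracle
  set.seed(13)
  for (i in 1:15) {
    x <- rnorm(21); y <- rnorm(21)
    mw <- mann_whitney_u(x, y)
    expect_identical(mw$method, "normal_approx")
    p_exact <- if (mw$U > 21 * 21 / 2)
      min(1, 2 * pwilcox(mw$U - 1, 21, 21, lower.tail = FALSE))
    else min(1, 2 * pwilcox(mw$U, 21, 21))
    expect_lt(abs(mw$p - p_exact), 0.02)
  }
})

test_that("two-sided p is near-uniform under the null", {
  set.seed(21)
  ps <- replicate(2000, {
    mann_whitney_u(rnorm(10), rnorm(10))$p
  })
  reject <- mean(ps < 0.05)
  expect_gte(reject, 0.03)
  expect_lte(reject, 0.07)
})

test_that("compare_groups is reproducible and reports all contrasts", {
  m <- random_occurrences(6, 30, seed = 17)
  groups <- setNames(rep(c("g1", "g2"), each = 3), rownames(m))
  cts <- list("g1", "g2", c("g1", "g2"))
  r1 <- compare_groups(m, groups, cts, n_reps = 50, seed = 2)
  r2 <- compare_groups(m, groups, cts, n_reps = 50, seed = 2)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$summary), 3)
  expect_equal(nrow(r1$tests), 3)
  expect_true(all(r1$summary$mean >= 0 & r1$summary$mean <= 1))
})
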