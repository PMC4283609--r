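make_records <- function(df) {
  defaults <- data.frame(origin_continent = "NA",
                         recording_continent = "SA", region = "temperate",
                         stringsAsFactors = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  fad_records(df)
}

test_that("FAD record validation enforces the domain invariants", {
  ok <- make_records(data.frame(genus = c("Ga", "Gb"),
                                age_max = c(9, 5), age_min = c(8, 5)))
  expect_s3_class(ok, "fad_records")
  expect_error(make_records(data.frame(genus = "Ga", age_max = 5,
                                       age_min = 6)), "age_max >= age_min")
  expect_error(fad_records(data.frame(genus = "Ga",
    origin_continent = "NA", recording_continent = "NA",
    region = "tropical", age_max = 5, age_min = 4)),
    "outside their origin")
  expect_error(make_records(data.frame(genus = c("Ga", "Ga"),
    origin_continent = c("NA", "SA"),
    recording_continent = c("SA", "NA"),
    age_max = c(5, 4), age_min = c(4, 3))), "conflicting origin")
  expect_identical(region_from_latitude(c(-10, 22, -30)),
                   c("tropical", "tropical", "temperate"))
})

test_that("age draws are uniform on the interval, exact when degenerate", {
  pt <- make_records(data.frame(genus = "Ga", age_max = 7.3,
                                age_min = 7.3))
  set.seed(1)
  expect_equal(unique(replicate(20, draw_age(pt))), 7.3)
  iv <- make_records(data.frame(genus = "Gb", age_max = 10, age_min = 8))
  set.seed(2)
  draws <- replicate(1e5, draw_age(iv))
  expect_lt(abs(mean(draws) - 9), 3 * sqrt(4 / 12) / sqrt(1e5))
  expect_lt(abs(var(draws) - 4 / 12), 0.01)
  expect_true(all(draws >= 8 & draws <= 10))
})

test_that("cumulative FAD curves count drawn ages at closed edges", {
  pts <- make_records(data.frame(genus = c("Ga", "Gb"),
                                 age_max = c(9.5, 3.2),
                                 age_min = c(9.5, 3.2)))
  curve <- cumulative_fad_curve(pts, n_reps = 20, seed = 1)
  at <- function(t) curve$mean_count[curve$edge_ma == t]
  expect_equal(at(10), 0)
  expect_equal(at(9), 1)
  expect_equal(at(3), 2)
  expect_equal(curve$sd_count, rep(0, nrow(curve)))
  # one record on [8,10]: P(age >= 9) = 0.5
  iv <- make_records(data.frame(genus = "Gc", age_max = 10, age_min = 8))
  cv <- cumulative_fad_curve(iv, n_reps = 1000, seed = 3)
  m9 <- cv$mean_count[cv$edge_ma == 9]
  s9 <- cv$sd_count[cv$edge_ma == 9]
  expect_lt(abs(m9 - 0.5), 3 * s9 / sqrt(1000))
  expect_error(cumulative_fad_curve(pts, region = "tropical"),
               "no FAD records left")
})

test_that("exact expected curve matches hand values and bounds the MC mean", {
  iv <- make_records(data.frame(genus = "Gc", age_max = 10, age_min = 8))
  ex <- expected_fad_curve(iv)
  expect_equal(ex$expected_count[ex$edge_ma == 9], 0.5)
  expect_equal(ex$expected_count[ex$edge_ma == 11], 0)
  expect_equal(ex$expected_count[ex$edge_ma == 7], 1)
  # point ages reduce to the step function
  pts <- make_records(data.frame(genus = c("Ga", "Gb"),
                                 age_max = c(9.5, 3.2),
                                 age_min = c(9.5, 3.2)))
  exp_pts <- expected_fad_curve(pts)
  expect_equal(exp_pts$expected_count,
               vapply(exp_pts$edge_ma,
                      function(t) sum(c(9.5, 3.2) >= t), 0))
  # MC mean within 3 se of the expectation at every edge, random records
  set.seed(44)
  rec <- make_records(data.frame(
    genus = paste0("G", 1:15),
    age_max = runif(15, 2, 12), age_min = 0))
  rec$age_min <- pmax(0, rec$age_max - runif(15, 0, 3))
  rec <- fad_records(rec)
  mc <- cumulative_fad_curve(rec, n_reps = 1000, seed = 5)
  exv <- expected_fad_curve(rec)$expected_count
  tol <- 3 * mc$sd_count / sqrt(1000)
  expect_true(all(abs(mc$mean_count - exv) <= tol + 1e-9))
})

test_that("single-replicate curves are monotone and regions partition", {
  set.seed(17)
  rec <- make_records(data.frame(
    genus = paste0("G", 1:12),
    region = sample(c("tropical", "temperate"), 12, replace = TRUE),
    age_max = runif(12, 3, 11), age_min = 0))
  rec$age_min <- pmax(0, rec$age_max - runif(12, 0, 2))
  rec <- fad_records(rec)
  for (s in 1:5) {
    one <- cumulative_fad_curve(rec, n_reps = 1, seed = s)
    expect_true(all(diff(one$mean_count) >= 0))   # edges decrease in Ma
  }
  if (all(c("tropical", "temperate") %in% rec$region)) {
    tot <- expected_fad_curve(rec)$expected_count
    parts <- expected_fad_curve(rec, region = "tropical")$expected_count +
      expected_fad_curve(rec, region = "temperate")$expected_count
    expect_equal(parts, tot, tolerance = 1e-12)
  }
})

test_that("collections bin by interval midpoint with half-open bins", {
  tab <- data.frame(age_max = 3.5, age_min = 2.5, region = "tropical")
  out <- collections_per_bin(tab)
  expect_equal(out$tropical[out$bin_young_ma == 3], 1)
  expect_equal(sum(out$tropical), 1)
  # empty table: all-zero counts
  empty <- collections_per_bin(data.frame(age_max = numeric(0),
                                          age_min = numeric(0),
                                          region = character(0)))
  expect_true(all(empty$tropical == 0) && all(empty$temperate == 0))
  # same bin, different regions: one count in each series
  two <- collections_per_bin(data.frame(age_max = c(4.2, 4.4),
                                        age_min = c(4.0, 4.0),
                                        region = c("tropical",
                                                   "temperate")))
  expect_equal(two$tropical[two$bin_young_ma == 4], 1)
  expect_equal(two$temperate[two$bin_young_ma == 4], 1)
})

test_that("the packaged synthetic FAD table is valid and determinstic", {
  rec <- synthetic_gabi_fads()
  expect_s3_class(rec, "fad_records")
  expect_true(all(rec$age_max >= rec$age_min))
  expect_true(all(rec$origin_continent != rec$recording_continent))
  c1 <- cumulative_fad_curve(rec, region = "temperate", n_reps = 100,
                             seed = 9)
  c2 <- cumulative_fad_curve(rec, region = "temperate", n_reps = 100,
                             seed = 9)
  expect_identical(c1, c2)
  salma <- salma_boundaries()
  expect_true(all(salma$start_ma > salma$end_ma))
  expect_true(all(diff(salma$start_ma) < 0))
})
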