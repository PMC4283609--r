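# Rarefaction engine shared by the pair and group entry points.
# `sets`: named list of (deduplicated, sorted) genus vectors;
# `targets`: draw count per set. Per replicate, one subsample is drawn
# per DISTINCT (genus set, target) combination, sequentially from the
# current RNG stream: assemblages with identical faunas receive the
# same subsample (their rarefied dissimilarity is exactly 0, as it must
# be for indistinguishable communities), different faunas receive
# independent draws, and an assemblage appearing in several pairs is
# subsampled once per replicate.
rarefied_replicates <- function(sets, targets, pairs, n_reps) {
  keys <- paste0(vapply(sets, paste, "", collapse = "|"), "@", targets)
  uniq <- !duplicated(keys)
  draw_sets <- sets[uniq]
  draw_targets <- targets[uniq]
  slot <- match(keys, keys[uniq])
  vals <- matrix(0, n_reps, nrow(pairs))
  for (r in seq_len(n_reps)) {
    subs <- lapply(seq_along(draw_sets), function(i)
      unique(sample(draw_sets[[i]], draw_targets[i], replace = TRUE)))
    for (p in seq_len(nrow(pairs)))
      vals[r, p] <- bray_curtis_binary(subs[[slot[pairs[p, 1]]]],
                                       subs[[slot[pairs[p, 2]]]])
  }
  vals
}

#' Richness-equalized dissimilarity replicates for one assemblage pair
#'
#' Per replicate, \code{target_richness} genera are drawn with
#' replacement from each assemblage's genus list, duplicates collapse to
#' a presence set, and the binary Bray-Curtis dissimilarity of the two
#' sets is recorded. Subsampling to a common richness removes the bias
#' that richer faunas look more dissimilar simply by having more taxa to
#' not share. Two identical genus lists share each replicate's
#' subsample, so their rarefied dissimilarity is exactly 0.
#'
#' @param x,y character vectors of genus labels
#' @param target_richness number of draws per assemblage (>= 1)
#' @param n_reps number of replicates
#' @param seed integer seed
#' @return numeric vector of \code{n_reps} dissimilarities in [0, 1]
#' @export
rarefied_pair_dissimilarity <- function(x, y, target_richness,
                                        n_reps = 1000, seed = 1L) {
  x <- sort(unique(x)); y <- sort(unique(y))
  if (length(x) == 0 || length(y) == 0)
    stop("genus sets must be non-empty", call. = FALSE)
  if (target_richness < 1)
    stop("target_richness must be >= 1", call. = FALSE)
  old <- restore_rng(seed)
  on.exit(old())
  as.vector(rarefied_replicates(list(x, y),
                                rep(target_richness, 2),
                                matrix(1:2, 1), n_reps))
}

#' Richness-equalized dissimilarity distribution for a group contrast
#'
#' Computes the pooled distribution of rarefied pair dissimilarities for
#' a within-group contrast (all pairs inside one group) or a
#' between-groups contrast (all pairs with one member in each group).
#' The subsampling target is the minimum richness among all assemblages
#' involved in the contrast (\code{rarefy_per_pair = TRUE} instead uses
#' each pair's own minimum).
#'
#' @param m an \code{\link{occurrence_matrix}}
#' @param groups named character vector mapping assemblage -> group label
#' @param contrast one group label (within-group) or two (between-groups)
#' @param n_reps replicates per pair (default 1000)
#' @param seed integer seed
#' @param rarefy_per_pair use per-pair rather than per-subgroup minimum
#'   richness
#' @return list with \code{contrast}, \code{pairs} (two-column matrix of
#'   labels), \code{target_richness}, \code{values} (pooled replicates,
#'   length n_reps x n_pairs), \code{mean}, \code{sd}
#' @export
group_dissimilarity_distribution <- function(m, groups, contrast,
                                             n_reps = 1000, seed = 1L,
                                             rarefy_per_pair = FALSE) {
  stopifnot(inherits(m, "occurrence_matrix"))
  if (!all(names(groups) %in% rownames(m)))
    stop("groups name assemblages absent from the matrix", call. = FALSE)
  if (!length(contrast) %in% 1:2)
    stop("contrast must name one or two groups", call. = FALSE)
  members <- lapply(contrast, function(g) names(groups)[groups == g])
  if (length(contrast) == 1L) {
    if (length(members[[1]]) < 2)
      stop("within-group contrast needs >= 2 assemblages in group '",
           contrast, "'", call. = FALSE)
    prs <- t(utils::combn(members[[1]], 2))
  } else {
    if (any(lengths(members) < 1))
      stop("between-groups contrast needs >= 1 assemblage per group",
         call. = FALSE)
    prs <- as.matrix(expand.grid(members[[1]], members[[2]],
                                 stringsAsFactors = FALSE))
  }
  involved <- unique(c(prs))
  rich <- rowSums(unclass(m))[involved]
  target <- min(rich)
  n_pairs <- nrow(prs)
  sets <- rep(list(NULL), 2 * n_pairs)
  targets <- numeric(2 * n_pairs)
  for (i in seq_len(n_pairs)) {
    tg <- if (rarefy_per_pair)
      min(rich[prs[i, 1]], rich[prs[i, 2]]) else target
    sets[[2 * i - 1]] <- sort(genus_set(m, prs[i, 1]))
    sets[[2 * i]] <- sort(genus_set(m, prs[i, 2]))
    targets[c(2 * i - 1, 2 * i)] <- tg
  }
  old <- restore_rng(seed)
  on.exit(old())
  vals <- rarefied_replicates(sets, targets,
                              cbind(2 * seq_len(n_pairs) - 1,
                                    2 * seq_len(n_pairs)), n_reps)
  list(contrast = paste(contrast, collapse = " vs "),
       pairs = unname(prs), target_richness = unname(target),
       values = as.vector(vals), mean = mean(vals),
       sd = stats::sd(as.vector(vals)))
}

#' Compare group dissimilarity distributions
#'
#' Runs \code{\link{group_dissimilarity_distribution}} for each contrast
#' and Mann-Whitney tests between every pair of contrasts.
#'
#' @param m an \code{\link{occurrence_matrix}}
#' @param groups named character vector mapping assemblage -> group
#' @param contrasts list of contrasts (each one or two group labels)
#' @param n_reps replicates per pair
#' @param seed integer seed
#' @param alternative passed to \code{\link{mann_whitney_u}}
#' @param test_unit observations entering the Mann-Whitney tests:
#'   \code{"pooled"} compares the pooled replicate values (the
#'   resampling procedure's convention; replicates of one pair are
#'   dependent, so p values are anticonservative and should be read as
#'   descriptive); \code{"pair_mean"} compares one mean dissimilarity
#'   per assemblage pair, which keeps the test's size near nominal
#' @return object of class \code{group_comparison}: list(distributions,
#'   summary data.frame, tests data.frame)
#' @export
compare_groups <- function(m, groups, contrasts, n_reps = 1000, seed = 1L,
                           alternative = "two_sided",
                           test_unit = c("pooled", "pair_mean")) {
  test_unit <- match.arg(test_unit)
  dists <- lapply(seq_along(contrasts), function(i)
    group_dissimilarity_distribution(m, groups, contrasts[[i]],
                                     n_reps = n_reps, seed = seed + i))
  labs <- vapply(dists, `[[`, "", "contrast")
  summary <- data.frame(
    contrast = labs,
    n_pairs = vapply(dists, function(d) nrow(d$pairs), 0L),
    target_richness = vapply(dists, `[[`, 0, "target_richness"),
    mean = vapply(dists, `[[`, 0, "mean"),
    sd = vapply(dists, `[[`, 0, "sd"))
  tests <- NULL
  if (length(dists) > 1) {
    obs <- lapply(dists, function(d) {
      if (test_unit == "pooled") d$values else
        colMeans(matrix(d$values, nrow = n_reps))
    })
    cmb <- utils::combn(length(dists), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      mw <- mann_whitney_u(obs[[i1]], obs[[i2]],
                           alternative = alternative)
      data.frame(a = labs[i1], b = labs[i2], U = mw$U, p = mw$p,
                 method = mw$method)
    }))
  }
  structure(list(distributions = dists, summary = summary, tests = tests),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Richness-equalized dissimilarity comparison\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nMann-Whitney contrasts:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U statistic for sample \code{a} versus \code{b} with midrank tie
#' handling. The p value is exact (distribution of U under the null,
#' via the standard recursion) when \code{n_a * n_b <= 400} and there
#' are no ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param a,b numeric sample vectors
#' @param alternative "two_sided" (default), "less" or "greater"
#'   (alternatives on the distribution of \code{a} relative to \code{b})
#' @return list(U, p, method)
#' @export
mann_whitney_u <- function(a, b,
                           alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na * nb <= 400) {
    # exact tail of the null U distribution (base R's pwilcox)
    p <- switch(alternative,
      less = stats::pwilcox(u, na, nb),
      greater = stats::pwilcox(u - 1, na, nb, lower.tail = FALSE),
      two_sided = {
        if (u > na * nb / 2)
          min(1, 2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE))
        else
          min(1, 2 * stats::pwilcox(u, na, nb))
      })
    method <- "exact"
  } else {
    mu <- na * nb / 2
    nt <- na + nb
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 *
      ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    sigma <- sqrt(sigma2)
    z_less <- (u + 0.5 - mu) / sigma
    z_greater <- (u - 0.5 - mu) / sigma
    p <- switch(alternative,
      less = stats::pnorm(z_less),
      greater = stats::pnorm(z_greater, lower.tail = FALSE),
      two_sided = {
        z <- max(0, abs(u - mu) - 0.5) / sigma
        min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
      })
    method <- "normal_approx"
  }
  list(U = u, p = p, method = method)
}
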