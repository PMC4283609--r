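#' Binary Bray-Curtis dissimilarity between two genus sets
#'
#' The presence/absence form of the Bray-Curtis index,
#' \eqn{(b + c) / (2a + b + c)} with \eqn{a} shared genera and
#' \eqn{b, c} the genera unique to each assemblage. Equal to one minus
#' the Sorensen similarity; reaches 1 when no taxa are shared.
#'
#' @param x,y character vectors of genus labels (duplicates ignored)
#' @return dissimilarity in [0, 1]
#' @export
bray_curtis_binary <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 || length(y) == 0)
    stop("genus sets must be non-empty", call. = FALSE)
  a <- length(intersect(x, y))
  b <- length(x) - a
  c_ <- length(y) - a
  (b + c_) / (2 * a + b + c_)
}

#' Pairwise binary Bray-Curtis dissimilarity matrix
#'
#' @param m an \code{\link{occurrence_matrix}} with at least 2 assemblages
#' @return a \code{dissimilarity_matrix}: symmetric numeric matrix in
#'   [0, 1] with zero diagonal and assemblage dimnames
#' @export
pairwise_dissimilarity <- function(m) {
  stopifnot(inherits(m, "occurrence_matrix"))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 assemblages", call. = FALSE)
  inc <- unclass(m)
  # a = shared, row sums give a + unique; vectorized via crossprod
  shared <- tcrossprod(inc)            # n x n, diagonal = richness
  rich <- diag(shared)
  denom <- outer(rich, rich, "+")      # 2a + b + c
  d <- (denom - 2 * shared) / denom
  diag(d) <- 0
  dissimilarity_matrix(d)
}

#' Construct/validate a dissimilarity matrix
#'
#' @param d symmetric numeric matrix, entries in [0, 1], zero diagonal,
#'   with matching dimnames
#' @return the matrix, classed \code{dissimilarity_matrix}
#' @export
dissimilarity_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("dissimilarity matrix needs labels",
                                 call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("dissimilarity matrix diagonal must be zero", call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12))
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  diag(d) <- 0
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' UPGMA (average-linkage) clustering of a dissimilarity matrix
#'
#' Unweighted pair-group average linkage: the merge height of two
#' clusters is the arithmetic mean of all between-cluster
#' dissimilarities. Ties between candidate merges are broken
#' deterministically by choosing the pair whose concatenated sorted
#' member labels sort lexicographically first, so the dendrogram is
#' identical across platforms.
#'
#' @param d a \code{\link{dissimilarity_matrix}} (n >= 2)
#' @return an object of classes \code{upgma}/\code{hclust} (merge,
#'   height, labels, order), so \code{stats::cophenetic}, \code{plot} and
#'   \code{ape::as.phylo} apply directly
#' @export
upgma <- function(d) {
  if (!inherits(d, "dissimilarity_matrix")) d <- dissimilarity_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 labels to cluster", call. = FALSE)
  labels <- rownames(d)
  # active clusters: list of member leaf indices; id in hclust convention
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  d0 <- unclass(d)
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL; best_h <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        h <- mean(d0[members[[i]], members[[j]]])
        key <- paste(sort(labels[c(members[[i]], members[[j]])]),
                     collapse = "|")
        if (h < best_h - 1e-12 ||
            (abs(h - best_h) <= 1e-12 && key < best_key)) {
          best <- c(i, j); best_h <- h; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    # hclust child convention: singletons (negative) first, by leaf
    # index; clusters after, by merge step
    pair <- c(ids[[i]], ids[[j]])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best_h
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
  }
  structure(list(merge = merge, height = height,
                 order = dendro_order(merge, n), labels = labels,
                 method = "upgma", call = match.call(),
                 dist.method = "binary bray-curtis"),
            class = c("upgma", "hclust"))
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
dendro_order <- function(merge, n) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1]), walk(merge[id, 2]))
  }
  walk(n - 1L)
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric layout: each branch length is half the difference of the
#' merge heights it spans, so the leaf-to-root path equals half the
#' cophenetic height (two leaves merged at 0.5 give "(A:0.25,B:0.25);").
#' Branch lengths are written with 6 significant digits.
#'
#' @param t an \code{hclust}-like tree (e.g. from \code{\link{upgma}})
#' @return a Newick string
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "hclust"))
  ape::write.tree(ape::as.phylo(t), digits = 6)
}

#' First bipartition of a dendrogram
#'
#' The two groups of leaves separated by the root: a convenience for
#' asking whether the deepest split recovers a known partition (e.g.
#' biogeographic provinces).
#'
#' @param t an \code{hclust}-like tree
#' @return list of two character vectors of leaf labels
#' @export
first_bipartition <- function(t) {
  stopifnot(inherits(t, "hclust"))
  n <- length(t$labels)
  leaves <- function(id) {
    if (id < 0) return(-id)
    c(leaves(t$merge[id, 1]), leaves(t$merge[id, 2]))
  }
  root <- n - 1L
  list(t$labels[leaves(t$merge[root, 1])],
       t$labels[leaves(t$merge[root, 2])])
}

#' Distance decay of faunal similarity
#'
#' Tabulates every assemblage pair's great-circle distance and
#' dissimilarity, classifies pairs by biome (tropical-tropical,
#' temperate-temperate, tropical-temperate), and quantifies the
#' association between the geographic and faunal distance matrices with
#' a Mantel test (Pearson r, permutation p).
#'
#' @param d a \code{\link{dissimilarity_matrix}}
#' @param meta an \code{assemblage_metadata} data.frame covering all labels
#' @param within_epoch_only if TRUE (default), cross-epoch pairs are
#'   excluded from the pair table and the Mantel matrices
#' @param permutations number of Mantel permutations (default 999), or
#'   \code{"exact"} to enumerate all label permutations (n <= 7)
#' @param seed integer seed for the permutation draw
#' @return list with \code{pairs} (data.frame: a, b, km, dissimilarity,
#'   pair_class, epoch_pair), \code{mantel_r}, \code{mantel_p},
#'   \code{degenerate} (TRUE when a matrix has zero variance, in which
#'   case r/p are NA)
#' @export
distance_decay <- function(d, meta, within_epoch_only = TRUE,
                           permutations = 999, seed = 1L) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  labels <- rownames(d)
  missing <- setdiff(labels, meta$assemblage_id)
  if (length(missing))
    stop("metadata missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(labels, meta$assemblage_id), ]
  if (anyNA(meta$latitude) || anyNA(meta$longitude))
    stop("missing coordinates for: ",
         paste(meta$assemblage_id[is.na(meta$latitude) |
                                  is.na(meta$longitude)], collapse = ", "),
         call. = FALSE)
  n <- length(labels)
  km <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    km[i, j] <- km[j, i] <- great_circle_distance(
      c(meta$latitude[i], meta$longitude[i]),
      c(meta$latitude[j], meta$longitude[j]))
  }
  keep <- matrix(TRUE, n, n)
  if (within_epoch_only)
    keep <- outer(meta$epoch, meta$epoch, "==")
  ut <- upper.tri(d) & keep
  idx <- which(ut, arr.ind = TRUE)
  cls <- function(i, j) {
    b <- sort(c(meta$biome[i], meta$biome[j]))
    paste(b, collapse = "-")
  }
  pairs <- data.frame(
    a = labels[idx[, 1]], b = labels[idx[, 2]],
    km = km[ut], dissimilarity = unclass(d)[ut],
    pair_class = mapply(cls, idx[, 1], idx[, 2]),
    epoch_pair = paste(meta$epoch[idx[, 1]], meta$epoch[idx[, 2]],
                       sep = "/"),
    stringsAsFactors = FALSE)
  mt <- mantel_test(unclass(d), km, mask = if (within_epoch_only) keep,
                    permutations = permutations, seed = seed)
  c(list(pairs = pairs), mt)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the (optionally masked) upper triangles, with
#' significance from random row/column permutations of one matrix, or
#' exact enumeration of all n! label permutations when requested.
#' The p value counts permutations with r at least as large as observed
#' (one-sided, positive association), including the identity.
#'
#' @param x,y symmetric matrices with identical dimensions
#' @param mask optional logical matrix; only pairs with \code{mask} TRUE
#'   enter the correlation
#' @param permutations count (p = (1 + #{r* >= r}) / (1 + permutations)),
#'   or \code{"exact"}
#' @param seed integer seed
#' @return list(mantel_r, mantel_p, degenerate)
#' @export
mantel_test <- function(x, y, mask = NULL, permutations = 999, seed = 1L) {
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  sel <- function(m, perm) {
    mp <- m[perm, perm]
    mp[upper.tri(mp) & mask]
  }
  v1 <- sel(x, seq_len(n)); v2 <- sel(y, seq_len(n))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    return(list(mantel_r = NA_real_, mantel_p = NA_real_,
                degenerate = TRUE))
  r_obs <- stats::cor(v1, v2)
  stat <- function(perm) {
    v <- sel(x, perm)
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, v2)
  }
  if (identical(permutations, "exact")) {
    if (n > 7) stop("exact enumeration limited to n <= 7", call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, 0)
    p <- mean(rs >= r_obs - 1e-12, na.rm = TRUE)
  } else {
    old <- restore_rng(seed)
    on.exit(old())
    idn <- seq_len(n)
    rs <- replicate(permutations, {
      repeat {
        perm <- sample.int(n)
        if (!identical(perm, idn)) break
      }
      stat(perm)
    })
    p <- (1 + sum(rs >= r_obs - 1e-12, na.rm = TRUE)) / (1 + permutations)
  }
  list(mantel_r = r_obs, mantel_p = p, degenerate = FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) for (pos in 0:(n - 1)) {
    k <- k + 1
    out[[k]] <- as.integer(append(p, n, after = pos))
  }
  out
}

# seed the RNG for a reproducible block, returning a restore function
restore_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
  }
}
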