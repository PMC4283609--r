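#' Construct a collection-level incidence table
#'
#' Collections are individual geographic/stratigraphic sampling points;
#' accumulation curves measure how genus richness grows as collections
#' are added, i.e. how far sampling is from exhausting the fauna.
#'
#' @param incidence binary matrix, collections in rows, genera in columns
#' @return object of class \code{collection_incidence}
#' @export
collection_incidence <- function(incidence) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (nrow(incidence) < 1) stop("need at least one collection",
                                call. = FALSE)
  if (!all(incidence %in% c(0, 1)))
    stop("incidence entries must be 0 or 1", call. = FALSE)
  storage.mode(incidence) <- "integer"
  if (is.null(rownames(incidence)))
    rownames(incidence) <- paste0("coll", seq_len(nrow(incidence)))
  structure(incidence, class = c("collection_incidence", "matrix", "array"))
}

#' Read a collection incidence table from a long file
#'
#' @param path CSV/TSV with columns (collection_id, genus)
#' @param drop_empty drop collections with no genus records (default
#'   FALSE: empty collections legitimately stall the curve)
#' @return a \code{\link{collection_incidence}}
#' @export
read_collections <- function(path, drop_empty = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  inc <- table(factor(df[[1]], levels = unique(df[[1]])),
               factor(df[[2]], levels = unique(df[[2]])))
  inc <- matrix(pmin(unclass(inc), 1L), nrow = nrow(inc),
                dimnames = list(unique(df[[1]]), unique(df[[2]])))
  if (drop_empty) inc <- inc[rowSums(inc) > 0, , drop = FALSE]
  collection_incidence(inc)
}

#' Genus accumulation curve, random method
#'
#' For each of \code{n_perm} random orderings of the collections, the
#' cumulative number of distinct genera is recorded at every step; the
#' curve reports per-step mean, standard deviation, and a 95% interval
#' (mean +/- 1.96 sd by default, permutation quantiles with
#' \code{ci = "quantile"}).
#'
#' @param c a \code{\link{collection_incidence}}
#' @param n_perm number of random orderings (>= 2)
#' @param seed integer seed
#' @param ci "normal" (mean +/- 1.96 sd) or "quantile" (2.5/97.5%)
#' @return data.frame of class \code{accumulation_curve}: steps,
#'   mean_richness, sd_richness, ci_low, ci_high
#' @export
accumulation_random <- function(c, n_perm = 1000, seed = 1L,
                                ci = c("normal", "quantile")) {
  ci <- match.arg(ci)
  stopifnot(inherits(c, "collection_incidence"))
  if (n_perm < 2) stop("n_perm must be >= 2", call. = FALSE)
  n <- nrow(c)
  old <- restore_rng(seed)
  on.exit(old())
  inc <- unclass(c)
  richness <- matrix(0L, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- matrix(FALSE, 1, ncol(inc))
    cum <- integer(n)
    acc <- logical(ncol(inc))
    for (k in seq_len(n)) {
      acc <- acc | (inc[ord[k], ] == 1L)
      cum[k] <- sum(acc)
    }
    richness[p, ] <- cum
  }
  m <- colMeans(richness)
  s <- apply(richness, 2, stats::sd)
  if (ci == "normal") {
    lo <- m - 1.96 * s; hi <- m + 1.96 * s
  } else {
    lo <- apply(richness, 2, stats::quantile, 0.025)
    hi <- apply(richness, 2, stats::quantile, 0.975)
  }
  structure(data.frame(steps = seq_len(n), mean_richness = m,
                       sd_richness = s, ci_low = lo, ci_high = hi),
            class = c("accumulation_curve", "data.frame"))
}

#' Exact expected genus accumulation curve
#'
#' Closed-form expectation of the random method: with \eqn{N}
#' collections of which \eqn{n_g} contain genus \eqn{g}, the expected
#' richness after \eqn{k} random collections is
#' \eqn{E[S_k] = \sum_g (1 - {N-n_g \choose k} / {N \choose k})}.
#'
#' @param c a \code{\link{collection_incidence}}
#' @return numeric vector of expected richness at steps 1..N
#' @export
accumulation_exact <- function(c) {
  stopifnot(inherits(c, "collection_incidence"))
  inc <- unclass(c)
  n <- nrow(inc)
  ng <- colSums(inc)
  vapply(seq_len(n), function(k) {
    miss <- ifelse(n - ng >= k,
                   exp(lchoose(n - ng, k) - lchoose(n, k)), 0)
    sum(1 - miss)
  }, 0)
}
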