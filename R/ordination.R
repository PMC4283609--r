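#' Weighted monotone (isotonic) regression by pool-adjacent-violators
#'
#' Least-squares non-decreasing fit of \code{targets} taken in the
#' sequence given by \code{order}; the fitted values are returned in the
#' original positions. This is the regression step of Kruskal's
#' nonmetric scaling: configuration distances are replaced by the
#' closest vector that respects the rank order of the dissimilarities.
#'
#' @param targets numeric vector
#' @param order integer permutation giving the processing sequence
#'   (default: natural order)
#' @param weights non-negative weights, same length
#' @return fitted vector, non-decreasing along \code{order}
#' @export
monotone_regression <- function(targets, order = seq_along(targets),
                                weights = rep(1, length(targets))) {
  stopifnot(length(order) == length(targets),
            length(weights) == length(targets))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  y <- targets[order]
  w <- weights[order]
  n <- length(y)
  if (n == 0) return(targets)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      tw <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- if (tw > 0)
        (val[nb - 1L] * wt[nb - 1L] + val[nb] * wt[nb]) / tw else
        (val[nb - 1L] + val[nb]) / 2
      wt[nb - 1L] <- tw
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  fit_sorted <- rep(val[seq_len(nb)], sz[seq_len(nb)])
  fit <- numeric(n)
  fit[order] <- fit_sorted
  fit
}

#' Kruskal stress-1 of a configuration
#'
#' \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}} where
#' \eqn{d} are configuration distances and \eqn{\hat d} their monotone
#' regression onto the rank order of the dissimilarities (primary tie
#' treatment: tied dissimilarities are processed in order of the current
#' configuration distances, so ties impose no constraint).
#'
#' @param dissimilarities vectorized upper-triangle dissimilarities
#' @param config_dist configuration distances, same length and pair order
#' @return stress-1 in [0, 1]
#' @export
stress1 <- function(dissimilarities, config_dist) {
  stopifnot(length(dissimilarities) == length(config_dist),
            length(config_dist) >= 1)
  if (all(config_dist == 0))
    stop("degenerate configuration: all distances zero", call. = FALSE)
  ord <- order(dissimilarities, config_dist)
  dhat <- monotone_regression(config_dist, ord)
  sqrt(sum((config_dist - dhat)^2) / sum(config_dist^2))
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Multi-start NMDS: each random start is refined by alternating
#' SMACOF-style majorization (Guttman transform toward the current
#' disparities) with monotone regression of the configuration distances
#' onto the dissimilarity ranks, until the relative stress change drops
#' below \code{tol} or \code{max_iter} iterations. The best (lowest
#' final stress) configuration is centered, rotated to its principal
#' axes, and sign-fixed (the largest-magnitude coordinate on each axis
#' is positive) so results are comparable across platforms. Identical
#' seed and input give bit-identical output.
#'
#' @param d a \code{\link{dissimilarity_matrix}} (n >= 3)
#' @param k number of dimensions (default 2)
#' @param n_starts random starts (default 1000)
#' @param seed integer seed
#' @param tol relative stress-change convergence tolerance
#' @param max_iter maximum refinement iterations per start
#' @return an object of class \code{nmds}: list(points, stress,
#'   n_starts, best_start_index, converged, trajectory, k)
#' @export
nmds_fit <- function(d, k = 2, n_starts = 1000, seed = 42L,
                     tol = 1e-6, max_iter = 500) {
  if (!inherits(d, "dissimilarity_matrix")) d <- dissimilarity_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("NMDS needs at least 3 points", call. = FALSE)
  delta <- unclass(d)[upper.tri(d)]
  degenerate <- (stats::sd(delta) == 0)
  if (degenerate)
    warning("all dissimilarities equal: configuration is arbitrary",
            call. = FALSE)
  old <- restore_rng(seed)
  on.exit(old())
  inits <- lapply(seq_len(n_starts),
                  function(i) matrix(stats::rnorm(n * k), n, k))
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- nmds_refine(delta, inits[[s]], n, k, tol, max_iter)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$start <- s
    }
  }
  x <- scale(best$x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- sv$u %*% diag(sv$d, k, k)
  for (j in seq_len(k)) {
    top <- which.max(abs(x[, j]))
    if (x[top, j] < 0) x[, j] <- -x[, j]
  }
  dimnames(x) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(points = x, stress = best$stress, n_starts = n_starts,
                 best_start_index = best$start,
                 converged = best$converged,
                 trajectory = best$trajectory, k = k,
                 degenerate = degenerate),
            class = "nmds")
}

# one SMACOF/PAVA refinement from a given start configuration
nmds_refine <- function(delta, x, n, k, tol, max_iter) {
  dist_vec <- function(x) {
    dx <- as.matrix(stats::dist(x))
    dx[upper.tri(dx)]
  }
  s_prev <- Inf
  traj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cd <- dist_vec(x)
    if (all(cd == 0)) break
    ord <- order(delta, cd)
    dhat <- monotone_regression(cd, ord)
    s <- sqrt(sum((cd - dhat)^2) / sum(cd^2))
    traj <- c(traj, s)
    if (is.finite(s_prev) &&
        (s_prev - s) < tol * max(s_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    s_prev <- s
    # normalize disparities so the Guttman transform preserves scale
    dhat <- dhat * sqrt(sum(cd^2) / sum(dhat^2))
    # Guttman transform
    b <- matrix(0, n, n)
    ratio <- ifelse(cd > 0, dhat / cd, 0)
    b[upper.tri(b)] <- -ratio
    b <- b + t(b)
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
  }
  list(x = x, stress = if (length(traj)) traj[length(traj)] else NA_real_,
       trajectory = traj, converged = converged)
}

#' @export
print.nmds <- function(x, ...) {
  cat("NMDS (", x$k, " dimensions, ", x$n_starts, " starts)\n", sep = "")
  cat("Best stress-1:", format(x$stress, digits = 4),
      "(start", x$best_start_index,
      if (x$converged) "converged)" else "iteration cap)", "\n")
  invisible(x)
}
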