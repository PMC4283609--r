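#' Province model for synthetic occurrence data
#'
#' Describes biome-structured genus pools with epoch turnover, the
#' statistical skeleton behind a compilation of Neogene assemblages:
#' two biogeographic provinces (tropical/temperate) whose genus pools
#' share a fraction \code{overlap} of genera, per-epoch pool turnover
#' (a fraction of each pool replaced by new genera each epoch, which is
#' what makes assemblages group primarily by age), heterogeneous
#' per-assemblage richness, and imperfect per-collection detection.
#'
#' Defaults mirror the study design: provinces tropical/temperate over
#' three epochs with the 2/2, 2/5, 0/2 assemblage layout of the
#' thirteen-assemblage compilation, pools of 120 genera, 10% shared
#' between provinces, half the pool turning over each epoch, assemblage
#' richness 10-45 genera, and 20 collections per assemblage detecting
#' each locally present genus with probability 0.15 (so observed
#' richness visibly undersamples the fauna, as the accumulation curves
#' of real tropical assemblages do).
#'
#' @param n_provinces number of provinces (named after biomes when 2)
#' @param pool_size genera per province pool
#' @param overlap fraction of each pool shared between provinces [0, 1]
#' @param epochs character vector of epoch labels
#' @param turnover fraction of each pool replaced at each epoch step
#' @param assemblages_per_province integer matrix provinces x epochs (or
#'   a single count used everywhere)
#' @param richness_range length-2 integer range of true assemblage richness
#' @param collections_per_assemblage collections sampled per assemblage
#' @param detection_prob per-genus per-collection detection probability
#' @return validated list of class \code{province_model}
#' @export
province_model <- function(n_provinces = 2,
                           pool_size = 120,
                           overlap = 0.1,
                           epochs = c("middle_miocene", "late_miocene",
                                      "pliocene"),
                           turnover = 0.5,
                           assemblages_per_province =
                             rbind(tropical = c(2, 2, 0),
                                   temperate = c(2, 5, 2)),
                           richness_range = c(10, 45),
                           collections_per_assemblage = 20,
                           detection_prob = 0.15) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]",
                                       call. = FALSE)
  if (turnover < 0 || turnover > 1) stop("turnover must be in [0, 1]",
                                         call. = FALSE)
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must be in (0, 1]", call. = FALSE)
  if (length(assemblages_per_province) == 1)
    assemblages_per_province <- matrix(assemblages_per_province,
                                       n_provinces, length(epochs))
  if (is.null(rownames(assemblages_per_province)))
    rownames(assemblages_per_province) <-
      if (n_provinces == 2) c("tropical", "temperate") else
        paste0("province", seq_len(n_provinces))
  stopifnot(nrow(assemblages_per_province) == n_provinces,
            ncol(assemblages_per_province) == length(epochs))
  if (max(richness_range) > pool_size)
    stop("richness_range exceeds pool_size", call. = FALSE)
  structure(list(n_provinces = n_provinces, pool_size = pool_size,
                 overlap = overlap, epochs = epochs, turnover = turnover,
                 assemblages_per_province = assemblages_per_province,
                 richness_range = richness_range,
                 collections_per_assemblage = collections_per_assemblage,
                 detection_prob = detection_prob),
            class = "province_model")
}

#' Simulate biome-structured occurrence data
#'
#' Builds province genus pools with the stated between-province overlap,
#' applies per-epoch turnover, draws each assemblage's true genus list
#' from its province-epoch pool, and observes it through per-collection
#' binomial detection (observed incidence = union of collection
#' detections). Genera never detected anywhere are absent from the
#' observed matrix. Assemblages whose collections detect nothing are
#' re-observed until at least one genus is seen, since an empty fauna is
#' not a usable assemblage.
#'
#' @param model a \code{\link{province_model}}
#' @param seed integer seed (same seed, same output, bit for bit)
#' @return list: \code{occurrences} (\code{occurrence_matrix}),
#'   \code{metadata} (\code{assemblage_metadata}), \code{collections}
#'   (named list of \code{collection_incidence}, one per assemblage),
#'   \code{truth} (province pools per epoch and true genus lists)
#' @export
simulate_occurrences <- function(model, seed = 1L) {
  stopifnot(inherits(model, "province_model"))
  old <- restore_rng(seed)
  on.exit(old())
  npool <- model$pool_size
  n_shared <- round(model$overlap * npool)
  gid <- local({
    counter <- 0L
    function(n) {
      labs <- sprintf("G%05d", counter + seq_len(n))
      counter <<- counter + n
      labs
    }
  })
  provinces <- rownames(model$assemblages_per_province)
  # epoch 1 pools: one shared block + per-province unique blocks
  shared <- gid(n_shared)
  pools <- lapply(provinces, function(p) c(shared, gid(npool - n_shared)))
  names(pools) <- provinces
  truth <- list(pools = list(), assemblages = list())
  inc_rows <- list()
  meta_rows <- list()
  collections <- list()
  for (e in seq_along(model$epochs)) {
    if (e > 1) {
      # turnover: replace a fraction of the shared block (jointly, to
      # keep overlap) and of each unique block (independently)
      n_new_shared <- round(model$turnover * n_shared)
      old_shared <- shared
      keep_shared <- sample(shared, n_shared - n_new_shared)
      shared <- c(keep_shared, gid(n_new_shared))
      pools <- lapply(pools, function(pool) {
        uniq <- setdiff(pool, old_shared)
        n_new <- round(model$turnover * length(uniq))
        c(shared, sample(uniq, length(uniq) - n_new), gid(n_new))
      })
    }
    truth$pools[[model$epochs[e]]] <- pools
    for (p in provinces) {
      n_asm <- model$assemblages_per_province[p, e]
      for (a in seq_len(n_asm)) {
        label <- sprintf("%s_%s_%d", p, model$epochs[e], a)
        rr <- model$richness_range
        rich <- if (rr[1] == rr[2]) rr[1] else sample(seq(rr[1], rr[2]), 1)
        true_list <- sample(pools[[p]], rich)
        truth$assemblages[[label]] <- true_list
        ncoll <- model$collections_per_assemblage
        repeat {
          det <- matrix(stats::rbinom(ncoll * rich, 1,
                                      model$detection_prob),
                        ncoll, rich,
                        dimnames = list(paste0(label, "_c", seq_len(ncoll)),
                                        true_list))
          if (any(det == 1L)) break
        }
        collections[[label]] <- collection_incidence(det)
        observed <- true_list[colSums(det) > 0]
        inc_rows[[label]] <- observed
        lat <- if (p == "tropical") stats::runif(1, -15, 11) else
          stats::runif(1, -41, -19)
        meta_rows[[label]] <- data.frame(
          assemblage_id = label, latitude = lat,
          longitude = stats::runif(1, -76, -58),
          biome = if (p %in% c("tropical", "temperate")) p else "tropical",
          epoch = model$epochs[e], stringsAsFactors = FALSE)
      }
    }
  }
  all_genera <- sort(unique(unlist(inc_rows)))
  inc <- t(vapply(inc_rows, function(g) as.integer(all_genera %in% g),
                  integer(length(all_genera))))
  colnames(inc) <- all_genera
  list(occurrences = occurrence_matrix(inc),
       metadata = assemblage_metadata(do.call(rbind, meta_rows)),
       collections = collections,
       truth = truth)
}

#' Immigration model for synthetic FAD records
#'
#' Emulates a curated interchange FAD compilation: per direction,
#' \code{n_migrants} true first-appearance ages drawn uniformly in
#' \code{true_fad_range}, each reported only as an interval of width
#' drawn from \code{interval_width_range} centered on the true age
#' (clipped at 0 Ma), recorded in the tropics with probability
#' \code{region_mix}.
#'
#' @param n_migrants immigrants per direction (NA to SA and SA to NA)
#' @param true_fad_range Ma interval for true first appearances
#'   (default c(10, 1))
#' @param interval_width_range Ma range of reported interval widths
#' @param region_mix probability a record falls in the tropics
#' @return list of class \code{immigration_model}
#' @export
immigration_model <- function(n_migrants = 20,
                              true_fad_range = c(10, 1),
                              interval_width_range = c(0.2, 1.5),
                              region_mix = 0.35) {
  if (any(interval_width_range < 0))
    stop("interval widths must be >= 0", call. = FALSE)
  if (region_mix < 0 || region_mix > 1)
    stop("region_mix must be in [0, 1]", call. = FALSE)
  structure(list(n_migrants = n_migrants,
                 true_fad_range = sort(true_fad_range, decreasing = TRUE),
                 interval_width_range = interval_width_range,
                 region_mix = region_mix),
            class = "immigration_model")
}

#' Simulate FAD records with age-interval uncertainty
#'
#' @param model an \code{\link{immigration_model}}
#' @param seed integer seed
#' @return list: \code{records} (a \code{fad_records} data.frame),
#'   \code{truth} (data.frame with the true ages)
#' @export
simulate_fads <- function(model, seed = 1L) {
  stopifnot(inherits(model, "immigration_model"))
  old <- restore_rng(seed)
  on.exit(old())
  dirs <- data.frame(origin = c("NA", "SA"), recording = c("SA", "NA"))
  rows <- lapply(1:2, function(d) {
    n <- model$n_migrants
    true_age <- stats::runif(n, model$true_fad_range[2],
                             model$true_fad_range[1])
    w <- stats::runif(n, model$interval_width_range[1],
                      model$interval_width_range[2])
    data.frame(
      genus = sprintf("M%s%03d", dirs$origin[d], seq_len(n)),
      origin_continent = dirs$origin[d],
      recording_continent = dirs$recording[d],
      region = ifelse(stats::runif(n) < model$region_mix,
                      "tropical", "temperate"),
      age_max = true_age + w / 2,
      age_min = pmax(0, true_age - w / 2),
      true_age = true_age,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  truth <- df[, c("genus", "true_age", "region", "origin_continent")]
  df$true_age <- NULL
  list(records = fad_records(df), truth = truth)
}
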