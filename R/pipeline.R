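#' Validate a pipeline run configuration
#'
#' A run configuration lists the inputs and stochastic settings of the
#' full workflow: occurrence table (+ layout), assemblage metadata,
#' FAD record table, optional collection tables, replicate counts, NMDS
#' starts, master seed, and output directory. Accepts a list or a path
#' to a YAML file with the same fields.
#'
#' @param config list or YAML path. Fields: \code{occurrences} (path),
#'   \code{layout} ("wide"/"long"), \code{metadata} (path), \code{fads}
#'   (path, optional), \code{collections} (named list of long-table
#'   paths, optional), \code{group_by} ("biome", default), \code{epoch}
#'   (optional epoch filter for the group comparison), \code{n_reps},
#'   \code{n_starts}, \code{n_perm}, \code{seed}, \code{out_dir}
#' @return validated list of class \code{run_config}
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(layout = "wide", group_by = "biome", epoch = NULL,
                   n_reps = 1000, n_starts = 100, n_perm = 999,
                   seed = 1L, fads = NULL, collections = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  for (nm in c("occurrences", "metadata", "out_dir"))
    if (is.null(config[[nm]]))
      stop("config missing required field: ", nm, call. = FALSE)
  for (nm in c("n_reps", "n_starts", "n_perm")) {
    config[[nm]] <- as.integer(config[[nm]])
    if (config[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  paths <- c(config$occurrences, config$metadata, config$fads,
             unlist(config$collections))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- read inputs,
#' dissimilarity, clustering (UPGMA + Newick), NMDS, distance decay,
#' group comparison, accumulation (if collection tables are given), FAD
#' curves (if a FAD table is given) -- writing flat CSV/JSON outputs and
#' a JSON run manifest with input digests, per-stage status, seeds and
#' wall-clock times. Per-stage seeds are derived from the master seed by
#' fixed offsets, so a stage rerun in isolation reproduces its numbers.
#' A stage is skipped when its outputs already exist and no upstream
#' stage ran in this invocation; deleting one stage's outputs therefore
#' regenerates only that stage and its dependents.
#'
#' @param config a \code{\link{run_config}} (or list/path coercible to one)
#' @param force rerun every stage regardless of existing outputs
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json})
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  occ <- read_occurrences(cfg$occurrences, cfg$layout)
  meta <- read_metadata(cfg$metadata)
  stage_seed <- function(i) cfg$seed + 1000L * i
  manifest <- list(
    inputs = as.list(tools::md5sum(c(cfg$occurrences, cfg$metadata,
                                     cfg$fads))),
    seed = cfg$seed, stages = list())
  ran <- character(0)
  out <- function(...) file.path(cfg$out_dir, ...)
  stage <- function(name, outputs, depends, fun) {
    t0 <- proc.time()[["elapsed"]]
    needed <- force || !all(file.exists(outputs)) ||
      any(depends %in% ran)
    if (needed) {
      ok <- tryCatch({fun(); TRUE},
                     error = function(e)
                       stop("stage '", name, "' failed: ",
                            conditionMessage(e), call. = FALSE))
      ran <<- c(ran, name)
    }
    manifest$stages[[name]] <<- list(
      status = if (needed) "ran" else "skipped",
      outputs = as.list(tools::md5sum(outputs)),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  stage("dissimilarity", out("dissimilarity.csv"), character(0), function() {
    d <- pairwise_dissimilarity(occ)
    utils::write.csv(as.data.frame(unclass(d)), out("dissimilarity.csv"))
  })
  read_d <- function() {
    m <- as.matrix(utils::read.csv(out("dissimilarity.csv"),
                                   row.names = 1, check.names = FALSE))
    dissimilarity_matrix(m)
  }
  stage("cluster", out("dendrogram.nwk"), "dissimilarity", function() {
    writeLines(to_newick(upgma(read_d())), out("dendrogram.nwk"))
  })
  stage("nmds", out(c("nmds_coordinates.csv", "nmds_report.json")),
        "dissimilarity", function() {
    fit <- nmds_fit(read_d(), k = 2, n_starts = cfg$n_starts,
                    seed = stage_seed(2))
    utils::write.csv(data.frame(assemblage = rownames(fit$points),
                                fit$points, check.names = FALSE),
                     out("nmds_coordinates.csv"), row.names = FALSE)
    jsonlite::write_json(list(stress = fit$stress,
                              n_starts = fit$n_starts,
                              best_start_index = fit$best_start_index,
                              converged = fit$converged),
                         out("nmds_report.json"), auto_unbox = TRUE,
                         digits = NA)
  })
  stage("distance_decay", out("distance_decay.csv"), "dissimilarity",
        function() {
    dd <- distance_decay(read_d(), meta, within_epoch_only = TRUE,
                         permutations = cfg$n_perm, seed = stage_seed(3))
    utils::write.csv(cbind(dd$pairs, mantel_r = dd$mantel_r,
                           mantel_p = dd$mantel_p),
                     out("distance_decay.csv"), row.names = FALSE)
  })
  stage("group_comparison", out("group_comparison.csv"), character(0),
        function() {
    grp_meta <- meta
    if (!is.null(cfg$epoch))
      grp_meta <- grp_meta[grp_meta$epoch == cfg$epoch, ]
    grp_meta <- grp_meta[grp_meta$assemblage_id %in% rownames(occ), ]
    groups <- stats::setNames(grp_meta[[cfg$group_by]],
                              grp_meta$assemblage_id)
    keep_occ <- occurrence_subset(occ, names(groups))
    lv <- unique(groups)
    contrasts <- c(as.list(lv), if (length(lv) == 2) list(lv))
    gc <- compare_groups(keep_occ, groups, contrasts,
                         n_reps = cfg$n_reps, seed = stage_seed(4))
    utils::write.csv(gc$summary, out("group_comparison.csv"),
                     row.names = FALSE)
    if (!is.null(gc$tests))
      utils::write.csv(gc$tests, out("group_tests.csv"),
                       row.names = FALSE)
  })
  if (!is.null(cfg$collections)) {
    stage("accumulation",
          out(paste0("accumulation_", names(cfg$collections), ".csv")),
          character(0), function() {
      for (nm in names(cfg$collections)) {
        curve <- accumulation_random(
          read_collections(cfg$collections[[nm]]),
          n_perm = cfg$n_perm, seed = stage_seed(5))
        utils::write.csv(curve, out(paste0("accumulation_", nm, ".csv")),
                         row.names = FALSE)
      }
    })
  }
  if (!is.null(cfg$fads)) {
    stage("fad_curves", out(c("fad_curve_tropical.csv",
                              "fad_curve_temperate.csv")),
          character(0), function() {
      rec <- read_fad_records(cfg$fads)
      for (reg in c("tropical", "temperate")) {
        curve <- cumulative_fad_curve(rec, region = reg,
                                      n_reps = cfg$n_reps,
                                      seed = stage_seed(6))
        utils::write.csv(curve, out(paste0("fad_curve_", reg, ".csv")),
                         row.names = FALSE)
      }
    })
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Subset an occurrence matrix to chosen assemblages
#'
#' Drops genera left without any occurrence.
#'
#' @param m an \code{\link{occurrence_matrix}}
#' @param assemblages labels to keep
#' @return an \code{occurrence_matrix}
#' @export
occurrence_subset <- function(m, assemblages) {
  stopifnot(inherits(m, "occurrence_matrix"))
  missing <- setdiff(assemblages, rownames(m))
  if (length(missing)) stop("unknown assemblages: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  sub <- unclass(m)[assemblages, , drop = FALSE]
  occurrence_matrix(sub[, colSums(sub) > 0, drop = FALSE])
}
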