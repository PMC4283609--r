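#' Read and validate a table of first-appearance-datum (FAD) records
#'
#' Each row is the first record of an interchange (GABI) immigrant genus
#' in its new continent, with the age known only to an interval
#' [age_min, age_max] in Ma. Origin classification (whether a genus or
#' its ancestors lived in North or South America before 10 Ma) is input
#' data: the table is validated for internal consistency (one origin per
#' genus, origin differing from the recording continent), never inferred.
#'
#' @param path CSV/TSV with columns genus, origin_continent (NA/SA),
#'   recording_continent (NA/SA), region (tropical/temperate), age_max,
#'   age_min, and optionally locality
#' @return data.frame of class \code{fad_records}
#' @export
read_fad_records <- function(path) {
  # "NA" is the North America code, not a missing value
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE,
                          na.strings = character(0))
  fad_records(df)
}

#' Validate a FAD record data.frame
#'
#' @param df data.frame with the columns of \code{\link{read_fad_records}}
#' @return the validated data.frame, classed \code{fad_records}
#' @export
fad_records <- function(df) {
  req <- c("genus", "origin_continent", "recording_continent", "region",
           "age_max", "age_min")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("FAD table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$origin_continent <- match_vocab(df$origin_continent, c("NA", "SA"),
                                     "origin_continent", toupper)
  df$recording_continent <- match_vocab(df$recording_continent,
                                        c("NA", "SA"),
                                        "recording_continent", toupper)
  df$region <- match_vocab(df$region, c("tropical", "temperate"), "region")
  if (any(df$age_min < 0) || any(df$age_max < df$age_min))
    stop("require age_max >= age_min >= 0", call. = FALSE)
  if (any(df$origin_continent == df$recording_continent))
    stop("GABI participants must be recorded outside their origin ",
         "continent: ",
         paste(df$genus[df$origin_continent == df$recording_continent],
               collapse = ", "), call. = FALSE)
  origins <- tapply(df$origin_continent, df$genus,
                    function(x) length(unique(x)))
  if (any(origins > 1))
    stop("genus with conflicting origin: ",
         paste(names(origins)[origins > 1], collapse = ", "),
         call. = FALSE)
  class(df) <- c("fad_records", "data.frame")
  df
}

#' Tropical/temperate assignment from latitude
#'
#' Fallback for raw-coordinate inputs lacking a region column:
#' |latitude| <= 23.437 degrees is tropical. An approximation only;
#' curated tables should carry an explicit region.
#'
#' @param latitude decimal degrees
#' @return "tropical" or "temperate"
#' @export
region_from_latitude <- function(latitude) {
  ifelse(abs(latitude) <= 23.437, "tropical", "temperate")
}

#' Draw one plausible age per FAD record
#'
#' Uniform on [age_min, age_max]; a zero-width interval returns age_min
#' exactly.
#'
#' @param records a \code{fad_records} data.frame
#' @return numeric vector of ages in Ma (uses the current RNG state)
#' @export
draw_age <- function(records) {
  w <- records$age_max - records$age_min
  records$age_min + ifelse(w > 0, stats::runif(nrow(records)) * w, 0)
}

#' Monte-Carlo cumulative FAD curve under age-interval uncertainty
#'
#' Per replicate, one age is drawn per record; the cumulative count at
#' grid edge t is the number of records with drawn age >= t (closed at
#' the edge: a record "by 10 Ma" includes age exactly 10). The curve
#' reports the mean and standard deviation over replicates at each edge.
#'
#' @param records a \code{fad_records} data.frame
#' @param region optional filter: "tropical" or "temperate"
#' @param continent optional filter on recording_continent ("NA"/"SA")
#' @param bins Ma grid edges, default \code{seq(12, 0)} (old to young)
#' @param n_reps Monte-Carlo replicates (default 1000)
#' @param seed integer seed
#' @return data.frame of class \code{fad_curve}: edge_ma, mean_count,
#'   sd_count; attribute \code{n_reps}
#' @export
cumulative_fad_curve <- function(records, region = NULL, continent = NULL,
                                 bins = seq(12, 0), n_reps = 1000,
                                 seed = 1L) {
  records <- filter_fads(records, region, continent)
  old <- restore_rng(seed)
  on.exit(old())
  counts <- matrix(0L, n_reps, length(bins))
  for (r in seq_len(n_reps)) {
    ages <- draw_age(records)
    counts[r, ] <- vapply(bins, function(t) sum(ages >= t), 0L)
  }
  structure(data.frame(edge_ma = bins, mean_count = colMeans(counts),
                       sd_count = apply(counts, 2, stats::sd)),
            class = c("fad_curve", "data.frame"), n_reps = n_reps)
}

#' Exact expected cumulative FAD curve
#'
#' Closed-form expectation of \code{\link{cumulative_fad_curve}}: at
#' edge t the expected count is the sum over records of
#' P(Uniform(age_min, age_max) >= t), with point intervals contributing
#' an indicator.
#'
#' @inheritParams cumulative_fad_curve
#' @return data.frame: edge_ma, expected_count
#' @export
expected_fad_curve <- function(records, region = NULL, continent = NULL,
                               bins = seq(12, 0)) {
  records <- filter_fads(records, region, continent)
  expect_one <- function(t) {
    w <- records$age_max - records$age_min
    p <- ifelse(w > 0,
                pmin(1, pmax(0, (records$age_max - t) / w)),
                as.numeric(records$age_min >= t))
    sum(p)
  }
  data.frame(edge_ma = bins,
             expected_count = vapply(bins, expect_one, 0))
}

filter_fads <- function(records, region, continent) {
  stopifnot(inherits(records, "fad_records"))
  if (!is.null(region))
    records <- records[records$region == region, , drop = FALSE]
  if (!is.null(continent))
    records <- records[records$recording_continent == continent, ,
                       drop = FALSE]
  if (nrow(records) == 0)
    stop("no FAD records left after filter (region=",
         if (is.null(region)) "any" else region, ", continent=",
         if (is.null(continent)) "any" else continent, ")", call. = FALSE)
  records
}

#' Collections per time bin and region
#'
#' Sampling-effort diagnostic: each collection is assigned to the 1-Myr
#' bin containing its age-interval midpoint, and counted per region.
#' Bins contain their younger edge and exclude their older edge
#' (midpoint 3.0 falls in bin [3, 4)).
#'
#' @param table data.frame with columns age_max, age_min, region
#' @param bins younger bin edges, default \code{seq(0, 11)} for twelve
#'   1-Myr bins covering 0-12 Ma
#' @return data.frame: bin_young_ma, bin_old_ma, tropical, temperate
#' @export
collections_per_bin <- function(table, bins = seq(0, 11)) {
  if (nrow(table) == 0)
    return(data.frame(bin_young_ma = bins, bin_old_ma = bins + 1,
                      tropical = 0L, temperate = 0L))
  if (any(table$age_max < table$age_min))
    stop("require age_max >= age_min", call. = FALSE)
  region <- match_vocab(table$region, c("tropical", "temperate"), "region")
  mid <- (table$age_max + table$age_min) / 2
  count <- function(reg, b)
    sum(region == reg & mid >= b & mid < b + 1)
  data.frame(bin_young_ma = bins, bin_old_ma = bins + 1,
             tropical = vapply(bins, function(b) count("tropical", b), 0L),
             temperate = vapply(bins, function(b) count("temperate", b), 0L))
}

#' Synthetic GABI FAD record table
#'
#' Loads the packaged synthetic stand-in for a curated
#' interchange-immigrant FAD compilation. The table is constructed, not
#' compiled from the fossil literature: record counts and age intervals
#' emulate the qualitative immigration history of the interchange (first
#' temperate records, the two late-Miocene ground sloths, near 10 Ma;
#' slow accrual to the mid-Pliocene; a steep Plio-Pleistocene rise,
#' larger at temperate latitudes) so that every timeline analysis can
#' run end to end without external data.
#'
#' @return a \code{fad_records} data.frame
#' @export
synthetic_gabi_fads <- function() {
  read_fad_records(system.file("extdata", "synthetic_gabi_fad_records.csv",
                               package = "gabifauna", mustWork = TRUE))
}

#' South American Land Mammal Age (SALMA) boundary ages
#'
#' Reference constants for the biochronologic units spanning the study
#' interval, oldest first. Where the literature carries alternative
#' calibrations (Montehermosan/Chapadmalalan boundary 4.5 or 5.0 Ma;
#' Ensenadan/Bonaerian boundary 0.78 or 0.5 Ma) the first value is
#' stored.
#'
#' @return data.frame: salma, start_ma, end_ma
#' @export
salma_boundaries <- function() {
  data.frame(
    salma = c("Colloncuran", "Laventan", "Mayoan", "Chasicoan",
              "Huayquerian", "Montehermosan", "Chapadmalalan",
              "Marplatan", "Ensenadan", "Bonaerian", "Lujanian"),
    start_ma = c(15.7, 13.5, 11.8, 10, 8.5, 5.28, 4.5, 3.3, 2.0, 0.78,
                 0.13),
    end_ma = c(14, 11.8, 10, 8.5, 5.28, 4.5, 3.3, 2.0, 0.78, 0.13, 0.08))
}
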