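#' Construct a validated occurrence matrix
#'
#' An occurrence matrix records genus-level presence/absence per faunal
#' assemblage: rows are assemblages, columns genera, entries 0/1.
#'
#' @param incidence numeric or integer matrix with assemblage rownames and
#'   genus colnames; entries must be exactly 0 or 1.
#' @return an object of class \code{occurrence_matrix} (an integer matrix).
#' @export
occurrence_matrix <- function(incidence) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("occurrence matrix needs assemblage rownames and genus colnames",
         call. = FALSE)
  if (!all(incidence %in% c(0, 1)))
    stop("occurrence matrix entries must be exactly 0 or 1", call. = FALSE)
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(as.character(rownames(incidence)),
                              as.character(colnames(incidence)))
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate assemblage labels", call. = FALSE)
  if (anyDuplicated(colnames(incidence)))
    stop("duplicate genus labels", call. = FALSE)
  if (any(rowSums(incidence) < 1))
    stop("every assemblage must record at least one genus; empty: ",
         paste(rownames(incidence)[rowSums(incidence) < 1], collapse = ", "),
         call. = FALSE)
  if (any(colSums(incidence) < 1))
    stop("every genus must occur in at least one assemblage; absent: ",
         paste(colnames(incidence)[colSums(incidence) < 1], collapse = ", "),
         call. = FALSE)
  structure(incidence, class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("Occurrence matrix:", nrow(x), "assemblages x", ncol(x), "genera\n")
  cat("Richness per assemblage:",
      paste(range(rowSums(unclass(x))), collapse = "-"), "(min-max)\n")
  invisible(x)
}

#' Genus list of one assemblage
#'
#' @param m an \code{occurrence_matrix}
#' @param assemblage assemblage label
#' @return character vector of genera present
#' @export
genus_set <- function(m, assemblage) {
  stopifnot(inherits(m, "occurrence_matrix"))
  if (!assemblage %in% rownames(m))
    stop("unknown assemblage: ", assemblage, call. = FALSE)
  colnames(m)[m[assemblage, ] == 1L]
}

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an occurrence table from delimited text
#'
#' Two layouts are supported. \code{wide}: assemblages x genera 0/1 table
#' with genus names in the header and assemblage labels in the first
#' column. \code{long}: two columns (assemblage, genus), one row per
#' occurrence; repeated rows are collapsed to a single presence.
#' Genus labels pass through \code{\link{normalize_genus}}, so open
#' nomenclature qualifiers (cf., aff.) merge onto the bare genus.
#'
#' @param path path to a .csv (comma) or .tsv (tab) file
#' @param layout \code{"wide"} or \code{"long"}
#' @return an \code{\link{occurrence_matrix}}
#' @export
read_occurrences <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delim_for(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) stop("empty occurrence table: ", path, call. = FALSE)
  if (layout == "wide") {
    labels <- tab[[1]]
    cells <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
    bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
    if (length(bad))
      stop("non-binary cell in wide occurrence table at data row ",
           bad[1, 1], ", column '", colnames(cells)[bad[1, 2]], "'",
           call. = FALSE)
    dimnames(num) <- list(labels, vapply(colnames(cells), normalize_genus,
                                         "", USE.NAMES = FALSE))
    occurrence_matrix(num)
  } else {
    if (ncol(tab) < 2)
      stop("long layout needs two columns (assemblage, genus): ", path,
           call. = FALSE)
    blank <- which(!nzchar(trimws(tab[[1]])) | !nzchar(trimws(tab[[2]])))
    if (length(blank))
      stop("malformed long-occurrence row ", blank[1], ": empty field",
           call. = FALSE)
    asm <- trimws(tab[[1]])
    gen <- vapply(tab[[2]], normalize_genus, "", USE.NAMES = FALSE)
    inc <- table(factor(asm, levels = unique(asm)),
                 factor(gen, levels = unique(gen)))
    inc <- matrix(pmin(unclass(inc), 1L), nrow = nrow(inc),
                  dimnames = list(unique(asm), unique(gen)))
    occurrence_matrix(inc)
  }
}

#' Write an occurrence matrix to delimited text
#'
#' @param m an \code{occurrence_matrix}
#' @param path output path (.csv or .tsv decides the delimiter)
#' @param layout \code{"wide"} or \code{"long"} (see
#'   \code{\link{read_occurrences}})
#' @return \code{path}, invisibly
#' @export
write_occurrences <- function(m, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(m, "occurrence_matrix"))
  sep <- delim_for(path)
  if (layout == "wide") {
    df <- data.frame(assemblage = rownames(m), unclass(m),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(m == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(assemblage = rownames(m)[idx[, 1]],
                     genus = colnames(m)[idx[, 2]])
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Normalize a raw taxon string to a canonical genus label
#'
#' Strips leading open-nomenclature qualifiers ("cf." / "aff.",
#' case-insensitive, with or without the period), collapses whitespace,
#' discards any trailing species epithet (genus is the taxonomic unit),
#' and stores the genus in title case. Idempotent. Other qualifiers
#' ("?", quotation marks) are not interpreted: they are stripped with a
#' warning so the record is not silently dropped.
#'
#' @param name raw taxon string
#' @return canonical genus label (length-1 character)
#' @export
normalize_genus <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("empty taxon name", call. = FALSE)
  x <- gsub("\\s+", " ", trimws(name))
  repeat {
    x2 <- sub("^(cf|aff)\\.?\\s+", "", x, ignore.case = TRUE)
    if (identical(x2, x)) break
    x <- x2
  }
  if (grepl('^[?"“”\']', x)) {
    warning("unhandled qualifier stripped from taxon '", name, "'",
            call. = FALSE)
    x <- trimws(gsub('^[?"“”\']+', "", x))
  }
  if (!nzchar(x)) stop("taxon name reduces to nothing: ", name, call. = FALSE)
  parts <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (length(parts) > 1L && grepl("^[a-z]", parts[2]))
    warning("species epithet discarded from '", name, "' (genus is the unit)",
            call. = FALSE)
  g <- parts[1]
  paste0(toupper(substring(g, 1, 1)), tolower(substring(g, 2)))
}

#' Great-circle distance between two points, in kilometers
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Used for the
#' distance-decay analysis; the spherical approximation is more than
#' adequate at the continental scale of inter-assemblage distances.
#'
#' @param a,b numeric length-2 vectors \code{c(lat, lon)} in decimal degrees
#' @return distance in km
#' @export
great_circle_distance <- function(a, b) {
  check_coord <- function(p, nm) {
    if (length(p) != 2L || anyNA(p))
      stop("coordinate ", nm, " must be c(lat, lon)", call. = FALSE)
    if (abs(p[1]) > 90) stop("latitude out of range: ", p[1], call. = FALSE)
    if (abs(p[2]) > 180) stop("longitude out of range: ", p[2], call. = FALSE)
  }
  check_coord(a, "a"); check_coord(b, "b")
  # geosphere expects lon/lat order
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371.0088)
}

#' Read an assemblage metadata table
#'
#' Required columns: assemblage_id, latitude, longitude, biome
#' (tropical/temperate), epoch (middle_miocene/late_miocene/pliocene).
#' Optional: paleolatitude, elevation_m. Biome and epoch are taken from
#' the table, never inferred from latitude: high-elevation low-latitude
#' sites (e.g. Quebrada Honda at ~22 degrees S, ~3500 m) are temperate.
#'
#' @param path CSV/TSV path
#' @return validated data.frame of class \code{assemblage_metadata}
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  assemblage_metadata(df)
}

#' Validate an assemblage metadata data.frame
#'
#' @param df data.frame with the columns listed in \code{\link{read_metadata}}
#' @return the validated data.frame, classed \code{assemblage_metadata}
#' @export
assemblage_metadata <- function(df) {
  req <- c("assemblage_id", "latitude", "longitude", "biome", "epoch")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("metadata missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$assemblage_id))
    stop("duplicate assemblage_id in metadata", call. = FALSE)
  if (any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]", call. = FALSE)
  df$biome <- match_vocab(df$biome, c("tropical", "temperate"), "biome")
  df$epoch <- match_vocab(df$epoch,
                          c("middle_miocene", "late_miocene", "pliocene"),
                          "epoch")
  class(df) <- c("assemblage_metadata", "data.frame")
  df
}

match_vocab <- function(x, vocab, what, transform = tolower) {
  x <- transform(trimws(as.character(x)))
  bad <- setdiff(unique(x), vocab)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(vocab, collapse = ", "), call. = FALSE)
  x
}

#' Metadata for the thirteen Neogene study assemblages
#'
#' Modern coordinates, paleolatitude, elevation, biome and epoch of the
#' middle Miocene-Pliocene South American faunal assemblages analysed in
#' this package's worked examples (La Venta, Fitzcarrald, Quebrada Honda,
#' Collon Cura, Urumaco, Acre, Mesopotamian, Cerro Azul, Chiquimil,
#' Andalhuala, Monte Hermoso, Inchasi, Uquia). Longitudes are approximate
#' modern locality longitudes (the source compilation lists latitude and
#' elevation only); they feed only the km axis of the distance-decay
#' analysis.
#'
#' @return an \code{assemblage_metadata} data.frame with 13 rows
#' @export
study_metadata <- function() {
  read_metadata(system.file("extdata", "assemblage_metadata.csv",
                            package = "gabifauna", mustWork = TRUE))
}
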