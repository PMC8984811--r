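#' Encode hypsodonty categories as ordinal crown-height scores
#'
#' Relative molar crown height is recorded categorically in NOW-style data as
#' `bra` (brachydont), `mes` (mesodont), `hyp` (hypsodont) and `hys`
#' (hypselodont). These are mapped to an ordinal score: bra = 1, mes = 2,
#' and hyp = hys = 3. Anything else (including empty strings) becomes `NA`.
#'
#' @param raw character vector of raw categories.
#' @return integer vector of scores in 1..3, `NA` where unknown or missing.
#' @examples
#' encode_hypsodonty(c("bra", "mes", "hyp", "hys", "?"))
#' @export
encode_hypsodonty <- function(raw) {
  raw <- tolower(trimws(as.character(raw)))
  out <- rep(NA_integer_, length(raw))
  out[raw == "bra"] <- 1L
  out[raw == "mes"] <- 2L
  out[raw %in% c("hyp", "hys")] <- 3L
  unknown <- !is.na(raw) & raw != "" & is.na(out)
  if (any(unknown)) {
    message(sum(unknown), " unknown hypsodonty categor",
            if (sum(unknown) == 1) "y" else "ies", " treated as missing")
  }
  out
}

#' Cap longitudinal loph counts at 2
#'
#' Loph counts in NOW-style data range 0-3 ("many"); the ecometric transfer
#' models use counts capped at 2, so 3 maps to 2. Values outside 0..3 are
#' treated as missing.
#'
#' @param raw numeric vector of raw counts (0-3) or `NA`.
#' @return integer vector with values in 0..2 or `NA`.
#' @examples
#' cap_lophs(c(0, 1, 2, 3, NA))
#' @export
cap_lophs <- function(raw) {
  raw <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & (raw < 0 | raw > 3 | raw != round(raw))
  if (any(bad)) {
    message(sum(bad), " invalid loph count(s) treated as missing")
    raw[bad] <- NA_real_
  }
  as.integer(pmin(raw, 2))
}

# regex for open-nomenclature species names excluded by default
.indet_pattern <- "(^|[ _])(sp\\.?|indet\\.?|cf\\.?)([ _]|$)"

#' Normalize an occurrence table
#'
#' Validates and cleans a raw species-occurrence table: resolves time bins
#' against a scheme, drops rows with unresolvable bins or missing
#' coordinates, optionally drops taxonomically indeterminate names
#' (containing "sp.", "indet." or "cf."), encodes dental traits, and
#' collapses duplicated (species, locality, bin) rows to one occurrence.
#'
#' @param df data frame with columns `species`, `locality`, `lon`, `lat`,
#'   `bin`, and optionally `order`, `hypsodonty`, `lophs`.
#' @param scheme a [bin_scheme()] the `bin` column must resolve against.
#' @param drop_indeterminate drop open-nomenclature species names? Default
#'   `TRUE`.
#' @return A data frame with columns `species`, `locality`, `lon`, `lat`,
#'   `bin`, `bin_ordinal`, `order_name`, `hyp`, `lop`, `in_region`; one row
#'   per retained occurrence.
#' @export
normalize_occurrences <- function(df, scheme, drop_indeterminate = TRUE) {
  need <- c("species", "locality", "lon", "lat", "bin")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(
    species = as.character(df$species),
    locality = as.character(df$locality),
    lon = as.numeric(df$lon),
    lat = as.numeric(df$lat),
    bin = as.character(df$bin),
    stringsAsFactors = FALSE
  )
  out$bin_ordinal <- bin_ordinal(scheme, out$bin)
  out$order_name <- if ("order" %in% names(df)) as.character(df$order) else NA_character_
  out$hyp <- if ("hypsodonty" %in% names(df)) encode_hypsodonty(df$hypsodonty) else NA_integer_
  out$lop <- if ("lophs" %in% names(df)) cap_lophs(df$lophs) else NA_integer_

  drop <- is.na(out$bin_ordinal) | is.na(out$lon) | is.na(out$lat) |
    abs(out$lon) > 180 | abs(out$lat) > 90
  if (any(drop)) {
    message(sum(drop), " row(s) dropped (unresolvable bin or bad coordinates)")
    out <- out[!drop, , drop = FALSE]
  }
  if (drop_indeterminate) {
    indet <- grepl(.indet_pattern, out$species, ignore.case = TRUE)
    if (any(indet)) {
      message(sum(indet), " indeterminate taxon row(s) dropped")
      out <- out[!indet, , drop = FALSE]
    }
  }
  dup <- duplicated(out[, c("species", "locality", "bin")])
  if (any(dup)) {
    message(sum(dup), " duplicate (species, locality, bin) row(s) collapsed")
    out <- out[!dup, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no occurrences left after filtering")
  out$in_region <- NA
  rownames(out) <- NULL
  out
}

#' Read a NOW-style occurrence CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `species`, `locality`,
#' `lon`, `lat` (WGS84 decimal degrees), `bin` (a name in `scheme`), and
#' optionally `order`, `hypsodonty` (bra/mes/hyp/hys) and `lophs` (0-3).
#' Rows are cleaned via [normalize_occurrences()].
#'
#' @inheritParams normalize_occurrences
#' @param path path to the CSV file.
#' @return A normalized occurrence data frame; see [normalize_occurrences()].
#' @export
read_occurrence_csv <- function(path, scheme, drop_indeterminate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species = "character",
                                       locality = "character"))
  normalize_occurrences(df, scheme, drop_indeterminate = drop_indeterminate)
}

#' Write a normalized occurrence table to CSV
#'
#' Writes the raw-format columns so that [read_occurrence_csv()] round-trips
#' the table.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_csv <- function(occurrences, path) {
  hyp_chr <- c("bra", "mes", "hyp")[occurrences$hyp]
  utils::write.csv(data.frame(
    species = occurrences$species,
    locality = occurrences$locality,
    lon = occurrences$lon,
    lat = occurrences$lat,
    bin = occurrences$bin,
    order = occurrences$order_name,
    hypsodonty = ifelse(is.na(hyp_chr), "", hyp_chr),
    lophs = occurrences$lop,
    stringsAsFactors = FALSE
  ), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict occurrences to a rectangular study region
#'
#' Retains occurrences with `lon_min <= lon <= lon_max` and `lat > lat_min`:
#' longitude bounds are inclusive while the latitude bound is strict,
#' matching the convention "latitude above X degrees". The default window is
#' Europe, -25 to 40 degrees longitude and latitude above 35 degrees.
#'
#' Idempotent: filtering an already filtered table is a no-op.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param lon_min,lon_max inclusive longitude bounds (degrees east).
#' @param lat_min strict lower latitude bound (degrees north).
#' @return The retained rows with `in_region = TRUE`.
#' @export
filter_region <- function(occurrences, lon_min = -25, lon_max = 40,
                          lat_min = 35) {
  stopifnot(is.finite(lon_min), is.finite(lon_max), is.finite(lat_min))
  keep <- occurrences$lon >= lon_min & occurrences$lon <= lon_max &
    occurrences$lat > lat_min
  out <- occurrences[keep, , drop = FALSE]
  out$in_region <- TRUE
  if (nrow(out) == 0) message("no occurrences inside the region window")
  rownames(out) <- NULL
  out
}

#' Global first and last appearance bins per species
#'
#' Computes, for every species in the table, the bin of its globally first
#' (smallest ordinal) and last (largest ordinal) occurrence. This must be
#' run on the global (regionally unfiltered) table: first/last occurrence
#' status in a study region is defined against the species' global range.
#'
#' @param occurrences a normalized occurrence data frame (global scope).
#' @param scheme the [bin_scheme()] used to bin the table.
#' @return A data frame with columns `species`, `fad_bin`, `lad_bin`,
#'   `fad_ordinal`, `lad_ordinal`.
#' @export
global_fad_lad <- function(occurrences, scheme) {
  stopifnot(!anyNA(occurrences$bin_ordinal))
  fad <- tapply(occurrences$bin_ordinal, occurrences$species, min)
  lad <- tapply(occurrences$bin_ordinal, occurrences$species, max)
  out <- data.frame(
    species = names(fad),
    fad_bin = bin_at(scheme, as.integer(fad)),
    lad_bin = bin_at(scheme, as.integer(lad)),
    fad_ordinal = as.integer(fad),
    lad_ordinal = as.integer(lad),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Flag first and last occurrences
#'
#' An occurrence is a first (last) occurrence iff its bin equals its
#' species' global FAD (LAD) bin; all occurrences in that bin count, so a
#' species with several occurrences in its FAD bin contributes several first
#' occurrences.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param ranges output of [global_fad_lad()] computed on the global table.
#' @return `occurrences` with logical columns `is_first` and `is_last`
#'   appended. Species absent from `ranges` get `NA` flags.
#' @export
flag_event_occurrences <- function(occurrences, ranges) {
  i <- match(occurrences$species, ranges$species)
  occurrences$is_first <- occurrences$bin_ordinal == ranges$fad_ordinal[i]
  occurrences$is_last <- occurrences$bin_ordinal == ranges$lad_ordinal[i]
  occurrences
}
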