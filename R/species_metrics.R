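#' Species longevity in Myr
#'
#' Observed longevity under the full-span convention: from the older bound
#' of the FAD bin to the younger bound of the LAD bin, so that single-bin
#' species carry their bin's full duration rather than zero. A
#' midpoint-to-midpoint alternative is available (zero for single-bin
#' species).
#'
#' @param ranges a [global_fad_lad()] table (columns `fad_bin`, `lad_bin`).
#' @param scheme the [bin_scheme()].
#' @param convention `"span"` (default) or `"midpoint"`.
#' @return numeric vector of durations in Myr along `ranges`.
#' @export
species_longevity <- function(ranges, scheme,
                              convention = c("span", "midpoint")) {
  convention <- match.arg(convention)
  fi <- match(ranges$fad_bin, scheme$name)
  li <- match(ranges$lad_bin, scheme$name)
  if (anyNA(fi) || anyNA(li)) stop("FAD/LAD bins not all in scheme")
  if (convention == "span") {
    scheme$older_bound[fi] - scheme$younger_bound[li]
  } else {
    mid <- (scheme$older_bound + scheme$younger_bound) / 2
    mid[fi] - mid[li]
  }
}

# Lambert azimuthal equal-area projection about (lon0, lat0), output in km
.laea_project <- function(lon, lat, lon0, lat0) {
  to_rad <- pi / 180
  lam <- lon * to_rad; phi <- lat * to_rad
  lam0 <- lon0 * to_rad; phi0 <- lat0 * to_rad
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  cbind(x = .earth_radius_km * k * cos(phi) * sin(lam - lam0),
        y = .earth_radius_km * k *
          (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

# shoelace polygon area for points in km, in the given vertex order
.shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Geographic range area of a set of occurrence locations
#'
#' Range area in km2 for one species in one time bin, following the
#' three-tier convention: a single location has zero range; two locations
#' span a 10 km wide rectangle along the great circle between them (area =
#' distance x 10); three or more locations take the planar area of their
#' convex hull after Lambert azimuthal equal-area projection about the
#' point centroid. Collinear point sets (degenerate hulls) fall back to the
#' two-point rule applied to the farthest pair. Duplicate coordinates are
#' collapsed first.
#'
#' @param lon,lat coordinates of the locations in degrees.
#' @return area in km2.
#' @examples
#' per_bin_range_area(c(0, 0), c(50, 50 + 100 / 111.1949)) # ~1000 km2
#' @export
per_bin_range_area <- function(lon, lat) {
  if (length(lon) == 0) stop("at least one location is required")
  stopifnot(length(lon) == length(lat))
  pts <- unique(cbind(lon, lat))
  m <- nrow(pts)
  if (m == 1) return(0)
  if (m == 2) {
    return(great_circle_km(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2]) * 10)
  }
  xy <- .laea_project(pts[, 1], pts[, 2], mean(pts[, 1]), mean(pts[, 2]))
  h <- grDevices::chull(xy)
  area <- if (length(h) >= 3) .shoelace_area(xy[h, , drop = FALSE]) else 0
  if (area > 1e-6) return(area)
  # collinear: widest pair, 10 km rectangle rule
  d <- .gc_km_matrix(pts[, 1], pts[, 2], pts[, 1], pts[, 2])
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  d[far[1], far[2]] * 10
}

#' Per-species summary of longevity, range and hotspot membership
#'
#' Builds one row per species occurring in the supplied (typically
#' region-filtered) table: global FAD/LAD bins, longevity, mean per-bin
#' range area (mean over the bins in which the species actually occurs in
#' the table), whether both FAD and LAD fall inside the analysis window,
#' and membership flags. A species is an origination-hotspot member if any
#' of its first occurrences falls in a grid cell classified as origination
#' hotspot in its FAD bin (nearest grid node within half the lattice
#' spacing); extinction membership is defined symmetrically from last
#' occurrences.
#'
#' @param occurrences a normalized occurrence data frame (study region).
#' @param ranges [global_fad_lad()] on the global table.
#' @param scheme the [bin_scheme()].
#' @param origination_cells,extinction_cells optional [detect_hotspots()]
#'   outputs used for membership (klass `"hotspot"` rows); `NULL` leaves
#'   the flag `FALSE`.
#' @param window integer ordinals of the analysis window used for the
#'   `in_window` flag; default all bins except the first and last.
#' @param longevity_convention passed to [species_longevity()].
#' @return A data frame with columns `species`, `fad_bin`, `lad_bin`,
#'   `longevity_myr`, `mean_area_km2`, `n_bins_observed`, `single_bin`,
#'   `in_window`, `origination_hotspot_member`, `extinction_hotspot_member`.
#' @export
species_summaries <- function(occurrences, ranges, scheme,
                              origination_cells = NULL,
                              extinction_cells = NULL,
                              window = 2:(nrow(scheme) - 1),
                              longevity_convention = "span") {
  occ <- flag_event_occurrences(occurrences, ranges)
  sp <- sort(unique(occ$species))
  r <- ranges[match(sp, ranges$species), , drop = FALSE]
  areas <- numeric(length(sp))
  nbins <- integer(length(sp))
  for (i in seq_along(sp)) {
    o <- occ[occ$species == sp[i], , drop = FALSE]
    per_bin <- vapply(unique(o$bin), function(b) {
      per_bin_range_area(o$lon[o$bin == b], o$lat[o$bin == b])
    }, numeric(1))
    areas[i] <- mean(per_bin)
    nbins[i] <- length(per_bin)
  }
  member <- function(cells, event_flag) {
    out <- rep(FALSE, length(sp))
    if (is.null(cells)) return(out)
    hot <- cells[cells$klass == "hotspot", , drop = FALSE]
    if (nrow(hot) == 0) return(out)
    spacing <- .grid_spacing(cells)
    # is_first/is_last already pin the occurrence to its FAD/LAD bin
    ev <- occ[which(event_flag), , drop = FALSE]
    if (nrow(ev) == 0) return(out)
    hit <- .in_hotspot_cell(ev, hot, spacing)
    out[sp %in% ev$species[hit]] <- TRUE
    out
  }
  out <- data.frame(
    species = sp,
    fad_bin = r$fad_bin, lad_bin = r$lad_bin,
    longevity_myr = species_longevity(r, scheme, longevity_convention),
    mean_area_km2 = areas,
    n_bins_observed = nbins,
    single_bin = r$fad_ordinal == r$lad_ordinal,
    in_window = r$fad_ordinal %in% window & r$lad_ordinal %in% window,
    origination_hotspot_member = member(origination_cells, occ$is_first),
    extinction_hotspot_member = member(extinction_cells, occ$is_last),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# lattice spacing from a hotspot grid (minimum positive difference)
.grid_spacing <- function(cells) {
  u <- sort(unique(cells$lon))
  v <- sort(unique(cells$lat))
  d <- c(diff(u), diff(v))
  d <- d[d > 0]
  if (length(d) == 0) 1 else min(d)
}

# which event occurrences fall in a flagged cell of their own bin
.in_hotspot_cell <- function(events, hot_cells, spacing) {
  key_hot <- paste(hot_cells$lon, hot_cells$lat, hot_cells$bin, sep = "\r")
  lons <- sort(unique(hot_cells$lon)); lats <- sort(unique(hot_cells$lat))
  near <- function(x, ref) {
    i <- vapply(x, function(v) which.min(abs(ref - v)), integer(1))
    cbind(ref[i], abs(ref[i] - x))
  }
  nl <- near(events$lon, lons); nt <- near(events$lat, lats)
  ok <- nl[, 2] <= spacing / 2 + 1e-9 & nt[, 2] <= spacing / 2 + 1e-9
  key_ev <- paste(nl[, 1], nt[, 1], events$bin, sep = "\r")
  ok & key_ev %in% key_hot
}

#' Compare hotspot and background species
#'
#' Group means of longevity and mean occupied area for hotspot-member
#' versus non-member species, restricted to species whose global FAD and
#' LAD both fall inside the analysis window (`in_window`), optionally
#' excluding single-bin species.
#'
#' @param summaries output of [species_summaries()].
#' @param membership `"origination"` or `"extinction"`: which membership
#'   flag defines the hotspot group.
#' @param exclude_single_bin drop species observed in a single bin?
#' @return A data frame with one row per group (`hotspot`, `background`):
#'   `group`, `n_species`, `mean_longevity_myr`, `mean_area_km2`.
#' @export
hotspot_species_comparison <- function(summaries,
                                       membership = c("origination",
                                                      "extinction"),
                                       exclude_single_bin = FALSE) {
  membership <- match.arg(membership)
  flag_col <- paste0(membership, "_hotspot_member")
  df <- summaries[summaries$in_window, , drop = FALSE]
  if (exclude_single_bin) df <- df[!df$single_bin, , drop = FALSE]
  grp <- ifelse(df[[flag_col]], "hotspot", "background")
  out <- do.call(rbind, lapply(c("hotspot", "background"), function(g) {
    x <- df[grp == g, , drop = FALSE]
    data.frame(group = g, n_species = nrow(x),
               mean_longevity_myr = if (nrow(x)) mean(x$longevity_myr) else NA_real_,
               mean_area_km2 = if (nrow(x)) mean(x$mean_area_km2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
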