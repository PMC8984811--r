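# mean Earth radius, km (IUGG)
.earth_radius_km <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized over
#' all arguments with the usual recycling.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in km.
#' @examples
#' great_circle_km(0, 0, 1, 0) # ~111.19 km, one degree along the equator
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = .earth_radius_km)
}

# distance matrix (length(flon) x length(lon)) in km
.gc_km_matrix <- function(flon, flat, lon, lat) {
  pts <- cbind(lon, lat)
  out <- matrix(0, nrow = length(flon), ncol = length(lon))
  for (i in seq_along(flon)) {
    out[i, ] <- geosphere::distHaversine(c(flon[i], flat[i]), pts,
                                         r = .earth_radius_km)
  }
  out
}

#' Distance-decay weight
#'
#' The spatial weight of an occurrence at distance `d` from a focal point
#' with aggregation radius `R`. The default (and standard) kernel is linear
#' decay, `max(0, 1 - d/R)`: weight 1 at the focal point, 0 at and beyond
#' the radius. An exponential kernel `exp(-d/R)` is available as an
#' experimental alternative.
#'
#' @param distance_km non-negative distances in km.
#' @param radius_km aggregation radius in km (> 0).
#' @param kernel `"linear"` (default) or `"exponential"`.
#' @return weights in `[0, 1]`.
#' @examples
#' decay_weight(400, 500) # 0.2
#' @export
decay_weight <- function(distance_km, radius_km = 500,
                         kernel = c("linear", "exponential")) {
  kernel <- match.arg(kernel)
  stopifnot(radius_km > 0, all(distance_km >= 0))
  # pmax takes shape attributes from its first argument; keep matrix dims
  switch(kernel,
    linear = pmax(1 - distance_km / radius_km, 0),
    exponential = exp(-distance_km / radius_km)
  )
}

# weight matrix focal points x occurrence points
.weight_matrix <- function(flon, flat, lon, lat, radius_km,
                           kernel = "linear") {
  d <- .gc_km_matrix(flon, flat, lon, lat)
  w <- decay_weight(d, radius_km, kernel)
  attr(w, "distance_km") <- d
  w
}

#' Weighted occurrence count around a focal point
#'
#' Sums the distance-decay weights of all occurrences in one time bin
#' (optionally restricted by a predicate) around a focal point. This is the
#' basic sampling-intensity statistic: occurrences at the focal point count
#' 1 each, occurrences at the radius or beyond count 0.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param lon,lat focal point, decimal degrees.
#' @param bin bin name; only occurrences of this bin are counted. `NULL`
#'   counts across all bins.
#' @param radius_km aggregation radius (default 500 km).
#' @param predicate optional logical vector along `occurrences` selecting
#'   which occurrences are counted (e.g. first occurrences only).
#' @param kernel weight kernel, see [decay_weight()].
#' @return A list with `value` (weighted count), `n_contributing` (raw
#'   occurrences with positive weight) and `min_distance_km` (distance to
#'   the nearest selected occurrence; `Inf` if none).
#' @examples
#' occ <- data.frame(species = c("a", "b"), locality = "L1",
#'                   lon = 0, lat = 50, bin = "B1", bin_ordinal = 1)
#' weighted_occurrence_count(occ, 0, 50, bin = "B1")$value # 2
#' @export
weighted_occurrence_count <- function(occurrences, lon, lat, bin = NULL,
                                      radius_km = 500, predicate = NULL,
                                      kernel = "linear") {
  keep <- rep(TRUE, nrow(occurrences))
  if (!is.null(bin)) keep <- keep & occurrences$bin == bin
  if (!is.null(predicate)) keep <- keep & predicate
  occ <- occurrences[keep, , drop = FALSE]
  if (nrow(occ) == 0) {
    return(list(value = 0, n_contributing = 0L, min_distance_km = Inf))
  }
  d <- great_circle_km(lon, lat, occ$lon, occ$lat)
  w <- decay_weight(d, radius_km, kernel)
  list(value = sum(w), n_contributing = sum(w > 0),
       min_distance_km = min(d))
}

#' Regular lon/lat lattice of focal grid points
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box in degrees.
#' @param spacing_deg lattice spacing in degrees (default 1).
#' @return A data frame with columns `lon` and `lat`.
#' @export
make_grid <- function(lon_min, lon_max, lat_min, lat_max, spacing_deg = 1) {
  stopifnot(spacing_deg > 0, lon_max >= lon_min, lat_max >= lat_min)
  g <- expand.grid(lon = seq(lon_min, lon_max, by = spacing_deg),
                   lat = seq(lat_min, lat_max, by = spacing_deg),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$lat, g$lon), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Locality-level aggregation of one bin's occurrences: unique coordinates
# with total and per-flag counts.  Weighted counts at focal points are then
# weight-matrix products, which is what makes grid scans cheap.
.bin_locality_counts <- function(occurrences, bin, flags = NULL) {
  occ <- occurrences[occurrences$bin == bin, , drop = FALSE]
  if (nrow(occ) == 0) {
    out <- data.frame(locality = character(), lon = numeric(),
                      lat = numeric(), n = numeric())
    for (f in names(flags)) out[[f]] <- numeric()
    return(out)
  }
  key <- paste(occ$locality, occ$lon, occ$lat, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(locality = occ$locality[first], lon = occ$lon[first],
                    lat = occ$lat[first], stringsAsFactors = FALSE)
  idx <- match(key, key[first])
  out$n <- as.numeric(tabulate(idx, nbins = nrow(out)))
  for (f in names(flags)) {
    v <- as.numeric(flags[[f]][occurrences$bin == bin])
    v[is.na(v)] <- 0
    # rowsum groups are 1..nrow(out), returned in sorted order
    out[[f]] <- as.numeric(rowsum(v, idx)[, 1])
  }
  out
}
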