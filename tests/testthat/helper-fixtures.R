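# Shared fixtures built in code. All geometry is laid out along meridians,
# where the haversine distance is exactly R * delta_phi, so distances in km
# convert to exact latitude offsets.

EARTH_R <- 6371.0088

# latitude offset (degrees) spanning `km` along a meridian
km_to_lat <- function(km) km / EARTH_R * 180 / pi

# n contiguous 1-Myr bins named B1..Bn, oldest first, youngest bound 0.01
toy_scheme <- function(n = 4) {
  older <- rev(seq_len(n)) + 0.01
  bin_scheme(paste0("B", seq_len(n)), older, older - 1)
}

# assemble a normalized occurrence table from parallel vectors
toy_occ <- function(species, locality, lon, lat, bin, scheme,
                    order = "Artiodactyla", hyp = NA, lop = NA) {
  df <- data.frame(species = species, locality = locality, lon = lon,
                   lat = lat, bin = bin, order = order,
                   hypsodonty = hyp, lophs = lop,
                   stringsAsFactors = FALSE)
  suppressMessages(normalize_occurrences(df, scheme,
                                         drop_indeterminate = FALSE))
}

# The worked toy configuration: focal locality A (4 occurrences, one of
# them a first occurrence) in the focal bin, locality B (3 occurrences)
# 400 km away in the same bin, locality C (5 occurrences) 350 km away in
# the previous bin; weighting radius 500 km.
fig_toy <- function() {
  scheme <- bin_scheme(c("T0", "T1", "T2"), c(3, 2, 1), c(2, 1, 0.1))
  lonA <- 10; latA <- 45
  latB <- latA + km_to_lat(400)
  latC <- latA - km_to_lat(350)
  occ <- toy_occ(
    species = c("a1", "a2", "a3", "a4",      # locality A, focal bin
                "b1", "b2", "b3",            # locality B, focal bin
                "a2", "a3", "a4", "b1", "b2"), # locality C, previous bin
    locality = c(rep("A", 4), rep("B", 3), rep("C", 5)),
    lon = lonA,
    lat = c(rep(latA, 4), rep(latB, 3), rep(latC, 5)),
    bin = c(rep("T1", 7), rep("T0", 5)),
    scheme = scheme
  )
  list(scheme = scheme, occ = occ, focal = c(lon = lonA, lat = latA))
}
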