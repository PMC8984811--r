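test_that("longevity follows the full-span convention", {
  s <- bin_scheme(c("X1", "X2", "X3", "X4"),
                  c(20.0, 17.2, 11.1, 5.3),
                  c(17.2, 11.1, 5.3, 4.9))
  r <- data.frame(species = c("single", "ranged"),
                  fad_bin = c("X4", "X1"), lad_bin = c("X4", "X3"))
  lon <- species_longevity(r, s)
  expect_equal(lon[1], 0.4)   # single-bin species get the full bin span
  expect_equal(lon[2], 20.0 - 5.3)
  # the midpoint alternative gives zero for single-bin species
  mid <- species_longevity(r, s, convention = "midpoint")
  expect_equal(mid[1], 0)
  # longevity strictly increases as the LAD moves younger
  r2 <- data.frame(species = "a", fad_bin = "X1", lad_bin = c("X2", "X3", "X4"))
  expect_true(all(diff(species_longevity(r2, s)) > 0))
})

test_that("range areas follow the 0 / rectangle / hull tiers", {
  expect_equal(per_bin_range_area(10, 45), 0)
  # two locations 100 km apart: a 10 km wide rectangle
  expect_equal(per_bin_range_area(c(10, 10), c(45, 45 + km_to_lat(100))),
               1000, tolerance = 1e-9)
  # duplicated coordinates collapse to one location
  expect_equal(per_bin_range_area(c(10, 10), c(45, 45)), 0)
  # right triangle with ~100 km legs near the equator: ~5000 km2
  d <- km_to_lat(100)
  expect_equal(per_bin_range_area(c(0, d, 0), c(0, 0, d)), 5000,
               tolerance = 1e-3)
  # collinear points fall back to the farthest-pair rectangle
  expect_equal(per_bin_range_area(c(10, 10, 10),
                                  c(45, 45 + km_to_lat(40),
                                    45 + km_to_lat(100))),
               1000, tolerance = 1e-6)
  expect_error(per_bin_range_area(numeric(), numeric()))
})

test_that("hull areas match a brute-force subset oracle and ignore duplication", {
  shoelace <- function(xy) {
    n <- nrow(xy); j <- c(2:n, 1)
    abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
  }
  # brute force: the hull area is the maximum, over all subsets of >= 3
  # points, of the polygon area with vertices sorted around the centroid
  brute_area <- function(xy) {
    n <- nrow(xy)
    best <- 0
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(idx) < 3) next
      p <- xy[idx, , drop = FALSE]
      o <- order(atan2(p[, 2] - mean(p[, 2]), p[, 1] - mean(p[, 1])))
      best <- max(best, shoelace(p[o, , drop = FALSE]))
    }
    best
  }
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    lon <- runif(n, 0, 4); lat <- runif(n, 42, 46)
    area <- per_bin_range_area(lon, lat)
    xy <- fossilhotspots:::.laea_project(lon, lat, mean(unique(cbind(lon, lat))[, 1]),
                                         mean(unique(cbind(lon, lat))[, 2]))
    expect_equal(area, brute_area(xy), tolerance = 1e-6)
    # permutation and duplication invariance
    p <- sample(n)
    expect_equal(per_bin_range_area(lon[p], lat[p]), area, tolerance = 1e-9)
    expect_equal(per_bin_range_area(c(lon, lon[1]), c(lat, lat[1])), area,
                 tolerance = 1e-9)
  }
})

test_that("species summaries aggregate ranges, windows and membership", {
  s <- toy_scheme(5)
  d <- km_to_lat(100)
  occ <- toy_occ(
    species = c(rep("wide", 4), "edge", "mid", "mid"),
    locality = c("L1", "L2", "L3", "L1", "L4", "L1", "L1"),
    lon = c(0, d, 0, 0, 0, 0, 0),
    lat = c(45, 45, 45 + d, 45, 45, 45, 45),
    bin = c("B2", "B2", "B2", "B3", "B1", "B2", "B4"),
    scheme = s
  )
  ranges <- global_fad_lad(occ, s)
  ss <- species_summaries(occ, ranges, s)
  w <- ss[ss$species == "wide", ]
  # B2: 3 localities -> hull; B3: 1 locality -> 0; mean over observed bins
  tri <- per_bin_range_area(c(0, d, 0), c(45, 45, 45 + d))
  expect_equal(w$mean_area_km2, (tri + 0) / 2, tolerance = 1e-9)
  expect_equal(w$n_bins_observed, 2)
  expect_false(w$single_bin)
  expect_true(w$in_window)
  expect_false(ss$in_window[ss$species == "edge"]) # FAD in the first bin
  expect_true(ss$single_bin[ss$species == "edge"])
  # no hotspot grids supplied: membership flags default to FALSE
  expect_false(any(ss$origination_hotspot_member))
})

test_that("hotspot membership is assigned through flagged grid cells", {
  s <- toy_scheme(4)
  occ <- toy_occ(
    species = c("hot", "hot", "cold", "cold"),
    locality = c("L1", "L1", "L2", "L2"),
    lon = c(0, 0, 10, 10), lat = 45,
    bin = c("B2", "B3", "B2", "B3"),
    scheme = s
  )
  ranges <- global_fad_lad(occ, s)
  cells <- data.frame(lon = c(0, 10), lat = 45, bin = "B2",
                      klass = c("hotspot", "neutral"))
  ss <- species_summaries(occ, ranges, s, origination_cells = cells)
  expect_true(ss$origination_hotspot_member[ss$species == "hot"])
  expect_false(ss$origination_hotspot_member[ss$species == "cold"])
  cmp <- hotspot_species_comparison(ss, "origination")
  expect_equal(cmp$n_species, c(1, 1))
})

test_that("group comparisons handle empty groups and single-bin exclusion", {
  w <- generate_world(world_config(seed = 43))
  ranges <- global_fad_lad(w$occurrences, w$scheme)
  ss <- species_summaries(w$occurrences, ranges, w$scheme)
  cmp <- hotspot_species_comparison(ss, "origination")
  expect_equal(cmp$n_species[cmp$group == "hotspot"], 0)
  expect_true(is.na(cmp$mean_longevity_myr[cmp$group == "hotspot"]))
  # dropping single-bin species never decreases a group's mean longevity
  cmp_all <- hotspot_species_comparison(ss, "origination", FALSE)
  cmp_ex <- hotspot_species_comparison(ss, "origination", TRUE)
  g <- "background"
  expect_gte(cmp_ex$mean_longevity_myr[cmp_ex$group == g],
             cmp_all$mean_longevity_myr[cmp_all$group == g])
  # the per-species mean area is bounded by the largest per-bin area
  expect_true(all(ss$mean_area_km2 >= 0))
})
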