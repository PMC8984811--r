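#' Configuration for the synthetic fossil-record generator
#'
#' Defines the study conditions a generated world emulates: discrete time
#' bins of configurable duration, persistent localities scattered over a
#' lon/lat region, uneven (negative-binomially dispersed) per-locality
#' sampling, locality faunas that persist across bins with configurable
#' retention, controlled background fractions of first and last
#' occurrences, optional injected hotspots, and dental traits coupled to a
#' linear latent-productivity gradient.
#'
#' Species lifetimes are memoryless: every bin, the species drawn to
#' provide last occurrences are sampled with constant per-species hazard
#' from the currently recorded pool, so realized lifetimes are geometric in
#' bin count. Apparent (sampling-driven) local disappearance adds to the
#' realized last-occurrence fraction on top of `background_last_frac`, just
#' as incomplete sampling does in real records; the first-occurrence
#' fraction is controlled exactly.
#'
#' @param n_bins number of time bins (>= 3).
#' @param bin_duration_myr bin duration(s) in Myr; scalar or length `n_bins`.
#' @param lon_min,lon_max,lat_min,lat_max region window in degrees.
#' @param n_localities persistent fossil localities in the region.
#' @param mean_occurrences expected occurrences per locality per bin.
#' @param sampling_dispersion shape of the per-locality Gamma sampling
#'   intensity; counts are Poisson around a persistent per-locality
#'   intensity, i.e. negative-binomially dispersed across localities with
#'   this size parameter (smaller = more uneven sampling). Persistence
#'   across bins reflects that productive fossil sites stay productive.
#' @param background_first_frac background fraction of occurrences that are
#'   first occurrences (after the first bin, where every occurrence is one).
#' @param background_last_frac background fraction of occurrences drawn as
#'   true last occurrences (species killed on draw).
#' @param p_retain probability that a surviving species present at a
#'   locality is retained there in the next bin.
#' @param newborn_reuse probability that a first occurrence re-uses a
#'   species already originated in the same bin rather than founding a new
#'   one (a species factory yields species with several first occurrences).
#' @param single_bin_frac probability that a newly founded species is a
#'   single-bin species (its first occurrences are also its last).
#' @param herbivore_frac fraction of species assigned to the large
#'   plant-eating orders carrying dental traits.
#' @param env_gradient list with `base`, `lon_slope`, `lat_slope`,
#'   `bin_slope`, `ref`, `scale`: latent NPP (g C m-2 yr-1) is
#'   `base + lon_slope*lon + lat_slope*lat + bin_slope*ordinal`, and trait
#'   expectations depend on the standardized value `(npp - ref)/scale`.
#' @param trait_coupling slope linking low latent NPP to high hypsodonty
#'   and low loph count at species origin (0 = no coupling).
#' @param hotspot_longevity_mult factor by which the per-bin death hazard
#'   of species born inside an origination hotspot is divided (1 = none).
#' @param hotspots `NULL` or a data frame with columns `lon`, `lat`,
#'   `radius_km`, `bin` (ordinal; for `local_extinction` the earlier bin of
#'   the transition, for `immigration` the arrival bin), `type` in
#'   `{"first", "last", "local_extinction", "immigration"}`, and `frac`.
#'   `first`/`last` specs elevate the corresponding event fraction of
#'   occurrences at circle localities to `frac`; `local_extinction` specs
#'   extirpate `frac` of the circle's established species from circle
#'   localities at the transition while placing them as refugees at
#'   localities more than twice the circle radius away (regional loss with
#'   global survival, i.e. sorting); `immigration` specs replace retained
#'   circle fauna by immigrants with probability `frac`.
#' @param seed integer RNG seed.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(n_bins = 6, bin_duration_myr = 1.5,
                         lon_min = -10, lon_max = 20,
                         lat_min = 40, lat_max = 52,
                         n_localities = 40, mean_occurrences = 8,
                         sampling_dispersion = 5,
                         background_first_frac = 0.05,
                         background_last_frac = 0.05,
                         p_retain = 0.9,
                         newborn_reuse = 0.3, single_bin_frac = 0.15,
                         herbivore_frac = 0.75,
                         env_gradient = list(base = 1100, lon_slope = -20,
                                             lat_slope = 0, bin_slope = 0,
                                             ref = 800, scale = 400),
                         trait_coupling = 1,
                         hotspot_longevity_mult = 1,
                         hotspots = NULL, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_bins >= 3, n_localities >= 2, mean_occurrences > 0,
            sampling_dispersion > 0,
            background_first_frac >= 0, background_first_frac <= 1,
            background_last_frac >= 0, background_last_frac <= 1,
            background_first_frac + background_last_frac < 1,
            p_retain >= 0, p_retain <= 1,
            newborn_reuse >= 0, newborn_reuse < 1,
            single_bin_frac >= 0, single_bin_frac < 1,
            hotspot_longevity_mult >= 1,
            lon_max > lon_min, lat_max > lat_min)
  cfg$bin_duration_myr <- rep_len(bin_duration_myr, n_bins)
  stopifnot(all(cfg$bin_duration_myr > 0))
  if (!is.null(hotspots)) {
    need <- c("lon", "lat", "radius_km", "bin", "type", "frac")
    stopifnot(all(need %in% names(hotspots)),
              all(hotspots$frac >= 0), all(hotspots$frac <= 1),
              all(hotspots$radius_km > 0),
              all(hotspots$type %in% c("first", "last", "local_extinction",
                                       "immigration")),
              all(hotspots$bin >= 1), all(hotspots$bin <= n_bins))
    bad <- (hotspots$type == "first" &
              hotspots$frac + background_last_frac >= 1) |
      (hotspots$type == "last" &
         hotspots$frac + background_first_frac >= 1)
    if (any(bad)) stop("infeasible hotspot spec: event fractions exceed 1")
  }
  structure(cfg, class = "world_config")
}

# latent NPP of the configured environmental gradient
.world_npp <- function(cfg, lon, lat, ordinal) {
  e <- cfg$env_gradient
  e$base + e$lon_slope * lon + e$lat_slope * lat + e$bin_slope * ordinal
}

#' Generate a synthetic fossil record
#'
#' Simulates a fossil occurrence table with known ground truth under the
#' conditions of a [world_config()]. Every occurrence in the first bin
#' founds (or re-uses) a species; afterwards each locality's occurrences
#' split into first occurrences (founding new species), last occurrences
#' (species drawn from the established pool and killed), and mid
#' occurrences (fauna retained from the previous bin, topped up by
#' immigrants from the previous bin's recorded pool). Hotspot specs
#' locally elevate the first or last occurrence fraction, depress
#' retention (local extinction), or replace retained species by immigrants
#' (immigration). The generator is fully reproducible from the seed.
#'
#' @param config a [world_config()].
#' @return A list of class `world` with elements `occurrences` (normalized
#'   occurrence table), `scheme` (the [bin_scheme()]), and `truth` (list
#'   with the species registry, realized FAD/LAD table, hotspot specs with
#'   bin names, the localities, and the config).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  set.seed(cfg$seed)
  older <- rev(cumsum(rev(cfg$bin_duration_myr))) + 0.01
  younger <- older - cfg$bin_duration_myr
  scheme <- bin_scheme(paste0("B", seq_len(cfg$n_bins)), older, younger)

  loc <- data.frame(
    locality = sprintf("L%03d", seq_len(cfg$n_localities)),
    lon = stats::runif(cfg$n_localities, cfg$lon_min, cfg$lon_max),
    lat = stats::runif(cfg$n_localities, cfg$lat_min, cfg$lat_max),
    stringsAsFactors = FALSE
  )
  # persistent per-locality sampling intensity (Gamma-Poisson counts are
  # negative binomial across localities)
  loc_mu <- stats::rgamma(cfg$n_localities, shape = cfg$sampling_dispersion,
                          rate = cfg$sampling_dispersion /
                            cfg$mean_occurrences)
  hs <- cfg$hotspots
  no_specs <- data.frame(lon = numeric(), lat = numeric(),
                         radius_km = numeric(), bin = integer(),
                         type = character(), frac = numeric())
  specs_of <- function(type, bin) {
    if (is.null(hs)) return(no_specs)
    hs[hs$type == type & hs$bin == bin, , drop = FALSE]
  }
  in_circle <- function(spec_rows, lon, lat) {
    if (nrow(spec_rows) == 0) return(FALSE)
    any(great_circle_km(spec_rows$lon, spec_rows$lat, lon, lat) <=
          spec_rows$radius_km)
  }

  # species registry; killed = bin of the species' (drawn) extinction
  reg <- list(birth = integer(), killed = integer(), lon = numeric(),
              lat = numeric(), hyp = integer(), lop = integer(),
              order = character(), hotspot_born = logical())
  new_species <- function(bin, lon, lat, hotspot_born) {
    z <- (.world_npp(cfg, lon, lat, bin) - cfg$env_gradient$ref) /
      cfg$env_gradient$scale
    id <- length(reg$birth) + 1L
    reg$birth[id] <<- bin
    reg$killed[id] <<- NA_integer_
    reg$lon[id] <<- lon; reg$lat[id] <<- lat
    reg$hyp[id] <<- min(3L, max(1L, as.integer(round(
      2 - cfg$trait_coupling * z + stats::rnorm(1, sd = 0.6)))))
    reg$lop[id] <<- min(2L, max(0L, as.integer(round(
      1 - 0.75 * cfg$trait_coupling * z + stats::rnorm(1, sd = 0.6)))))
    reg$order[id] <<- if (stats::runif(1) < cfg$herbivore_frac) {
      sample(.herbivore_orders, 1)
    } else {
      sample(c("Rodentia", "Carnivora"), 1)
    }
    reg$hotspot_born[id] <<- hotspot_born
    id
  }

  fauna_prev <- vector("list", cfg$n_localities) # species ids per locality
  record_prev <- integer() # species recorded anywhere in the previous bin
  occ_species <- integer(); occ_loc <- integer(); occ_bin <- integer()

  for (b in seq_len(cfg$n_bins)) {
    first_specs <- specs_of("first", b)
    last_specs <- specs_of("last", b)
    lex_specs <- specs_of("local_extinction", b - 1L)
    imm_specs <- specs_of("immigration", b)
    newborn_pool <- integer() # persisting species founded in this bin
    fauna_now <- vector("list", cfg$n_localities)
    # established species eligible as last occurrences or immigrants
    established <- record_prev[is.na(reg$killed[record_prev])]
    dying <- integer() # killed in this bin; may recur at other localities
    # local-extinction injection: extirpate a fraction of the circle's
    # established species from circle localities, while they survive as
    # refugees at distant localities (sorting, not true extinction)
    extirpated <- integer(); circle_loc <- logical(cfg$n_localities)
    refuge_ok <- rep(TRUE, cfg$n_localities)
    if (nrow(lex_specs) > 0) {
      dc <- great_circle_km(lex_specs$lon[1], lex_specs$lat[1],
                            loc$lon, loc$lat)
      circle_loc <- dc <= lex_specs$radius_km[1]
      refuge_ok <- dc > 2 * lex_specs$radius_km[1]
      sp_in <- unique(unlist(fauna_prev[circle_loc]))
      sp_in <- sp_in[!is.na(reg$birth[sp_in]) & reg$birth[sp_in] < b &
                       is.na(reg$killed[sp_in])]
      n_ext <- round(lex_specs$frac[1] * length(sp_in))
      if (n_ext > 0) {
        extirpated <- sp_in[sample.int(length(sp_in), n_ext)]
      }
    }
    refugees <- extirpated # to be placed outside the circle this bin
    for (l in seq_len(cfg$n_localities)) {
      n_occ <- stats::rpois(1, loc_mu[l])
      if (n_occ == 0) next
      p_first <- if (b == 1) 1 else cfg$background_first_frac
      p_last <- if (b == 1) 0 else cfg$background_last_frac
      if (in_circle(first_specs, loc$lon[l], loc$lat[l])) {
        p_first <- max(p_first, first_specs$frac[1])
      }
      if (in_circle(last_specs, loc$lon[l], loc$lat[l])) {
        p_last <- max(p_last, last_specs$frac[1])
      }
      cat_counts <- stats::rmultinom(1, n_occ,
                                     c(p_first, p_last,
                                       1 - p_first - p_last))[, 1]
      chosen <- integer()
      # first occurrences: found a species, or re-use one founded this bin
      if (cat_counts[1] > 0) {
        hot_born <- in_circle(first_specs, loc$lon[l], loc$lat[l])
        for (i in seq_len(cat_counts[1])) {
          reuse <- setdiff(newborn_pool, chosen)
          if (length(reuse) > 0 && stats::runif(1) < cfg$newborn_reuse) {
            id <- reuse[sample.int(length(reuse), 1)]
          } else {
            id <- new_species(b, loc$lon[l], loc$lat[l], hot_born)
            sb <- cfg$single_bin_frac /
              (if (hot_born) cfg$hotspot_longevity_mult else 1)
            if (stats::runif(1) < sb) {
              reg$killed[id] <- b # never persists beyond its FAD bin
            } else {
              newborn_pool <- c(newborn_pool, id)
            }
          }
          chosen <- c(chosen, id)
        }
      }
      # last occurrences: draw from the established pool and kill; species
      # from longevity-boosted hotspots carry proportionally lower hazard
      if (cat_counts[2] > 0) {
        pool <- setdiff(c(established, dying), c(chosen, extirpated))
        take <- min(length(pool), cat_counts[2])
        if (take > 0) {
          wts <- ifelse(reg$hotspot_born[pool] &
                          cfg$hotspot_longevity_mult > 1,
                        1 / cfg$hotspot_longevity_mult, 1)
          got <- pool[sample.int(length(pool), take, prob = wts)]
          reg$killed[got] <- b
          dying <- union(dying, got)
          established <- setdiff(established, got)
          chosen <- c(chosen, got)
        }
      }
      # mid occurrences: retained locality fauna topped up by immigrants
      n_mid <- cat_counts[3]
      if (n_mid > 0) {
        cand <- fauna_prev[[l]]
        cand <- cand[is.na(reg$killed[cand]) & reg$birth[cand] < b]
        cand <- setdiff(cand, chosen)
        if (circle_loc[l]) cand <- setdiff(cand, extirpated)
        # the longevity boost protects record persistence as well as the
        # kill hazard: boosted species are more widespread and persistent
        pr_cand <- ifelse(reg$hotspot_born[cand] &
                            cfg$hotspot_longevity_mult > 1,
                          1 - (1 - cfg$p_retain) / cfg$hotspot_longevity_mult,
                          cfg$p_retain)
        retained <- cand[stats::runif(length(cand)) < pr_cand]
        if (in_circle(imm_specs, loc$lon[l], loc$lat[l])) {
          retained <- retained[stats::runif(length(retained)) >=
                                 imm_specs$frac[1]]
        }
        if (length(retained) > n_mid) {
          retained <- retained[sample.int(length(retained), n_mid)]
        }
        slots <- n_mid - length(retained)
        imm <- integer()
        if (slots > 0 && refuge_ok[l] && length(refugees) > 0) {
          take <- min(length(refugees), slots)
          pick <- refugees[seq_len(take)]
          refugees <- refugees[-seq_len(take)]
          imm <- pick
          slots <- slots - take
        }
        if (slots > 0) {
          pool <- setdiff(established, c(chosen, retained, imm))
          if (circle_loc[l]) pool <- setdiff(pool, extirpated)
          take <- min(length(pool), slots)
          if (take > 0) imm <- c(imm, pool[sample.int(length(pool), take)])
        }
        chosen <- c(chosen, retained, imm)
      }
      chosen <- unique(chosen)
      fauna_now[[l]] <- chosen
      occ_species <- c(occ_species, chosen)
      occ_loc <- c(occ_loc, rep(l, length(chosen)))
      occ_bin <- c(occ_bin, rep(b, length(chosen)))
    }
    fauna_prev <- fauna_now
    record_prev <- unique(occ_species[occ_bin == b])
  }

  sp_id <- sprintf("S%04d", seq_along(reg$birth))
  raw <- data.frame(
    species = sp_id[occ_species],
    locality = loc$locality[occ_loc],
    lon = loc$lon[occ_loc],
    lat = loc$lat[occ_loc],
    bin = scheme$name[occ_bin],
    order = reg$order[occ_species],
    hypsodonty = c("bra", "mes", "hyp")[reg$hyp[occ_species]],
    lophs = reg$lop[occ_species],
    stringsAsFactors = FALSE
  )
  occurrences <- suppressMessages(
    normalize_occurrences(raw, scheme, drop_indeterminate = FALSE))
  ranges <- global_fad_lad(occurrences, scheme)
  species <- data.frame(
    species = sp_id,
    birth_bin = scheme$name[reg$birth],
    killed_bin = scheme$name[ifelse(is.na(reg$killed), NA_integer_,
                                    reg$killed)],
    home_lon = reg$lon, home_lat = reg$lat,
    hyp = reg$hyp, lop = reg$lop, order = reg$order,
    hotspot_born = reg$hotspot_born,
    stringsAsFactors = FALSE
  )
  truth_hs <- if (is.null(hs)) NULL else
    transform(hs, bin_name = scheme$name[bin])
  structure(list(
    occurrences = occurrences,
    scheme = scheme,
    truth = list(species = species, ranges = ranges, hotspots = truth_hs,
                 localities = loc,
                 config = cfg[setdiff(names(cfg), "hotspots")])
  ), class = "world")
}

#' Write a synthetic world to plain-text fixture files
#'
#' Writes `occurrences.csv` (readable by [read_occurrence_csv()]),
#' `bins.csv` (readable by [read_bin_scheme()]) and `truth.json`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory, created if needed.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(world, dir) {
  stopifnot(inherits(world, "world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(occurrences = file.path(dir, "occurrences.csv"),
             bins = file.path(dir, "bins.csv"),
             truth = file.path(dir, "truth.json"))
  write_occurrence_csv(world$occurrences, paths["occurrences"])
  write_bin_scheme(world$scheme, paths["bins"])
  truth <- world$truth
  truth$config$env_gradient <- as.list(truth$config$env_gradient)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
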