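# Replicate studies shared by the acceptance checks. Worlds use the
# generator defaults (the study conditions); grids use 2-degree spacing
# over the default region.

study_grid <- function() make_grid(-10, 20, 40, 52, 2)

# Did the detector flag any supported node inside the injected circle, in
# the injected bin, with the expected class?
.flagged_in_circle <- function(cells, spec, bin_name) {
  sub <- cells[cells$bin == bin_name, , drop = FALSE]
  inside <- great_circle_km(spec$lon, spec$lat, sub$lon, sub$lat) <=
    spec$radius_km
  any(sub$klass[inside] == "hotspot")
}

# Origination power: a cluster where 50% of occurrences are first
# occurrences against a 5% background.
origination_power_study <- function(n_reps, seed_base = 0) {
  grid <- study_grid()
  spec <- data.frame(lon = 5, lat = 46, radius_km = 300, bin = 3,
                     type = "first", frac = 0.5)
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    w <- generate_world(world_config(seed = seed_base + i, hotspots = spec))
    ranges <- global_fad_lad(w$occurrences, w$scheme)
    cells <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 500,
                             "first")
    hits[i] <- .flagged_in_circle(cells, spec, "B3")
  }
  mean(hits)
}

# Local-extinction power: a region losing 60% of its species across one
# transition (survivors elsewhere) against ~10% background locality loss.
local_extinction_power_study <- function(n_reps, seed_base = 0) {
  grid <- study_grid()
  spec <- data.frame(lon = 5, lat = 46, radius_km = 300, bin = 3,
                     type = "local_extinction", frac = 0.6)
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    w <- generate_world(world_config(seed = seed_base + i, hotspots = spec))
    ranges <- global_fad_lad(w$occurrences, w$scheme)
    cells <- detect_sorting_hotspots(w$occurrences, ranges, w$scheme, grid,
                                     500)
    lex <- cells[cells$direction == "local_extinction", , drop = FALSE]
    hits[i] <- .flagged_in_circle(lex, spec, "B3")
  }
  mean(hits)
}

# Null calibration: fraction of supported cells with tail probability
# below alpha in worlds with no injected hotspots.
null_calibration_study <- function(n_reps, seed_base = 0, alpha = 0.05) {
  grid <- study_grid()
  org_flag <- org_n <- srt_flag <- srt_n <- lex_flag <- lex_n <- 0
  for (i in seq_len(n_reps)) {
    w <- generate_world(world_config(seed = seed_base + i))
    ranges <- global_fad_lad(w$occurrences, w$scheme)
    org <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 500,
                           "first")
    sup <- org$klass != "unsupported"
    org_flag <- org_flag + sum(org$tail_prob[sup] < alpha)
    org_n <- org_n + sum(sup)
    srt <- detect_sorting_hotspots(w$occurrences, ranges, w$scheme, grid,
                                   500)
    ssup <- srt$klass != "unsupported"
    srt_flag <- srt_flag + sum(srt$tail_prob[ssup] < alpha, na.rm = TRUE)
    srt_n <- srt_n + sum(ssup)
    lsel <- ssup & srt$direction == "local_extinction"
    lex_flag <- lex_flag + sum(srt$tail_prob[lsel] < alpha, na.rm = TRUE)
    lex_n <- lex_n + sum(lsel)
  }
  c(origination = org_flag / org_n,
    sorting = srt_flag / srt_n,
    local_extinction = lex_flag / lex_n)
}

# Qualitative recovery study: origination hotspot on the arid (low-NPP)
# side of a longitudinal productivity gradient, with hotspot-born species
# given lower death hazard and higher persistence. Returns per-replicate
# indicators for the longevity ordering and the NPP contrast.
hotspot_quality_study <- function(n_reps, seed_base = 0) {
  grid <- study_grid()
  env <- list(base = 1400, lon_slope = -30, lat_slope = 0, bin_slope = 0,
              ref = 1100, scale = 300)
  npp_model <- npp_model_config(1500, -300, 100,
                                provenance = "synthetic study config")
  spec <- data.frame(lon = 15, lat = 46, radius_km = 450, bin = 3,
                     type = "first", frac = 0.5)
  ok_longevity <- ok_npp <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    w <- generate_world(world_config(
      seed = seed_base + i, n_bins = 10, n_localities = 80,
      hotspots = spec, hotspot_longevity_mult = 3, trait_coupling = 2,
      env_gradient = env))
    ranges <- global_fad_lad(w$occurrences, w$scheme)
    org <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 300,
                           "first")
    ss <- species_summaries(w$occurrences, ranges, w$scheme,
                            origination_cells = org)
    cmp <- hotspot_species_comparison(ss, "origination")
    ok_longevity[i] <- isTRUE(
      cmp$mean_longevity_myr[cmp$group == "hotspot"] >
        cmp$mean_longevity_myr[cmp$group == "background"])
    tg <- trait_grid(w$occurrences, grid, w$scheme, bins = "B3",
                     radius_km = 300, model = npp_model)
    es <- hotspot_environment_summary(tg, org[org$bin == "B3", ])
    ok_npp[i] <- isTRUE(es$median[es$group == "hotspot"] <
                          es$median[es$group == "background"])
  }
  list(longevity = mean(ok_longevity), npp = mean(ok_npp))
}
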