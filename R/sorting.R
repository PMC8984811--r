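#' Species lists of a focal area in two consecutive bins
#'
#' Lists the unique species with at least one positively weighted occurrence
#' (great-circle distance strictly below the radius) around the focal point
#' in each of two adjacent bins, then prunes from BOTH lists every species
#' that is globally first seen in the second bin or globally last seen in
#' the first bin. What remains are species that exist somewhere in the
#' world in both bins, so that a presence/absence change within the focal
#' area is sorting (immigration or local extinction), not true origination
#' or extinction.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param ranges [global_fad_lad()] on the global table.
#' @param lon,lat focal point in degrees.
#' @param bin1,bin2 names of two adjacent bins, `bin1` older.
#' @param scheme the [bin_scheme()].
#' @param radius_km focal-area radius (default 500).
#' @return A list with character vectors `bin1` and `bin2` of retained
#'   species.
#' @export
focal_species_lists <- function(occurrences, ranges, lon, lat, bin1, bin2,
                                scheme, radius_km = 500) {
  o1 <- bin_ordinal(scheme, bin1); o2 <- bin_ordinal(scheme, bin2)
  if (is.na(o1) || is.na(o2) || o2 != o1 + 1) {
    stop("bin1 and bin2 must be adjacent bins of the scheme, bin1 older")
  }
  in_area <- function(bin) {
    occ <- occurrences[occurrences$bin == bin, , drop = FALSE]
    if (nrow(occ) == 0) return(character())
    d <- great_circle_km(lon, lat, occ$lon, occ$lat)
    unique(occ$species[d < radius_km])
  }
  s1 <- in_area(bin1); s2 <- in_area(bin2)
  i <- match(c(s1, s2), ranges$species)
  prune <- ranges$species[stats::na.omit(unique(i))]
  prune <- prune[ranges$fad_ordinal[match(prune, ranges$species)] == o2 |
                   ranges$lad_ordinal[match(prune, ranges$species)] == o1]
  list(bin1 = setdiff(s1, prune), bin2 = setdiff(s2, prune))
}

# per-species weighted occurrence sums around a focal point in one bin,
# restricted to the given species; returns named numeric vector
.species_weighted_sums <- function(occurrences, lon, lat, bin, species,
                                   radius_km, kernel = "linear") {
  occ <- occurrences[occurrences$bin == bin &
                       occurrences$species %in% species, , drop = FALSE]
  out <- stats::setNames(numeric(length(species)), species)
  if (nrow(occ) == 0) return(out)
  d <- great_circle_km(lon, lat, occ$lon, occ$lat)
  w <- decay_weight(d, radius_km, kernel)
  s <- rowsum(w, occ$species)
  out[rownames(s)] <- s[, 1]
  out
}

#' Build the species-sorting candidate table
#'
#' For every grid node and every adjacent bin transition, builds one
#' candidate row per species in the relevant focal-area list (after
#' global-presence pruning by [focal_species_lists()]):
#'
#' * `direction = "local_extinction"`: one row per species listed in the
#'   earlier bin; `event = 1` iff the species is absent from the later-bin
#'   list (present in the focal area before, gone after, while globally
#'   extant in both bins).
#' * `direction = "immigration"`: one row per species listed in the later
#'   bin; `event = 1` iff absent from the earlier-bin list.
#'
#' Each row carries two kinds of weighted sums: `w_unit1`/`w_unit2`, the
#' species' own weighted occurrence sums within the focal area in the two
#' bins (diagnostics; by construction `w_unit2 = 0` exactly characterizes a
#' local-extinction event), and `x_unit1`/`x_unit2`, the area-total
#' weighted sampling intensities around the node in the two bins. The
#' sorting model regresses the event indicator on the area totals: an
#' apparent disappearance is much more likely when the later bin is poorly
#' sampled, and that is the baseline the model must absorb. (The species'
#' own sums cannot serve as covariates: the target is a deterministic
#' function of them, so the logistic fit would be completely separated.)
#'
#' @inheritParams focal_species_lists
#' @param grid data frame of focal points (`lon`, `lat`).
#' @param direction `"local_extinction"` or `"immigration"`.
#' @param transitions optional integer vector of earlier-bin ordinals to
#'   use; default all adjacent pairs.
#' @param kernel weight kernel.
#' @return A data frame with columns `node`, `lon`, `lat`, `bin1`, `bin2`,
#'   `species`, `w_unit1`, `w_unit2`, `x_unit1`, `x_unit2`, `event`.
#' @export
build_sorting_rows <- function(occurrences, ranges, grid, scheme,
                               radius_km = 500,
                               direction = c("local_extinction", "immigration"),
                               transitions = NULL, kernel = "linear") {
  direction <- match.arg(direction)
  .sorting_rows_both(occurrences, ranges, grid, scheme, radius_km,
                     transitions, kernel)[[direction]]
}

# both directions in one pass (the weight matrices dominate the cost)
.sorting_rows_both <- function(occurrences, ranges, grid, scheme,
                               radius_km = 500, transitions = NULL,
                               kernel = "linear") {
  if (is.null(transitions)) transitions <- seq_len(nrow(scheme) - 1)
  species_all <- sort(unique(occurrences$species))
  fad <- ranges$fad_ordinal[match(species_all, ranges$species)]
  lad <- ranges$lad_ordinal[match(species_all, ranges$species)]
  # nodes x species: weighted sums and in-area indicators for one bin,
  # via locality-level incidence (dedup guarantees 0/1 entries)
  bin_mats <- function(bin) {
    occ <- occurrences[occurrences$bin == bin, , drop = FALSE]
    if (nrow(occ) == 0) {
      z <- matrix(0, nrow(grid), length(species_all))
      return(list(w = z, present = z > 0))
    }
    key <- paste(occ$locality, occ$lon, occ$lat, sep = "\r")
    fst <- !duplicated(key)
    inc <- matrix(0, sum(fst), length(species_all))
    inc[cbind(match(key, key[fst]),
              match(occ$species, species_all))] <- 1
    wm <- .weight_matrix(grid$lon, grid$lat, occ$lon[fst], occ$lat[fst],
                         radius_km, kernel)
    d <- attr(wm, "distance_km")
    list(w = wm %*% inc, present = ((d < radius_km) %*% inc) > 0)
  }
  out <- list(local_extinction = list(), immigration = list())
  mats <- NULL # reuse the later bin's matrices for the next transition
  for (b in transitions) {
    bin1 <- bin_at(scheme, b); bin2 <- bin_at(scheme, b + 1)
    m1 <- if (!is.null(mats) && mats$bin == bin1) mats$m else bin_mats(bin1)
    m2 <- bin_mats(bin2)
    mats <- list(bin = bin2, m = m2)
    xa1 <- rowSums(m1$w); xa2 <- rowSums(m2$w)
    keep_sp <- !(fad == b + 1 | lad == b) # global-presence pruning
    for (g in seq_len(nrow(grid))) {
      for (dir in c("local_extinction", "immigration")) {
        cand_idx <- which(keep_sp &
                            (if (dir == "local_extinction")
                               m1$present[g, ] else m2$present[g, ]))
        if (length(cand_idx) == 0) next
        absent <- if (dir == "local_extinction") {
          !m2$present[g, cand_idx]
        } else {
          !m1$present[g, cand_idx]
        }
        out[[dir]][[length(out[[dir]]) + 1]] <- data.frame(
          node = g, lon = grid$lon[g], lat = grid$lat[g],
          bin1 = bin1, bin2 = bin2, species = species_all[cand_idx],
          w_unit1 = m1$w[g, cand_idx], w_unit2 = m2$w[g, cand_idx],
          x_unit1 = xa1[g], x_unit2 = xa2[g],
          event = as.integer(absent),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  empty <- data.frame(node = integer(), lon = numeric(), lat = numeric(),
                      bin1 = character(), bin2 = character(),
                      species = character(), w_unit1 = numeric(),
                      w_unit2 = numeric(), x_unit1 = numeric(),
                      x_unit2 = numeric(), event = integer())
  lapply(out, function(o) {
    o <- do.call(rbind, o)
    if (is.null(o)) return(empty)
    rownames(o) <- NULL
    o
  })
}

#' Exact upper tail of a Poisson-binomial count
#'
#' `P(sum of independent Bernoulli(p_i) >= k)`, computed exactly by dynamic
#' programming over the count distribution. With all `p_i` equal this
#' reduces to the binomial tail.
#'
#' @param probabilities per-candidate event probabilities, each strictly in
#'   (0, 1).
#' @param k integer threshold, `0 <= k <= length(probabilities)`.
#' @return `P(X >= k)`.
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 1) # 0.75
#' @export
poisson_binomial_tail <- function(probabilities, k) {
  p <- as.numeric(probabilities)
  if (any(p <= 0 | p >= 1)) stop("probabilities must be strictly inside (0, 1)")
  k <- as.integer(round(k))
  if (k < 0) stop("k must be non-negative")
  if (k > length(p)) stop("k exceeds the number of candidates")
  if (k == 0) return(1)
  f <- 1 # distribution of the running count
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  sum(f[(k + 1):length(f)])
}

#' Detect immigration and local-extinction (sorting) hotspots
#'
#' Fits one pooled logistic model per direction on the sorting candidate
#' table (event indicator on the two weighted occurrence sums, with
#' intercept). Then, for every grid node and focal bin, computes the exact
#' Poisson-binomial exceedance probability of the observed event count
#' given the per-candidate model probabilities: immigration is assessed on
#' the transition into the focal bin, local extinction on the transition
#' out of it. Nodes need at least `min_support` weighted occurrences in the
#' focal, preceding and subsequent bins to be assessed.
#'
#' @inheritParams build_sorting_rows
#' @param alpha,beta classification thresholds (0.05 / 0.95).
#' @param min_support minimum weighted occurrence count in each of the
#'   three bins around the focal bin (default 1).
#' @param test `"poisson_binomial"` (exact, default) or `"binomial"` (tail
#'   of a binomial with the candidates' mean probability, the literal
#'   reading of the method description).
#' @return A data frame with one row per node, focal bin and direction:
#'   `lon`, `lat`, `bin`, `direction`, `n_candidates`, `k_events`,
#'   `tail_prob`, `klass`.
#' @export
detect_sorting_hotspots <- function(occurrences, ranges, scheme, grid,
                                    radius_km = 500, alpha = 0.05,
                                    beta = 0.95, min_support = 1,
                                    kernel = "linear",
                                    test = c("poisson_binomial", "binomial")) {
  test <- match.arg(test)
  n <- nrow(scheme)
  if (n < 3) stop("scheme needs at least 3 bins for sorting analysis")
  rows <- .sorting_rows_both(occurrences, ranges, grid, scheme, radius_km,
                             kernel = kernel)
  models <- lapply(rows, function(r) {
    if (nrow(r) == 0 || length(unique(r$event)) < 2) {
      return(NULL) # no events anywhere: nothing exceeds expectation
    }
    fit_event_model(data.frame(x_before = r$x_unit1, x_now = r$x_unit2,
                               y = r$event))
  })
  # weighted support per node x bin for the support rule
  support <- matrix(unlist(lapply(seq_len(n), function(b) {
    src <- .bin_locality_counts(occurrences, bin_at(scheme, b))
    if (nrow(src) == 0) return(numeric(nrow(grid)))
    w <- .weight_matrix(grid$lon, grid$lat, src$lon, src$lat, radius_km,
                        kernel)
    as.numeric(w %*% src$n)
  })), nrow = nrow(grid))
  out <- list()
  for (b in 2:(n - 1)) {
    supported <- support[, b - 1] >= min_support &
      support[, b] >= min_support & support[, b + 1] >= min_support
    for (dir in c("immigration", "local_extinction")) {
      r <- rows[[dir]]
      b1 <- if (dir == "immigration") bin_at(scheme, b - 1) else bin_at(scheme, b)
      sub <- r[r$bin1 == b1, , drop = FALSE]
      tails <- rep(NA_real_, nrow(grid))
      kn <- matrix(0L, nrow(grid), 2)
      if (nrow(sub) > 0) {
        pr <- if (is.null(models[[dir]])) NULL else {
          pmin(pmax(predict_event_prob(models[[dir]], sub$x_unit1,
                                       sub$x_unit2), 1e-12), 1 - 1e-12)
        }
        for (g in unique(sub$node)) {
          sel <- sub$node == g
          kk <- sum(sub$event[sel])
          kn[g, ] <- c(kk, sum(sel))
          tails[g] <- if (is.null(pr)) {
            # constant event indicator in the pooled table: with zero events
            # anywhere k = 0 and the exceedance is trivially 1
            if (kk == 0) 1 else NA_real_
          } else if (test == "poisson_binomial") {
            poisson_binomial_tail(pr[sel], kk)
          } else {
            binomial_tail(kk, sum(sel), mean(pr[sel]))
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        lon = grid$lon, lat = grid$lat, bin = bin_at(scheme, b),
        direction = dir, n_candidates = kn[, 2], k_events = kn[, 1],
        tail_prob = tails,
        klass = ifelse(!supported | is.na(tails), "unsupported",
                       ifelse(tails < alpha, "hotspot",
                              ifelse(tails > beta, "stable", "neutral"))),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  attr(out, "models") <- models
  rownames(out) <- NULL
  out
}

#' Joint sorting classification per node and bin
#'
#' Combines the two directions of [detect_sorting_hotspots()] into the
#' joint map classes: immigration hotspot, local-extinction hotspot, both
#' ("sorting-turnover"), stable (both tails above `beta`), neutral or
#' unsupported.
#'
#' @param sorting_grid output of [detect_sorting_hotspots()].
#' @inheritParams classify_cell
#' @return A data frame `lon`, `lat`, `bin`, `tail_prob_immigration`,
#'   `tail_prob_local_extinction`, `klass`.
#' @export
classify_sorting_grid <- function(sorting_grid, alpha = 0.05, beta = 0.95) {
  imm <- sorting_grid[sorting_grid$direction == "immigration", ]
  lex <- sorting_grid[sorting_grid$direction == "local_extinction", ]
  key <- function(g) paste(g$lon, g$lat, g$bin, sep = "\r")
  j <- match(key(imm), key(lex))
  out <- data.frame(
    lon = imm$lon, lat = imm$lat, bin = imm$bin,
    tail_prob_immigration = imm$tail_prob,
    tail_prob_local_extinction = lex$tail_prob[j],
    stringsAsFactors = FALSE
  )
  kl <- classify_cell(out$tail_prob_immigration,
                      out$tail_prob_local_extinction, alpha, beta)
  kl[kl == "origination-hotspot"] <- "immigration-hotspot"
  kl[kl == "extinction-hotspot"] <- "local-extinction-hotspot"
  kl[kl == "turnover"] <- "sorting-turnover"
  kl[imm$klass == "unsupported" | lex$klass[j] == "unsupported"] <- "unsupported"
  out$klass <- kl
  rownames(out) <- NULL
  out
}
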