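# orders whose dental traits enter the ecometric community means
.herbivore_orders <- c("Perissodactyla", "Artiodactyla", "Primates",
                       "Proboscidea", "Hyracoidea")

#' NPP transfer-function configuration
#'
#' The regression transfer function mapping community mean hypsodonty (HYP,
#' 1-3) and capped loph count (LOP, 0-2) to net primary productivity in
#' g C m-2 yr-1. The published coefficient sets are configuration, not code:
#' supply the coefficients of whichever calibration you use, with a
#' provenance note.
#'
#' @param intercept,hyp,lop,interaction finite coefficients of
#'   `npp = intercept + hyp*HYP + lop*LOP + interaction*HYP*LOP`.
#' @param provenance free-text note on where the coefficients come from.
#' @return An object of class `npp_model`.
#' @export
npp_model_config <- function(intercept, hyp, lop, interaction = 0,
                             provenance = "unspecified") {
  co <- c(intercept = intercept, hyp = hyp, lop = lop,
          interaction = interaction)
  if (any(!is.finite(co))) stop("NPP model coefficients must be finite")
  structure(list(coefficients = co, provenance = provenance),
            class = "npp_model")
}

#' Estimate net primary productivity from community trait means
#'
#' Deterministic evaluation of the configured transfer function; raw
#' predictions below zero are clipped to zero (NPP is non-negative).
#'
#' @param mean_hyp,mean_lop community trait means, from [grid_trait_means()].
#' @param model an [npp_model_config()]. There is no default: coefficients
#'   must be supplied explicitly.
#' @return NPP in g C m-2 yr-1, vectorized; `NA` where a mean is `NA`.
#' @export
estimate_npp <- function(mean_hyp, mean_lop, model) {
  if (missing(model) || !inherits(model, "npp_model")) {
    stop("supply an npp_model_config() with transfer-function coefficients")
  }
  co <- model$coefficients
  raw <- co["intercept"] + co["hyp"] * mean_hyp + co["lop"] * mean_lop +
    co["interaction"] * mean_hyp * mean_lop
  unname(pmax(raw, 0))
}

#' Distance-weighted community trait means around a focal point
#'
#' Weighted arithmetic means of the encoded hypsodonty and loph scores of
#' large herbivore occurrences around a focal point, using the same linear
#' distance-decay weights as the hotspot analysis. Only occurrences of the
#' allowed orders with both traits recorded contribute; the weighted count
#' of those trait-bearing occurrences is the cell's support, and means are
#' reported only when support reaches `min_support`.
#'
#' @param occurrences a normalized occurrence data frame.
#' @param lon,lat focal point in degrees.
#' @param bin bin name.
#' @param radius_km aggregation radius (default 500).
#' @param orders orders included in the community (default the five large
#'   plant-eating mammal orders).
#' @param min_support minimum weighted trait-bearing support for means to be
#'   defined (default 2).
#' @param kernel weight kernel.
#' @return A list with `mean_hyp`, `mean_lop` (NA below support) and
#'   `weighted_support`.
#' @export
grid_trait_means <- function(occurrences, lon, lat, bin, radius_km = 500,
                             orders = .herbivore_orders, min_support = 2,
                             kernel = "linear") {
  occ <- occurrences[occurrences$bin == bin &
                       occurrences$order_name %in% orders &
                       !is.na(occurrences$hyp) & !is.na(occurrences$lop), ,
                     drop = FALSE]
  if (nrow(occ) == 0) {
    return(list(mean_hyp = NA_real_, mean_lop = NA_real_,
                weighted_support = 0))
  }
  d <- great_circle_km(lon, lat, occ$lon, occ$lat)
  w <- decay_weight(d, radius_km, kernel)
  support <- sum(w)
  if (support < min_support) {
    return(list(mean_hyp = NA_real_, mean_lop = NA_real_,
                weighted_support = support))
  }
  list(mean_hyp = sum(w * occ$hyp) / support,
       mean_lop = sum(w * occ$lop) / support,
       weighted_support = support)
}

#' Trait and NPP grid over all bins
#'
#' Applies [grid_trait_means()] at every grid node and bin and, when a
#' transfer function is configured, evaluates NPP.
#'
#' @inheritParams grid_trait_means
#' @param grid data frame of focal points (`lon`, `lat`).
#' @param scheme the [bin_scheme()].
#' @param bins bin names to evaluate; default all.
#' @param model optional [npp_model_config()]; when `NULL` the `npp` column
#'   is omitted.
#' @return A data frame `lon`, `lat`, `bin`, `mean_hyp`, `mean_lop`,
#'   `weighted_support` and (with a model) `npp`.
#' @export
trait_grid <- function(occurrences, grid, scheme, bins = scheme$name,
                       radius_km = 500, orders = .herbivore_orders,
                       min_support = 2, model = NULL, kernel = "linear") {
  out <- list()
  for (bin in bins) {
    occ <- occurrences[occurrences$bin == bin &
                         occurrences$order_name %in% orders &
                         !is.na(occurrences$hyp) & !is.na(occurrences$lop), ,
                       drop = FALSE]
    res <- data.frame(lon = grid$lon, lat = grid$lat, bin = bin,
                      stringsAsFactors = FALSE)
    if (nrow(occ) == 0) {
      res$mean_hyp <- NA_real_; res$mean_lop <- NA_real_
      res$weighted_support <- 0
    } else {
      w <- .weight_matrix(grid$lon, grid$lat, occ$lon, occ$lat, radius_km,
                          kernel)
      support <- as.numeric(w %*% rep(1, nrow(occ)))
      ok <- support >= min_support
      res$mean_hyp <- ifelse(ok, as.numeric(w %*% occ$hyp) / support, NA)
      res$mean_lop <- ifelse(ok, as.numeric(w %*% occ$lop) / support, NA)
      res$weighted_support <- support
    }
    if (!is.null(model)) {
      res$npp <- estimate_npp(res$mean_hyp, res$mean_lop, model)
    }
    out[[length(out) + 1]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hotspot versus background environment summaries
#'
#' Pairs the trait/NPP grid with a hotspot classification grid and, per bin,
#' summarizes the NPP of hotspot cells against the remaining supported
#' cells (five-number summary plus mean and count). Cells without defined
#' NPP (support below the trait threshold) are excluded from both groups.
#'
#' @param trait_cells output of [trait_grid()] including an `npp` column.
#' @param hotspot_cells a classified grid with `lon`, `lat`, `bin`, `klass`
#'   (e.g. from [detect_hotspots()] or [classify_event_grids()]).
#' @param hotspot_class the `klass` value treated as "hotspot" (default
#'   `"hotspot"`, matching [detect_hotspots()] output).
#' @return A data frame with one row per bin and group (`hotspot` /
#'   `background`): `bin`, `group`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`.
#' @export
hotspot_environment_summary <- function(trait_cells, hotspot_cells,
                                        hotspot_class = "hotspot") {
  if (!"npp" %in% names(trait_cells)) {
    stop("trait_cells must carry an npp column (supply a transfer model)")
  }
  key <- function(g) paste(g$lon, g$lat, g$bin, sep = "\r")
  j <- match(key(trait_cells), key(hotspot_cells))
  df <- trait_cells[!is.na(j) & !is.na(trait_cells$npp), , drop = FALSE]
  kl <- hotspot_cells$klass[j[!is.na(j) & !is.na(trait_cells$npp)]]
  df <- df[kl != "unsupported", , drop = FALSE]
  kl <- kl[kl != "unsupported"]
  grp <- ifelse(kl == hotspot_class, "hotspot", "background")
  out <- list()
  for (bin in unique(df$bin)) {
    for (g in c("hotspot", "background")) {
      x <- df$npp[df$bin == bin & grp == g]
      if (length(x) == 0) {
        out[[length(out) + 1]] <- data.frame(
          bin = bin, group = g, n = 0L, min = NA_real_, q1 = NA_real_,
          median = NA_real_, q3 = NA_real_, max = NA_real_,
          mean = NA_real_, stringsAsFactors = FALSE)
      } else {
        q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          bin = bin, group = g, n = length(x), min = q[1], q1 = q[2],
          median = q[3], q3 = q[4], max = q[5], mean = mean(x),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
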