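#' Eligible analysis bins for an event type
#'
#' Origination analysis runs on every bin that has an older neighbour and is
#' not the youngest bin of the scheme (the terminal bins only anchor
#' first/last appearances); extinction analysis runs on every bin that has a
#' younger neighbour. With an 18-bin MN/MQ scheme this yields MN2-MQ18 for
#' origination and MN1-MQ18 for extinction.
#'
#' @param scheme a [bin_scheme()].
#' @param event `"first"` (origination) or `"last"` (extinction).
#' @return integer vector of eligible bin ordinals.
#' @export
eligible_event_bins <- function(scheme, event = c("first", "last")) {
  event <- match.arg(event)
  n <- nrow(scheme)
  if (n < 3) stop("scheme needs at least 3 bins for event analysis")
  if (event == "first") 2:(n - 1) else 1:(n - 1)
}

# covariate bins (other, focal) for one event bin ordinal
.covariate_ordinals <- function(b, event) {
  if (event == "first") c(other = b - 1, focal = b) else c(other = b + 1, focal = b)
}

#' Build the event-regression row table
#'
#' For every locality in every eligible bin, computes the weighted sampling
#' intensities around that locality in the focal bin (`x_now`) and in the
#' adjacent bin of the transition (`x_before`: the previous bin for
#' origination, the following bin for extinction), then emits one row per
#' raw occurrence at the locality with target `y = 1` iff that occurrence is
#' a first (resp. last) occurrence of its species per the global FAD/LAD.
#' Every in-scope occurrence contributes exactly one row.
#'
#' @param occurrences a normalized occurrence data frame (typically the
#'   region-filtered table).
#' @param ranges [global_fad_lad()] result computed on the global table.
#' @param scheme the [bin_scheme()].
#' @param event `"first"` or `"last"`.
#' @param radius_km spatial aggregation radius (default 500).
#' @param kernel weight kernel, see [decay_weight()].
#' @return A data frame with columns `species`, `locality`, `bin`, `lon`,
#'   `lat`, `x_before`, `x_now`, `y`.
#' @export
build_event_rows <- function(occurrences, ranges, scheme,
                             event = c("first", "last"), radius_km = 500,
                             kernel = "linear") {
  event <- match.arg(event)
  occ <- flag_event_occurrences(occurrences, ranges)
  flag <- if (event == "first") occ$is_first else occ$is_last
  if (anyNA(flag)) stop("some species lack global FAD/LAD entries")
  bins <- eligible_event_bins(scheme, event)
  out <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    b <- bins[i]
    cov <- .covariate_ordinals(b, event)
    in_b <- occ$bin_ordinal == b
    if (!any(in_b)) next
    occ_b <- occ[in_b, , drop = FALSE]
    locs <- .bin_locality_counts(occ_b, bin_at(scheme, b))
    x_now <- .weighted_total(locs, occ, bin_at(scheme, cov["focal"]),
                             radius_km, kernel)
    x_bef <- .weighted_total(locs, occ, bin_at(scheme, cov["other"]),
                             radius_km, kernel)
    j <- match(paste(occ_b$locality, occ_b$lon, occ_b$lat, sep = "\r"),
               paste(locs$locality, locs$lon, locs$lat, sep = "\r"))
    out[[i]] <- data.frame(
      species = occ_b$species, locality = occ_b$locality,
      bin = occ_b$bin, lon = occ_b$lon, lat = occ_b$lat,
      x_before = x_bef[j], x_now = x_now[j],
      y = as.integer(flag[in_b]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) stop("no rows in scope for event model")
  rownames(out) <- NULL
  out
}

# weighted totals of all occurrences of one bin around each focal row
.weighted_total <- function(focals, occurrences, bin, radius_km, kernel) {
  src <- .bin_locality_counts(occurrences, bin)
  if (nrow(src) == 0 || nrow(focals) == 0) return(numeric(nrow(focals)))
  w <- .weight_matrix(focals$lon, focals$lat, src$lon, src$lat,
                      radius_km, kernel)
  as.numeric(w %*% src$n)
}

#' Fit the two-covariate logistic event model
#'
#' Maximum-likelihood logistic regression of the per-occurrence event
#' indicator on the weighted sampling intensities of the two bins of the
#' transition, with an intercept. The fitted model gives the probability
#' that an occurrence made under given local sampling conditions is a
#' first (or last) occurrence.
#'
#' @param rows output of [build_event_rows()] (needs columns `x_before`,
#'   `x_now`, `y`).
#' @return An object of class `event_model`: a list with `intercept`,
#'   `beta_before`, `beta_now`, `converged`, `n_rows` and the underlying
#'   `glm` fit.
#' @export
fit_event_model <- function(rows) {
  stopifnot(all(c("x_before", "x_now", "y") %in% names(rows)))
  if (length(unique(rows$y)) < 2) {
    stop("single-class targets: event indicator is constant, cannot fit")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x_before + x_now, family = stats::binomial(),
               data = rows),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || any(!is.finite(stats::coef(fit)))) {
    stop("complete separation: logistic fit did not converge")
  }
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    beta_before = unname(stats::coef(fit)["x_before"]),
    beta_now = unname(stats::coef(fit)["x_now"]),
    converged = !separation,
    n_rows = nrow(rows),
    fit = fit
  ), class = "event_model")
}

#' Predicted event probability
#'
#' @param model an `event_model` from [fit_event_model()].
#' @param x_before,x_now weighted sampling intensities.
#' @return probabilities in (0, 1).
#' @export
predict_event_prob <- function(model, x_before, x_now) {
  eta <- model$intercept + model$beta_before * x_before +
    model$beta_now * x_now
  stats::plogis(eta)
}

#' @export
print.event_model <- function(x, ...) {
  cat("Logistic event model (", x$n_rows, " rows)\n", sep = "")
  cat(sprintf("  intercept  %+.4f\n  beta_before %+.4f\n  beta_now    %+.4f\n",
              x$intercept, x$beta_before, x$beta_now))
  if (!x$converged) cat("  (separation warning during fit)\n")
  invisible(x)
}

#' Upper tail probability of a (continuously extended) binomial
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`. For integer `k` and `n` this is
#' the exact binomial survival sum; non-integer weighted counts are handled
#' by the regularized incomplete beta function continuation
#' `I_p(k, n - k + 1)`, which coincides with the exact sum on integers.
#' `k = 0` returns 1 by convention.
#'
#' @param k observed (possibly weighted, non-integer) event count, `0 <= k <= n`.
#' @param n total (possibly weighted) trial count, `> 0`.
#' @param p per-trial event probability, strictly inside (0, 1).
#' @return `P(X >= k)`, vectorized over the inputs.
#' @examples
#' binomial_tail(4, 4, 0.5) # 0.0625
#' @export
binomial_tail <- function(k, n, p) {
  m <- max(length(k), length(n), length(p))
  k <- rep_len(k, m); n <- rep_len(n, m); p <- rep_len(p, m)
  if (any(k < 0)) stop("k must be non-negative")
  if (any(k > n + 1e-9)) stop("k must not exceed n")
  if (any(p <= 0 | p >= 1)) stop("p must be strictly inside (0, 1)")
  k <- pmin(k, n)
  out <- rep(1, m)
  pos <- k > 0
  out[pos] <- stats::pbeta(p[pos], k[pos], n[pos] - k[pos] + 1)
  out
}

#' Classify a grid cell from its two exceedance probabilities
#'
#' A cell is an origination hotspot when the origination tail probability
#' alone is below `alpha`, an extinction hotspot when the extinction tail
#' alone is below `alpha`, a turnover cell when both are, stable when both
#' exceed `beta`, and neutral otherwise.
#'
#' @param tail_prob_first,tail_prob_last exceedance probabilities in `[0, 1]`.
#' @param alpha significance threshold for "exceptionally many" (default 0.05).
#' @param beta threshold for "exceptionally few" (default 0.95).
#' @return character vector over
#'   `{"origination-hotspot", "extinction-hotspot", "turnover", "stable",
#'   "neutral"}`; `NA` inputs give `"unsupported"`.
#' @export
classify_cell <- function(tail_prob_first, tail_prob_last,
                          alpha = 0.05, beta = 0.95) {
  m <- max(length(tail_prob_first), length(tail_prob_last))
  f <- rep_len(tail_prob_first, m); l <- rep_len(tail_prob_last, m)
  out <- rep("neutral", m)
  out[f < alpha & l < alpha] <- "turnover"
  out[f < alpha & l >= alpha] <- "origination-hotspot"
  out[f >= alpha & l < alpha] <- "extinction-hotspot"
  out[f > beta & l > beta] <- "stable"
  out[is.na(f) | is.na(l)] <- "unsupported"
  out
}

#' Detect origination or extinction hotspots on a grid
#'
#' Fits (or reuses) the pooled logistic event model, then, for every grid
#' node and eligible bin, computes the weighted total and event occurrence
#' counts around the node, the model's expected per-occurrence event
#' probability at the node's own sampling covariates, and the binomial
#' exceedance probability of the observed weighted event count. Nodes with
#' weighted support below `min_support` are reported as `"unsupported"`.
#'
#' @inheritParams build_event_rows
#' @param grid data frame of focal points (`lon`, `lat`), e.g. from
#'   [make_grid()].
#' @param alpha,beta classification thresholds (defaults 0.05 / 0.95).
#' @param min_support minimum weighted occurrence count for a node to be
#'   assessed (default 1).
#' @param model optional pre-fitted `event_model`; fitted from the data when
#'   `NULL`.
#' @return A data frame with one row per grid node per eligible bin:
#'   `lon`, `lat`, `bin`, `event`, `n_weighted`, `k_weighted`, `x_before`,
#'   `x_now`, `p_event`, `tail_prob`, `min_distance_km`, `klass` (one of
#'   `hotspot`, `stable`, `neutral`, `unsupported`).
#' @export
detect_hotspots <- function(occurrences, ranges, scheme, grid,
                            radius_km = 500, event = c("first", "last"),
                            alpha = 0.05, beta = 0.95, min_support = 1,
                            kernel = "linear", model = NULL) {
  event <- match.arg(event)
  if (is.null(model)) {
    rows <- build_event_rows(occurrences, ranges, scheme, event,
                             radius_km, kernel)
    if (sum(rows$y) == 0) {
      # no events anywhere in scope: exceedance is trivially impossible
      model <- NA
    } else {
      model <- fit_event_model(rows)
    }
  }
  occ <- flag_event_occurrences(occurrences, ranges)
  flag <- if (event == "first") occ$is_first else occ$is_last
  bins <- eligible_event_bins(scheme, event)
  out <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    b <- bins[i]
    cov <- .covariate_ordinals(b, event)
    src <- .bin_locality_counts(occ, bin_at(scheme, b),
                                flags = list(k = flag))
    res <- data.frame(lon = grid$lon, lat = grid$lat,
                      bin = bin_at(scheme, b), event = event,
                      stringsAsFactors = FALSE)
    if (nrow(src) == 0) {
      res$n_weighted <- 0; res$k_weighted <- 0
      res$x_before <- NA_real_; res$x_now <- NA_real_
      res$p_event <- NA_real_; res$tail_prob <- NA_real_
      res$min_distance_km <- Inf
    } else {
      w <- .weight_matrix(grid$lon, grid$lat, src$lon, src$lat,
                          radius_km, kernel)
      d <- attr(w, "distance_km")
      res$n_weighted <- as.numeric(w %*% src$n)
      res$k_weighted <- as.numeric(w %*% src$k)
      res$x_now <- .weighted_total(grid, occ, bin_at(scheme, cov["focal"]),
                                   radius_km, kernel)
      res$x_before <- .weighted_total(grid, occ, bin_at(scheme, cov["other"]),
                                      radius_km, kernel)
      if (inherits(model, "event_model")) {
        res$p_event <- predict_event_prob(model, res$x_before, res$x_now)
        res$tail_prob <- ifelse(
          res$n_weighted > 0,
          binomial_tail(pmin(res$k_weighted, res$n_weighted),
                        pmax(res$n_weighted, 1e-12), res$p_event),
          NA_real_)
      } else {
        # zero events in scope: P(X >= 0) = 1 at every supported node
        res$p_event <- NA_real_
        res$tail_prob <- ifelse(res$n_weighted > 0, 1, NA_real_)
      }
      res$min_distance_km <- apply(d, 1, min)
    }
    res$klass <- ifelse(
      res$n_weighted < min_support | is.na(res$tail_prob), "unsupported",
      ifelse(res$tail_prob < alpha, "hotspot",
             ifelse(res$tail_prob > beta, "stable", "neutral")))
    out[[i]] <- res
  }
  out <- do.call(rbind, out)
  attr(out, "model") <- model
  rownames(out) <- NULL
  out
}

#' Combine origination and extinction grids into the joint classification
#'
#' Merges the per-event hotspot grids of [detect_hotspots()] and assigns
#' each node/bin the joint class of [classify_cell()]. Only bins present in
#' both grids are classified (the oldest analysis bin has no origination
#' assessment).
#'
#' @param first_grid,last_grid outputs of [detect_hotspots()] for
#'   `event = "first"` and `event = "last"`.
#' @inheritParams classify_cell
#' @return A data frame with `lon`, `lat`, `bin`, `tail_prob_first`,
#'   `tail_prob_last`, `klass`.
#' @export
classify_event_grids <- function(first_grid, last_grid,
                                 alpha = 0.05, beta = 0.95) {
  key <- function(g) paste(g$lon, g$lat, g$bin, sep = "\r")
  j <- match(key(first_grid), key(last_grid))
  keep <- !is.na(j)
  out <- data.frame(
    lon = first_grid$lon[keep], lat = first_grid$lat[keep],
    bin = first_grid$bin[keep],
    tail_prob_first = first_grid$tail_prob[keep],
    tail_prob_last = last_grid$tail_prob[j[keep]],
    stringsAsFactors = FALSE
  )
  unsupported <- first_grid$klass[keep] == "unsupported" |
    last_grid$klass[j[keep]] == "unsupported"
  out$klass <- classify_cell(out$tail_prob_first, out$tail_prob_last,
                             alpha, beta)
  out$klass[unsupported] <- "unsupported"
  rownames(out) <- NULL
  out
}
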