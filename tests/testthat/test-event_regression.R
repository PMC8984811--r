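test_that("event rows reproduce the worked regression-dataset example", {
  toy <- fig_toy()
  rows <- build_event_rows(toy$occ, global_fad_lad(toy$occ, toy$scheme),
                           toy$scheme, "first", radius_km = 500)
  a <- rows[rows$locality == "A", ]
  expect_equal(nrow(a), 4)
  expect_equal(unique(a$x_before), 1.5, tolerance = 1e-9)
  expect_equal(unique(a$x_now), 4.6, tolerance = 1e-9)
  expect_equal(sort(a$y), c(0, 0, 0, 1))
  # every focal-bin occurrence appears exactly once
  expect_equal(nrow(rows), sum(toy$occ$bin == "T1"))
})

test_that("event rows equal a brute-force enumeration on a small fixture", {
  s <- toy_scheme(4)
  set.seed(11)
  n <- 30
  occ <- toy_occ(
    species = sample(paste0("sp", 1:8), n, replace = TRUE),
    locality = sample(c("L1", "L2"), n, replace = TRUE),
    lon = 0, lat = 48, bin = sample(s$name, n, replace = TRUE),
    scheme = s
  )
  occ$lat <- ifelse(occ$locality == "L2", 48 + km_to_lat(200), 48)
  ranges <- global_fad_lad(occ, s)
  for (event in c("first", "last")) {
    rows <- build_event_rows(occ, ranges, s, event, radius_km = 500)
    flagged <- flag_event_occurrences(occ, ranges)
    flag <- if (event == "first") flagged$is_first else flagged$is_last
    bins <- eligible_event_bins(s, event)
    # independent enumeration: loop raw occurrences, recompute covariates
    # from scratch with weighted_occurrence_count
    expected_n <- 0
    for (i in seq_len(nrow(occ))) {
      b <- occ$bin_ordinal[i]
      if (!(b %in% bins)) next
      expected_n <- expected_n + 1
      other_bin <- if (event == "first") s$name[b - 1] else s$name[b + 1]
      x_now <- weighted_occurrence_count(occ, occ$lon[i], occ$lat[i],
                                         bin = s$name[b],
                                         radius_km = 500)$value
      x_other <- weighted_occurrence_count(occ, occ$lon[i], occ$lat[i],
                                           bin = other_bin,
                                           radius_km = 500)$value
      hit <- rows$species == occ$species[i] &
        rows$locality == occ$locality[i] & rows$bin == occ$bin[i]
      expect_equal(sum(hit), 1)
      expect_equal(rows$x_now[hit], x_now, tolerance = 1e-9)
      expect_equal(rows$x_before[hit], x_other, tolerance = 1e-9)
      expect_equal(rows$y[hit], as.integer(flag[i]))
    }
    expect_equal(nrow(rows), expected_n)
    expect_equal(sum(rows$y), sum(flag[occ$bin_ordinal %in% bins]))
  }
})

test_that("logistic fit recovers, rejects degeneracy, and scales", {
  set.seed(21)
  n <- 4000
  rows <- data.frame(x_before = runif(n, 0, 10), x_now = runif(n, 0, 10))
  eta <- -1 + 0.3 * rows$x_before + 0.1 * rows$x_now
  rows$y <- rbinom(n, 1, plogis(eta))
  m <- fit_event_model(rows)
  se <- sqrt(diag(vcov(m$fit)))
  expect_lt(abs(m$intercept - (-1)), 3 * se[1])
  expect_lt(abs(m$beta_before - 0.3), 3 * se[2])
  expect_lt(abs(m$beta_now - 0.1), 3 * se[3])
  expect_true(m$converged)
  # duplicating every row leaves the estimates unchanged
  m2 <- fit_event_model(rbind(rows, rows))
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-6)
  expect_equal(m2$beta_before, m$beta_before, tolerance = 1e-6)
  # single-class targets are a hard failure
  rows$y <- 0
  expect_error(fit_event_model(rows), "single-class")
})

test_that("binomial tail matches closed forms and is monotone", {
  expect_equal(binomial_tail(4, 4, 0.5), 0.0625, tolerance = 1e-12)
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(1, 3, 0.2), 1 - 0.8^3, tolerance = 1e-12)
  # monotone increasing in p, decreasing in k
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(binomial_tail(3, 10, p)) > 0))
  expect_true(all(diff(binomial_tail(c(1, 2, 3, 4.5), 10, 0.3)) < 0))
  expect_error(binomial_tail(5, 4, 0.5), "exceed")
  expect_error(binomial_tail(1, 4, 1), "inside")
})

test_that("cell classification follows the alpha/beta thresholds", {
  expect_equal(classify_cell(0.04, 0.50), "origination-hotspot")
  expect_equal(classify_cell(0.50, 0.04), "extinction-hotspot")
  expect_equal(classify_cell(0.01, 0.02), "turnover")
  expect_equal(classify_cell(0.96, 0.97), "stable")
  expect_equal(classify_cell(0.50, 0.50), "neutral")
  expect_equal(classify_cell(0.96, 0.50), "neutral")
  expect_equal(classify_cell(NA, 0.5), "unsupported")
  # vectorized
  expect_equal(classify_cell(c(0.04, 0.96), c(0.5, 0.96)),
               c("origination-hotspot", "stable"))
})

test_that("hotspot grids keep weighted counts consistent and label support", {
  w <- generate_world(world_config(seed = 5))
  ranges <- global_fad_lad(w$occurrences, w$scheme)
  grid <- make_grid(-10, 20, 40, 52, 3)
  res <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 500, "first")
  expect_true(all(res$k_weighted <= res$n_weighted + 1e-9))
  expect_true(all(res$tail_prob >= 0 & res$tail_prob <= 1, na.rm = TRUE))
  expect_true(all(res$klass[res$n_weighted < 1] == "unsupported"))
  expect_s3_class(attr(res, "model"), "event_model")
  # relabelling species and localities leaves the classification unchanged
  occ2 <- w$occurrences
  occ2$species <- paste0("relabel_", occ2$species)
  occ2$locality <- paste0("relabel_", occ2$locality)
  ranges2 <- global_fad_lad(occ2, w$scheme)
  res2 <- detect_hotspots(occ2, ranges2, w$scheme, grid, 500, "first")
  expect_equal(res2$klass, res$klass)
  expect_equal(res2$tail_prob, res$tail_prob, tolerance = 1e-12)
})

test_that("a record with no first occurrences after the opening bin flags nothing", {
  s <- toy_scheme(4)
  # every species appears in B1 and persists: no firsts in scope
  sp <- paste0("s", 1:6)
  occ <- toy_occ(
    species = rep(sp, times = 4),
    locality = rep(c("L1", "L2"), each = 3, times = 4),
    lon = rep(c(0, 2), each = 3, times = 4), lat = 48,
    bin = rep(s$name, each = 6),
    scheme = s
  )
  ranges <- global_fad_lad(occ, s)
  grid <- make_grid(0, 2, 47, 49, 1)
  res <- detect_hotspots(occ, ranges, s, grid, 500, "first")
  expect_false(any(res$klass == "hotspot"))
  expect_true(all(res$tail_prob[res$klass != "unsupported"] == 1))
})

test_that("joint event classification merges the two grids", {
  w <- generate_world(world_config(seed = 9))
  ranges <- global_fad_lad(w$occurrences, w$scheme)
  grid <- make_grid(-10, 20, 40, 52, 3)
  org <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 500, "first")
  ext <- detect_hotspots(w$occurrences, ranges, w$scheme, grid, 500, "last")
  joint <- classify_event_grids(org, ext)
  # origination bins are a subset of extinction bins; all must be matched
  expect_setequal(unique(joint$bin), unique(org$bin))
  expect_true(all(joint$klass %in% c("origination-hotspot",
                                     "extinction-hotspot", "turnover",
                                     "stable", "neutral", "unsupported")))
})
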