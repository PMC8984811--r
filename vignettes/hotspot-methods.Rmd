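---
title: "Detecting origination, extinction and sorting hotspots in fossil occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting origination, extinction and sorting hotspots in fossil occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilhotspots)
```

## The model

The record is a table of occurrences: one species at one locality in one
discrete time bin. Bins are ordered from oldest to youngest, with age
bounds in Ma; a species' first appearance datum (FAD) and last appearance
datum (LAD) are the bins of its globally earliest and latest occurrence,
determined on the *global* table before any regional filtering. Every
occurrence in the FAD bin is a first occurrence — a species recorded at
three localities in its FAD bin contributes three first occurrences. The
symmetric convention holds for last occurrences.

High raw counts of first occurrences mainly reflect sampling. The method
therefore asks, for each place and time, how many first occurrences would
be *expected* given local sampling intensity in the current and adjacent
bin, and flags places where the observed count exceeds that expectation.

**Spatial weighting.** Around a focal point with radius $R$, an
occurrence at great-circle distance $d$ carries weight
$w(d) = \max(0, 1 - d/R)$: 1 at the focal point, 0 at and beyond $R$.
Distances are haversine on a sphere of radius 6371.0088 km (the IUGG mean
radius); at the continental scale analysed, planar approximations would
distort, while geodesics on the ellipsoid would add complexity without
materially moving weights. An exponential kernel is exposed as an
experimental alternative but is not used by any default.

**The event model.** For each locality $L$ in each eligible bin, one
regression row is emitted per raw occurrence at $L$, with covariates
$x_\text{now}$ (weighted total occurrences around $L$ in the focal bin)
and $x_\text{before}$ (same, in the previous bin for origination, the
next bin for extinction), and target $y = 1$ iff the occurrence is a
first (resp. last) occurrence. A single pooled maximum-likelihood
logistic fit with intercept is used across all bins: the "local" aspect
of the model enters entirely through the locally weighted covariates, not
through per-locality fits, which one row set per locality could not
support. A per-bin stratified fit can be emulated by passing a restricted
occurrence table. Rows are unweighted in the likelihood; weighting lives
in the covariates and in the count statistics.

The analysis window excludes the terminal bins: the oldest bin has no
"before" (every species seen there is trivially first) and the youngest
serves only to anchor LADs. With an 18-bin MN/MQ scheme this yields
MN2–MQ18 for origination and MN1–MQ18 for extinction.

**The exceedance test.** At a grid node, with weighted total $n$,
weighted event count $k$ and model probability $p$ evaluated at the
node's own covariates, the tail probability is $P(X \ge k)$ for
$X \sim \text{Binomial}(n, p)$. Weighted counts are not integers; the
tail is continued as the regularized incomplete beta function
$I_p(k, n - k + 1)$, which agrees with the exact survival sum on integer
arguments (the test suite checks this to $10^{-12}$). $k = 0$ returns 1.
A rounding alternative was considered and rejected: it discards exactly
the fractional weighting the method is built on. Because the binomial
variance $p(1-p)\sum w_i$ exceeds the true variance of a weighted sum of
Bernoullis $p(1-p)\sum w_i^2$ whenever weights are below 1, the test is
conservative, which the null-calibration study confirms.

Cells with tail probability below $\alpha = 0.05$ are hotspots, above
$\beta = 0.95$ stable, in between neutral; cells with weighted support
below 1 are unsupported and reported with their minimum distance to any
locality, so users can mask artefacts where a node is "supported" only by
remote localities. No multiple-testing correction is applied, matching
standard practice for these exploratory maps; a Benjamini–Hochberg
adjustment can be applied downstream to the reported tail probabilities.

## Species sorting

Sorting — immigration and local extinction of species that persist
globally — is assessed on species lists. For a focal point and two
adjacent bins, the species with at least one positively weighted
occurrence in each bin are listed, and species globally first seen in the
later bin or last seen in the earlier bin are pruned from both lists:
what remains are species extant somewhere in the world in both bins, so a
presence change within the area is sorting rather than true origination
or extinction.

One candidate row is emitted per listed species (earlier-bin list for
local extinction, later-bin list for immigration), with the event
indicator marking absence from the other list. The logistic baseline
model uses the *area-total* weighted sampling intensities of the two bins
as covariates. This is a deliberate design choice: the species' own
weighted sums cannot serve as covariates because the event is a
deterministic function of them (a species is absent from a list exactly
when its weighted sum in that bin is zero), which makes the logistic
likelihood completely separated. Area totals express the relevant
baseline — apparent disappearance is likely when the later bin is poorly
sampled — and are fittable. The species' own sums are still reported per
row for diagnostics.

Since all candidates at a node then share one probability, the exceedance
test is an exact binomial there; the implementation nevertheless computes
the exact Poisson–binomial tail by dynamic programming over the count
distribution, so that heterogeneous probabilities (e.g. from a stratified
model) are handled without approximation. A mean-probability binomial
variant is available via `test = "binomial"`.

A node is assessed at focal bin $b$ using the transition into $b$ for
immigration and out of $b$ for local extinction, and requires weighted
support of at least 1 in the preceding, focal and subsequent bins.

## Ecometrics

Community dental traits track environment: crown height (hypsodonty,
encoded bra = 1, mes = 2, hyp = hys = 3) rises and loph counts (capped at
2) shift with aridity. Distance-weighted means of both traits are
computed at each node from occurrences of the five large plant-eating
orders (Perissodactyla, Artiodactyla, Primates, Proboscidea, Hyracoidea),
using occurrences — not species — as the unit, and only occurrences with
both traits recorded. Hypsodonty is ordinal but close enough to a ratio
scale for arithmetic means to be meaningful. Means require weighted
support of at least 2 (versus 1 for the event grids).

Net primary productivity is a *configured* linear transfer function of
the two means (intercept, HYP and LOP coefficients, optional
interaction), clipped below at zero. The package deliberately ships no
default coefficients: published calibrations should be supplied
explicitly with provenance, and all tests use synthetic configurations.

## Species longevity and range

Longevity is the span from the FAD bin's older bound to the LAD bin's
younger bound. The convention matters for single-bin species: under the
span convention they carry the full bin duration, which keeps group means
positive and is the default; a midpoint-to-midpoint alternative (zero for
single-bin species) is available.

Per-bin geographic range uses three tiers: one distinct location — zero;
two locations — great-circle distance × 10 km (a nominal 10 km wide
corridor); three or more — the planar convex hull area after Lambert
azimuthal equal-area projection about the points' centroid, where
spherical excess is negligible at these extents. Collinear point sets
fall back to the two-point rule on the farthest pair. A species' occupied
area is the mean of its per-bin areas over the bins where it is actually
recorded (unobserved bins contribute nothing, not zero).

A species is an origination-hotspot member if any of its first
occurrences falls in a grid cell classified as an origination hotspot in
its FAD bin (occurrences are snapped to the nearest lattice node within
half the spacing); extinction membership is symmetric with last
occurrences. Group comparisons are restricted to species whose FAD and
LAD both lie inside the analysis window, optionally excluding single-bin
species.

## The synthetic generator

`generate_world()` produces records with the statistical structure the
detectors assume, plus ground truth. Localities are persistent points
with persistent Gamma-distributed sampling intensities (counts are
Poisson around them, hence negative-binomially dispersed across
localities); persistence reflects that productive fossil sites remain
productive, and without it locality faunas churn so strongly that
apparent local extinction swamps any signal. Each locality's occurrences
in a bin split into first occurrences (founding new species, or re-using
a species founded in the same bin), last occurrences (drawn from the
established recorded pool and killed on draw — a constant per-bin hazard,
so lifetimes are geometric/memoryless), and mid occurrences (fauna
retained from the previous bin with probability 0.9 per species, topped
up by immigrants from the previous bin's recorded pool). The
first-occurrence fraction is controlled exactly (default 5% after the
opening bin, in which every occurrence is trivially first); the realized
last-occurrence fraction is the configured draw rate plus
sampling-driven disappearance, exactly as in real records.

Injected hotspots elevate the first or last fraction inside a circle,
extirpate a fraction of a circle's species at a transition while placing
them as refugees at distant localities (regional loss with global
survival — sorting, not extinction), or replace retained fauna with
immigrants. Species carry dental traits drawn at their origin from a
linear latent-NPP gradient; an optional longevity multiplier lowers both
the kill hazard and the churn-exit hazard of hotspot-born species.

What the generator does not emulate: spatially autocorrelated
environments beyond a linear gradient, species geographic-range cohesion
(occurrences of a species scatter freely over localities), diachronous
bin boundaries, and taxonomic error. Passing detection tests on these
worlds therefore demonstrates the statistical machinery under the model's
own assumptions, not robustness to every failure mode of real data.

## Validation studies and problem sizes

The test suite runs, besides fixture-level oracles, four replicate
studies on 2°-spaced grids over a 30° × 12° region with 40 localities and
6 bins of 1.5 Myr (about 2000 occurrences per world):

* **Origination power**: a 300 km circle in one bin where 50% of
  occurrences are first occurrences against a 5% background; the circle
  must be flagged in at least 90 of 100 seeded replicates.
* **Local-extinction power**: a circle losing 60% of its species across
  one transition (survivors elsewhere) against roughly 10% background
  locality-level loss; same criterion, via the sorting detector.
* **Null calibration**: in worlds with no injected structure, the
  fraction of supported cells with tail probability below 0.05 must stay
  below 0.10 for the origination detector and for the sorting detector.
  The origination test is strongly conservative (observed rates near
  0.01) for the variance reason given above; the sorting directions sit
  closer to nominal because candidate species sharing localities are not
  independent, with immigration the least conservative of the two.
* **Qualitative recovery** (50 replicates, 10-bin worlds with 80
  localities): with an origination hotspot placed on the arid side of a
  longitudinal productivity gradient and hotspot-born species given a
  3-fold lower exit hazard, the pipeline must recover both the longevity
  ordering (hotspot members outlive background species) and the NPP
  contrast (hotspot cells more arid), each through the full
  detection → membership → comparison chain.

These sizes keep the full suite within minutes on a single core while
leaving each study's verdict far from its threshold under the default
seeds.

## Numerical and degenerate-input conventions

* Longitude bounds of the study region are inclusive; the latitude bound
  is strict ("above 35°").
* Taxonomically indeterminate names (containing "sp.", "indet.", "cf.")
  are dropped by default, configurably.
* Duplicate (species, locality, bin) rows collapse to one occurrence;
  rows with unresolvable bins or invalid coordinates are dropped with a
  logged count; an empty table after cleaning is a hard error.
* A logistic fit with single-class targets or non-finite coefficients is
  a hard error naming the condition; a record with zero events in scope
  short-circuits to tail probability 1 everywhere (nothing can exceed a
  zero-rate expectation).
* `binomial_tail` requires `p` strictly inside (0, 1) and `k ≤ n`;
  predicted sorting probabilities are clamped away from 0/1 by 1e-12
  before the Poisson–binomial DP.
* The bundled MN/MQ bin table follows commonly used published
  correlations (MN1 at 23.0 Ma through MQ19 at 0.01 Ma, MN7 and MN8
  merged); it is a convenience default, and real analyses should supply
  their own calibration.

## Limitations

Weighted counts at nearby grid nodes share the same occurrences, so
neighbouring cells are strongly dependent and the hotspot maps should be
read as fields, not as independent tests. The method does not separate
sampling from genuine diversity change — it models their joint effect
through local sampling covariates — and inherits the assumption that
carrying capacity varies smoothly in space and time. Range areas ignore
sampling bias in occupancy, and NPP estimates are only as good as the
supplied transfer coefficients.
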