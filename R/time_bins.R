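#' Construct a time-bin scheme
#'
#' A time-bin scheme is an ordered set of named, contiguous, non-overlapping
#' time bins with age bounds in Ma (million years before present). Bins are
#' ordered from oldest to youngest; the `ordinal` column increases with
#' decreasing age, so "previous" means the bin with ordinal - 1 (older) and
#' "next" the bin with ordinal + 1 (younger).
#'
#' @param name character vector of unique bin names (e.g. `"MN3"`), oldest
#'   first.
#' @param older_bound,younger_bound numeric vectors of age bounds in Ma, with
#'   `older_bound > younger_bound > 0` for every bin.
#' @return A `data.frame` of class `bin_scheme` with columns `name`,
#'   `older_bound`, `younger_bound`, `ordinal`.
#' @examples
#' bin_scheme(c("B1", "B2", "B3"), c(6, 4, 2), c(4, 2, 1))
#' @export
bin_scheme <- function(name, older_bound, younger_bound) {
  name <- as.character(name)
  older_bound <- as.numeric(older_bound)
  younger_bound <- as.numeric(younger_bound)
  n <- length(name)
  stopifnot(length(older_bound) == n, length(younger_bound) == n, n >= 1)
  if (anyDuplicated(name)) stop("bin names must be unique")
  if (any(!is.finite(older_bound)) || any(!is.finite(younger_bound))) {
    stop("bin bounds must be finite")
  }
  if (any(older_bound <= younger_bound)) {
    stop("each bin needs older_bound > younger_bound")
  }
  if (any(younger_bound <= 0)) stop("bin bounds must be positive ages (Ma)")
  ord <- order(-older_bound)
  name <- name[ord]; older_bound <- older_bound[ord]
  younger_bound <- younger_bound[ord]
  if (n > 1) {
    # contiguity: each bin must start where the previous (older) one ended
    gap <- abs(older_bound[-1] - younger_bound[-n])
    if (any(younger_bound[-n] < older_bound[-1] - 1e-9)) {
      stop("bins overlap in time")
    }
    if (any(gap > 1e-6)) {
      warning("bin scheme has gaps between consecutive bins")
    }
  }
  out <- data.frame(
    name = name,
    older_bound = older_bound,
    younger_bound = younger_bound,
    ordinal = seq_len(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' Read a bin scheme from CSV
#'
#' The file must have columns `name`, `older_bound`, `younger_bound` (Ma).
#'
#' @param path path to a CSV file.
#' @return A [bin_scheme()] data frame.
#' @export
read_bin_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "older_bound", "younger_bound")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bin scheme CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bin_scheme(df$name, df$older_bound, df$younger_bound)
}

#' Write a bin scheme to CSV
#'
#' @param scheme a [bin_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_scheme <- function(scheme, path) {
  utils::write.csv(
    scheme[, c("name", "older_bound", "younger_bound")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Default European Neogene/Quaternary land-mammal bin scheme
#'
#' MN1-MN17 plus the informal Quaternary extensions MQ18-MQ19, with MN7 and
#' MN8 merged as "MN7-8", spanning 23-0.01 Ma. Bounds follow commonly used
#' published MN correlations; they are a convenient default, not an
#' authoritative calibration, and analyses of real data should supply their
#' own scheme via [read_bin_scheme()].
#'
#' @return A [bin_scheme()] with 18 bins.
#' @export
default_mn_scheme <- function() {
  path <- system.file("extdata", "mn_bins.csv", package = "fossilhotspots")
  read_bin_scheme(path)
}

#' Bin ordinals and names
#'
#' `bin_ordinal()` maps bin names to their ordinal position (older bins have
#' smaller ordinals); `bin_at()` is the inverse. Unknown names or ordinals
#' give `NA`.
#'
#' @param scheme a [bin_scheme()].
#' @param name character vector of bin names.
#' @param ordinal integer vector of ordinals.
#' @return integer ordinals, or bin names.
#' @export
bin_ordinal <- function(scheme, name) {
  scheme$ordinal[match(name, scheme$name)]
}

#' @rdname bin_ordinal
#' @export
bin_at <- function(scheme, ordinal) {
  scheme$name[match(ordinal, scheme$ordinal)]
}

#' Bin durations in Myr
#'
#' @param scheme a [bin_scheme()].
#' @param name optional bin names; default all bins in scheme order.
#' @return numeric vector of durations (older_bound - younger_bound).
#' @export
bin_duration <- function(scheme, name = scheme$name) {
  i <- match(name, scheme$name)
  scheme$older_bound[i] - scheme$younger_bound[i]
}
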