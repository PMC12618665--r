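#' Gestational-age bin schemes
#'
#' The model whose advice is being studied outputs gestational age (GA) as a
#' two-week interval rather than a point value: the 13--42 week range is split
#' into 13 ordered bins, the interior ones exactly two weeks wide and the two
#' outer ones wider, reflecting the scarcity of very early and very late
#' scans in the training data. A bin scheme is represented as a data frame
#' with columns `lo` and `hi` (weeks). Membership is half-open `[lo, hi)`
#' except the last bin, which is closed at its upper edge, so every GA in
#' range belongs to exactly one bin.
#'
#' @param lo,hi Numeric vectors of bin edges in weeks.
#' @return A `bin_scheme` tibble with columns `lo`, `hi`.
#' @export
#' @examples
#' default_bin_scheme()
bin_scheme <- function(lo, hi) {
  if (length(lo) != length(hi)) stopf("lo and hi must have the same length")
  scheme <- tibble::tibble(lo = as.numeric(lo), hi = as.numeric(hi))
  class(scheme) <- c("bin_scheme", class(scheme))
  validate_bin_scheme(scheme)
  scheme
}

#' @rdname bin_scheme
#' @param scheme A `bin_scheme`.
#' @export
validate_bin_scheme <- function(scheme) {
  if (!all(c("lo", "hi") %in% names(scheme))) stopf("bin scheme needs lo and hi columns")
  lo <- scheme$lo
  hi <- scheme$hi
  if (nrow(scheme) != 13L) stopf("bin scheme must have exactly 13 bins, got %d", nrow(scheme))
  if (any(lo >= hi)) stopf("every bin must satisfy lo < hi")
  if (any(hi - lo < 2)) stopf("every bin must be at least 2 weeks wide")
  if (lo[1] < 13 - 1e-9 || utils::tail(hi, 1) > 42 + 1e-9) {
    stopf("bins must lie within 13-42 weeks")
  }
  if (any(abs(utils::head(hi, -1) - lo[-1]) > 1e-9)) stopf("bins must be contiguous")
  interior <- seq(2L, nrow(scheme) - 1L)
  if (any(abs((hi - lo)[interior] - 2) > 1e-9)) stopf("interior bins must be exactly 2 weeks wide")
  if ((hi - lo)[1] <= 2 || utils::tail(hi - lo, 1) <= 2) {
    stopf("first and last bins must be wider than 2 weeks")
  }
  invisible(scheme)
}

#' Canonical 13-bin gestational-age scheme
#'
#' One consistent realisation of the 13-bin discretisation of 13--42 weeks:
#' a 3-week first bin \code{[13,16)}, eleven 2-week interior bins
#' \code{[16,18) ... [36,38)}, and a 4-week last bin \code{[38,42]}. With 13
#' contiguous bins over 29 weeks and 11 interior 2-week bins, the outer
#' widths 3 and 4 are forced up to which edge gets the extra week; this
#' scheme gives the wider bin to the late-GA end, where scans are sparsest.
#' Any other scheme satisfying [validate_bin_scheme()] can be used instead.
#'
#' @return A `bin_scheme` tibble with 13 rows.
#' @export
default_bin_scheme <- function() {
  lo <- c(13, seq(16, 36, by = 2), 38)
  hi <- c(lo[-1], 42)
  bin_scheme(lo, hi)
}

#' Map GA values to bins of a scheme
#'
#' Uses the half-open convention `[lo, hi)` with the last bin closed, so any
#' value in `[min(lo), max(hi)]` maps to exactly one bin.
#'
#' @param ga_weeks Numeric GA values in weeks.
#' @param scheme A `bin_scheme` (default [default_bin_scheme()]).
#' @return Integer bin indices (NA for out-of-range values).
#' @export
assign_bin <- function(ga_weeks, scheme = default_bin_scheme()) {
  idx <- findInterval(ga_weeks, c(scheme$lo, utils::tail(scheme$hi, 1)),
                      rightmost.closed = TRUE)
  idx[idx < 1L | idx > nrow(scheme)] <- NA_integer_
  idx
}

#' Bin midpoints of a scheme
#'
#' The scalar GA shown alongside an interval prediction defaults to the bin
#' midpoint throughout the package.
#'
#' @inheritParams assign_bin
#' @return Numeric vector of midpoints in weeks, one per bin.
#' @export
bin_midpoints <- function(scheme = default_bin_scheme()) {
  (scheme$lo + scheme$hi) / 2
}

# Is `x` inside bin [lo, hi), last bin (hi == scheme_max) closed?
in_bin <- function(x, lo, hi, scheme_max = 42) {
  x >= lo & (x < hi | (abs(hi - scheme_max) < 1e-9 & x <= hi))
}
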