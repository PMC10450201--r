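# Fragment-size sequencing-bias correction.
#
# Short-read sequencers recover short library fragments more efficiently
# than long ones, which distorts per-position 5' read counts: a TSS far
# from the fixed 3' end of an insert transcript yields a long fragment and
# is under-counted. A cubic spline interpolates a discrete size->relative
# efficiency table, and counts are divided by the interpolated efficiency.

#' Fit a fragment-size bias curve
#'
#' Interpolates a discrete table of (fragment size, relative sequencing
#' efficiency) with a natural cubic spline. The curve passes through every
#' knot; evaluation outside the knot range is clamped to the boundary knot
#' values (cubic splines extrapolate wildly), and interpolated efficiencies
#' are floored at `floor` to keep the downstream division stable. Note that
#' a monotone knot table need not produce a monotone interpolant between
#' knots.
#'
#' @param sizes Integer fragment sizes in bp; at least 4 distinct values.
#' @param efficiencies Positive relative efficiencies, one per size.
#' @param floor Lower clamp on interpolated efficiencies (default 1e-3).
#' @return An object of class `bias_curve`; call it like a function or use
#'   [bias_efficiency()].
#' @export
fit_bias_curve <- function(sizes, efficiencies, floor = 1e-3) {
  sizes <- as.numeric(sizes)
  efficiencies <- as.numeric(efficiencies)
  stopifnot(length(sizes) == length(efficiencies))
  if (anyDuplicated(sizes)) stop("fit_bias_curve: duplicate sizes")
  if (length(sizes) < 4L) {
    stop("fit_bias_curve: need at least 4 knots for a cubic spline")
  }
  if (anyNA(efficiencies) || any(efficiencies <= 0)) {
    stop("fit_bias_curve: efficiencies must be positive")
  }
  ord <- order(sizes)
  sizes <- sizes[ord]
  efficiencies <- efficiencies[ord]
  spline <- stats::splinefun(sizes, efficiencies, method = "natural")
  structure(
    list(knots = data.frame(size = sizes, efficiency = efficiencies),
         spline = spline,
         valid_range = range(sizes),
         floor = floor),
    class = "bias_curve"
  )
}

#' Evaluate a bias curve
#'
#' @param curve A [fit_bias_curve()] object.
#' @param size Fragment size(s) in bp; values outside the knot range are
#'   clamped to it.
#' @return Relative efficiency value(s), floored at `curve$floor`.
#' @export
bias_efficiency <- function(curve, size) {
  stopifnot(inherits(curve, "bias_curve"))
  size <- pmin(pmax(as.numeric(size), curve$valid_range[1]),
               curve$valid_range[2])
  pmax(curve$spline(size), curve$floor)
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf("<bias_curve> %d knots over sizes [%g, %g] bp, floor %g\n",
              nrow(x$knots), x$valid_range[1], x$valid_range[2], x$floor))
  invisible(x)
}

#' Fragment sizes implied by TSS positions within an insert
#'
#' For reporter transcripts read out at a fixed 3' end, a TSS at 0-based
#' position `i` of an insert of length `insert_length` produces a fragment
#' of `insert_length - i + adapter_length` bp. The adapter constant covers
#' the fixed vector/adapter sequence appended to every fragment.
#'
#' @param insert_length Insert length in bp.
#' @param adapter_length Constant 3' adapter/vector contribution in bp
#'   (default 121).
#' @return Integer vector of fragment sizes for positions `0..insert_length-1`.
#' @export
position_fragment_sizes <- function(insert_length, adapter_length = 121) {
  insert_length <- as.integer(insert_length)
  stopifnot(insert_length > 0L)
  insert_length - seq_len(insert_length) + 1L + as.integer(adapter_length)
}

#' Correct a TSS profile for fragment-size sequencing bias
#'
#' Divides each position's count by the interpolated relative sequencing
#' efficiency of the fragment size produced by a TSS at that position. The
#' result is a rescaled count profile flagged `size_normalized` (it is no
#' longer an integer count vector); `total_raw` is unchanged.
#'
#' @param profile A raw-state [tss_profile()].
#' @param sizes Integer vector of fragment sizes, one per profile position
#'   (see [position_fragment_sizes()]).
#' @param curve A [fit_bias_curve()] object.
#' @return The profile with values divided by per-position efficiency and
#'   state `"size_normalized"`.
#' @export
normalize_profile_by_size <- function(profile, sizes, curve) {
  stopifnot(is_tss_profile(profile), inherits(curve, "bias_curve"))
  if (profile$state != "raw") {
    stop("normalize_profile_by_size: profile must be in raw state")
  }
  if (length(sizes) != length(profile$values)) {
    stop(sprintf("normalize_profile_by_size: %d sizes for %d positions",
                 length(sizes), length(profile$values)))
  }
  eff <- bias_efficiency(curve, sizes)
  profile$values <- profile$values / eff
  profile$state <- "size_normalized"
  profile
}

#' Apply a synthetic size bias to a profile (for simulation)
#'
#' Multiplies each position's value by the curve's efficiency at that
#' position's fragment size — the generative counterpart of
#' [normalize_profile_by_size()], used to build round-trip tests and
#' synthetic fixtures.
#'
#' @inheritParams normalize_profile_by_size
#' @return The profile with biased values (state unchanged, `"raw"`).
#' @export
apply_size_bias <- function(profile, sizes, curve) {
  stopifnot(is_tss_profile(profile), inherits(curve, "bias_curve"))
  if (length(sizes) != length(profile$values)) {
    stop("apply_size_bias: size vector length mismatch")
  }
  profile$values <- profile$values * bias_efficiency(curve, sizes)
  profile
}
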