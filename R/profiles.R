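#' Genomic/insert region
#'
#' A lightweight 0-based, half-open interval (BED convention) on a named
#' reference sequence (a chromosome or an MPRA insert id) with an explicit
#' strand.
#'
#' @param ref_name Reference sequence name (chromosome or insert id).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must be greater than `start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `region`.
#' @examples
#' region("chr1", 1000, 1300, "+")
#' @export
region <- function(ref_name, start, end, strand = "+") {
  stopifnot(is.character(ref_name), length(ref_name) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || end <= start) {
    stop("region: 'end' must be greater than 'start' (0-based half-open)")
  }
  if (!strand %in% c("+", "-")) {
    stop("region: strand must be '+' or '-'")
  }
  structure(
    list(ref_name = ref_name, start = start, end = end, strand = strand),
    class = "region"
  )
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s:%d-%d(%s)\n", x$ref_name, x$start, x$end, x$strand))
  invisible(x)
}

region_length <- function(region) region$end - region$start

#' Single-nucleotide TSS profile
#'
#' A TSS profile is a vector of per-base transcription-initiation signal over
#' a region, stored 5'-to-3' on the transcribed strand. `values[i]` is the
#' signal at the i-th base of the region (in transcription direction). The
#' normalization `state` tracks whether values are raw read counts (`"raw"`),
#' counts per million (`"cpm"`), per-profile fractions summing to one
#' (`"unit"`), or size-bias rescaled counts (`"size_normalized"`).
#' `total_raw`, the raw read total before any normalization, is preserved
#' through normalization and is the quantity tested by the minimum-read
#' filter.
#'
#' @param values Numeric vector of non-negative per-base values, one per base
#'   of `region`.
#' @param region A [region()]; defaults to an unnamed insert spanning the
#'   vector.
#' @param state Normalization state; one of `"raw"`, `"cpm"`, `"unit"`,
#'   `"size_normalized"`.
#' @param total_raw Raw read total; defaults to `sum(values)` when
#'   `state == "raw"`, otherwise required.
#' @return An object of class `tss_profile`.
#' @examples
#' p <- tss_profile(c(0, 3, 10, 3, 0))
#' sum(p$values)
#' @export
tss_profile <- function(values, region = NULL, state = "raw",
                        total_raw = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("tss_profile: empty value vector")
  if (anyNA(values) || any(values < 0)) {
    stop("tss_profile: values must be non-negative and finite")
  }
  if (is.null(region)) {
    region <- region("insert", 0L, length(values), "+")
  }
  if (region_length(region) != length(values)) {
    stop(sprintf(
      "tss_profile: region length %d != value length %d",
      region_length(region), length(values)
    ))
  }
  state <- match.arg(state, c("raw", "cpm", "unit", "size_normalized"))
  if (is.null(total_raw)) {
    if (state != "raw") {
      stop("tss_profile: total_raw is required for non-raw states")
    }
    total_raw <- sum(values)
  }
  if (total_raw < 0) stop("tss_profile: total_raw must be non-negative")
  if (state == "unit" && total_raw > 0 && abs(sum(values) - 1) > 1e-9) {
    stop("tss_profile: unit-state values must sum to 1")
  }
  structure(
    list(region = region, values = values, state = state,
         total_raw = as.numeric(total_raw)),
    class = "tss_profile"
  )
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf(
    "<tss_profile> %s:%d-%d(%s)  length=%d  state=%s  total_raw=%g\n",
    x$region$ref_name, x$region$start, x$region$end, x$region$strand,
    length(x$values), x$state, x$total_raw
  ))
  invisible(x)
}

#' @export
length.tss_profile <- function(x) length(x$values)

is_tss_profile <- function(x) inherits(x, "tss_profile")

#' Convert a raw profile to counts per million
#'
#' Scales every value by `1e6 / library_total`, where `library_total` is the
#' total number of mapped reads in the experiment (not the profile sum), so
#' profiles from experiments of different sequencing depth are comparable.
#'
#' @param profile A raw-state [tss_profile()].
#' @param library_total Total mapped reads in the experiment; must be > 0.
#' @return The profile with state `"cpm"`; `total_raw` is unchanged.
#' @export
to_cpm <- function(profile, library_total) {
  stopifnot(is_tss_profile(profile))
  if (profile$state != "raw") {
    stop(sprintf("to_cpm: profile state is '%s', expected 'raw'", profile$state))
  }
  if (!is.numeric(library_total) || length(library_total) != 1L ||
      is.na(library_total) || library_total <= 0) {
    stop("to_cpm: library_total must be a positive number")
  }
  profile$values <- profile$values * (1e6 / library_total)
  profile$state <- "cpm"
  profile
}

#' Normalize a profile to unit mass
#'
#' Divides the profile by its own sum so that values sum to one, making
#' comparisons independent of overall signal intensity. All-zero profiles are
#' rejected (the supported path is to filter them out first with
#' [passes_min_reads()]).
#'
#' @param profile A [tss_profile()] with positive total signal.
#' @return The profile with state `"unit"` and `sum(values) == 1`.
#' @export
to_unit <- function(profile) {
  stopifnot(is_tss_profile(profile))
  s <- sum(profile$values)
  if (s <= 0) {
    stop("to_unit: degenerate all-zero profile cannot be unit-normalized")
  }
  profile$values <- profile$values / s
  profile$state <- "unit"
  profile
}

#' Minimum-read filter
#'
#' Profiles with fewer than `min_reads` raw reads are considered too shallow
#' for shape comparison. The boundary is inclusive: a profile with exactly
#' `min_reads` reads passes.
#'
#' @param profile A [tss_profile()].
#' @param min_reads Minimum raw read total (default 25).
#' @return `TRUE` if `total_raw >= min_reads`.
#' @export
passes_min_reads <- function(profile, min_reads = 25) {
  stopifnot(is_tss_profile(profile))
  profile$total_raw >= min_reads
}

#' Focus ratio of a TSS profile
#'
#' The fraction of a region's initiation signal that falls within
#' `halfwidth` bp (inclusive on both sides, clipped at the array edges) of a
#' focal TSS position. 1 indicates a fully focused (single-nucleotide)
#' profile, values near 0 an extremely dispersed one. The ratio is invariant
#' under CPM or unit normalization.
#'
#' @param profile A [tss_profile()] with positive total signal.
#' @param focal_position 0-based offset of the focal TSS within the profile.
#' @param halfwidth Window half-width in bp (default 10, i.e. "within 10 bp").
#' @return A list of class `focus_result` with `focal_position`,
#'   `focus_ratio`, `reads_in_window`, `reads_total`.
#' @export
focus_ratio <- function(profile, focal_position, halfwidth = 10) {
  stopifnot(is_tss_profile(profile))
  focal_position <- as.integer(focal_position)
  n <- length(profile$values)
  if (is.na(focal_position) || focal_position < 0L || focal_position >= n) {
    stop(sprintf("focus_ratio: focal_position %d out of bounds [0, %d)",
                 focal_position, n))
  }
  total <- sum(profile$values)
  if (total <= 0) stop("focus_ratio: degenerate all-zero profile")
  lo <- max(0L, focal_position - halfwidth)
  hi <- min(n - 1L, focal_position + halfwidth)
  in_window <- sum(profile$values[(lo + 1L):(hi + 1L)])
  structure(
    list(focal_position = focal_position,
         focus_ratio = in_window / total,
         reads_in_window = in_window,
         reads_total = total),
    class = "focus_result"
  )
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> position=%d ratio=%.4f (%g / %g reads)\n",
              x$focal_position, x$focus_ratio, x$reads_in_window,
              x$reads_total))
  invisible(x)
}

#' Extract a strand-oriented window around a center position
#'
#' Slices the `upstream + downstream` bases around `center` (a 0-based offset
#' in the stored, transcription-oriented vector): positions
#' `center - upstream` to `center + downstream - 1`. The default -150/+150
#' window yields the 300 bp surrounding an annotated TSS. Profiles are stored
#' 5'-to-3' on the transcribed strand, so no further re-orientation is
#' needed here; minus-strand orientation is applied when profiles are built
#' from reference-coordinate data (see [count_tss()]). The window must lie
#' fully inside the profile: no silent padding. Windowing happens before
#' unit normalization (a unit-state slice would no longer sum to one), so
#' unit-state input is rejected.
#'
#' @param profile A [tss_profile()].
#' @param center 0-based offset of the anchor position (typically the
#'   annotated TSS).
#' @param upstream Bases kept upstream of `center` (default 150).
#' @param downstream Bases kept at and downstream of `center` (default 150).
#' @return A [tss_profile()] of length `upstream + downstream`; `total_raw`
#'   is recomputed over the window when the input is raw, otherwise scaled by
#'   the fraction of signal retained.
#' @export
extract_window <- function(profile, center, upstream = 150, downstream = 150) {
  stopifnot(is_tss_profile(profile))
  if (profile$state == "unit") {
    stop("extract_window: window before unit normalization, not after")
  }
  center <- as.integer(center)
  n <- length(profile$values)
  lo <- center - upstream        # 0-based inclusive
  hi <- center + downstream      # 0-based exclusive
  if (lo < 0L || hi > n) {
    stop(sprintf(
      "extract_window: window [%d, %d) exceeds profile bounds [0, %d)",
      lo, hi, n
    ))
  }
  vals <- profile$values[(lo + 1L):hi]
  reg <- profile$region
  if (reg$strand == "+") {
    new_reg <- region(reg$ref_name, reg$start + lo, reg$start + hi, "+")
  } else {
    # stored orientation is 5'->3' on the minus strand; offset lo from the
    # 5' end corresponds to reference coordinates counted from region end
    new_reg <- region(reg$ref_name, reg$end - hi, reg$end - lo, "-")
  }
  old_sum <- sum(profile$values)
  total_raw <- if (profile$state == "raw") {
    sum(vals)
  } else if (old_sum > 0) {
    profile$total_raw * sum(vals) / old_sum
  } else {
    0
  }
  tss_profile(vals, region = new_reg, state = profile$state,
              total_raw = total_raw)
}
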