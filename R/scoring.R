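# Shape dissimilarity metrics for TSS profiles.
#
# The windowed initiation profile (WIP) score compares two unit-normalized
# profiles at multiple scales: for every window length k = 1..K a length-k
# window slides across both arrays, the absolute difference of the window
# sums is accumulated into a running k-diff score, and each k-diff is
# weighted by k before summing. Multi-scale weighting makes the score
# sensitive to both single-base shifts and broader redistribution of
# initiation signal, which single-scale metrics such as EMD flatten out.

# promote a profile to unit state: raw -> cpm -> unit; cpm -> unit.
# library_total only matters for the cpm step and cancels in unit
# normalization, so a nominal 1e6 is used when none is supplied.
prepare_unit <- function(profile, arg = "profile") {
  stopifnot(is_tss_profile(profile))
  if (sum(profile$values) <= 0) {
    stop(sprintf("%s: degenerate all-zero profile cannot be scored", arg))
  }
  if (profile$state == "raw" || profile$state == "size_normalized") {
    profile$state <- "raw"
    profile <- to_cpm(profile, 1e6)
  }
  if (profile$state != "unit") profile <- to_unit(profile)
  profile
}

check_pair <- function(a, b, max_window = NULL) {
  if (length(a$values) != length(b$values)) {
    stop(sprintf("profiles have different lengths (%d vs %d)",
                 length(a$values), length(b$values)))
  }
  if (!is.null(max_window)) {
    if (max_window < 1L) stop("max_window must be >= 1")
    if (length(a$values) < max_window) {
      stop(sprintf("profile length %d is shorter than max_window %d",
                   length(a$values), max_window))
    }
  }
  invisible(NULL)
}

new_shape_score <- function(metric, value, max_window = NA_integer_,
                            per_window = NULL) {
  structure(
    list(metric = metric, value = value,
         max_window = max_window, per_window = per_window),
    class = "shape_score"
  )
}

#' @export
print.shape_score <- function(x, ...) {
  cat(sprintf("<shape_score> metric=%s value=%.6g", x$metric, x$value))
  if (!is.na(x$max_window)) cat(sprintf(" (K=%d)", x$max_window))
  cat("\n")
  invisible(x)
}

#' Windowed initiation profile (WIP) dissimilarity score
#'
#' Quantifies how different two TSS profiles are. Both profiles are promoted
#' to unit state internally (raw counts go through CPM first), so the score
#' depends only on profile shape, never on sequencing depth. For each window
#' length `k` in `1..max_window`, a window slides at stride 1 over all fully
#' contained positions; at each position the absolute difference of the two
#' window sums is added to that k's running k-diff score. The WIP value is
#' `sum(k * kdiff[k])`. It is symmetric, non-negative, and zero exactly when
#' the unit-normalized profiles are equal.
#'
#' @param a,b [tss_profile()] objects of equal length, neither all-zero.
#' @param max_window Largest window length K (default 5).
#' @return A `shape_score` with `metric = "wip"`, the score `value`, and the
#'   unweighted `per_window` k-diff vector.
#' @examples
#' a <- tss_profile(c(0, 0, 10, 0, 0, 0, 0, 0))
#' b <- tss_profile(c(0, 0, 0, 10, 0, 0, 0, 0))
#' wip_score(a, b)$value  # adjacent single-base TSS shift
#' @export
wip_score <- function(a, b, max_window = 5) {
  max_window <- as.integer(max_window)
  check_pair(a, b, max_window)
  a <- prepare_unit(a, "a")
  b <- prepare_unit(b, "b")
  d <- a$values - b$values
  L <- length(d)
  # window sums of d via cumulative sums; kdiff_k = sum |rolling_sum_k(d)|
  cs <- c(0, cumsum(d))
  per_window <- numeric(max_window)
  for (k in seq_len(max_window)) {
    win <- cs[(k + 1L):(L + 1L)] - cs[1L:(L - k + 1L)]
    per_window[k] <- sum(abs(win))
  }
  value <- sum(seq_len(max_window) * per_window)
  new_shape_score("wip", value, max_window, per_window)
}

#' Literal nested-loop reference implementation of the WIP score
#'
#' Implements exactly the same contract as [wip_score()] with explicit loops
#' over every window position and every base inside each window — no
#' vectorization, no cumulative sums. Kept as an independent reference for
#' testing; use [wip_score()] for real work.
#'
#' @inheritParams wip_score
#' @return A `shape_score` with `metric = "wip"`.
#' @export
wip_score_oracle <- function(a, b, max_window = 5) {
  max_window <- as.integer(max_window)
  check_pair(a, b, max_window)
  a <- prepare_unit(a, "a")
  b <- prepare_unit(b, "b")
  va <- a$values
  vb <- b$values
  L <- length(va)
  per_window <- numeric(max_window)
  diffsum <- 0
  for (k in seq_len(max_window)) {
    kdiff <- 0
    for (start in 1L:(L - k + 1L)) {
      sa <- 0
      sb <- 0
      for (offset in 0L:(k - 1L)) {
        sa <- sa + va[start + offset]
        sb <- sb + vb[start + offset]
      }
      kdiff <- kdiff + abs(sa - sb)
    }
    per_window[k] <- kdiff
    diffsum <- diffsum + k * kdiff
  }
  new_shape_score("wip", diffsum, max_window, per_window)
}

#' 1D earth mover's distance between two TSS profiles
#'
#' Wasserstein-1 distance on the integer position grid, computed in closed
#' form as the sum of absolute differences of the two cumulative sums after
#' unit normalization. For two single-base profiles at positions i and j the
#' value is |i - j|. Included as the standard baseline metric that the WIP
#' score is benchmarked against.
#'
#' @inheritParams wip_score
#' @return A `shape_score` with `metric = "emd"`.
#' @export
emd_1d <- function(a, b) {
  check_pair(a, b)
  a <- prepare_unit(a, "a")
  b <- prepare_unit(b, "b")
  new_shape_score("emd", sum(abs(cumsum(a$values - b$values))))
}

#' All-vs-all score matrix
#'
#' Computes the symmetric dissimilarity matrix over a list of profiles, for
#' ranking-based benchmarks such as [rank_recovery()].
#'
#' @param profiles List of equal-length, non-degenerate [tss_profile()]s,
#'   optionally named.
#' @param metric `"wip"` or `"emd"`.
#' @param max_window WIP window parameter K (ignored for EMD).
#' @return A symmetric numeric matrix with zero diagonal; dimnames taken
#'   from `names(profiles)` when present.
#' @export
score_matrix <- function(profiles, metric = c("wip", "emd"), max_window = 5) {
  metric <- match.arg(metric)
  n <- length(profiles)
  if (n == 0L) stop("score_matrix: empty profile list")
  units <- vector("list", n)
  for (i in seq_len(n)) {
    units[[i]] <- tryCatch(
      prepare_unit(profiles[[i]]),
      error = function(e) {
        stop(sprintf("score_matrix: profile %d (%s): %s", i,
                     if (is.null(names(profiles))) "unnamed"
                     else names(profiles)[i],
                     conditionMessage(e)))
      }
    )
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- if (metric == "wip") {
        wip_score(units[[i]], units[[j]], max_window)$value
      } else {
        emd_1d(units[[i]], units[[j]])$value
      }
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  dimnames(m) <- list(names(profiles), names(profiles))
  m
}
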