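# Synthetic TSS-MPRA data generator.
#
# Emulates the empirical structure of 5'-end MPRA data: focused promoters
# with a single dominant TSS, dispersed promoters whose initiation spreads
# over tens of bases, 4-fold barcode replication of every sequence,
# Poisson counting noise on positions, and a lognormal per-barcode
# abundance factor capturing the multiplicative dispersion observed
# between barcode replicates.

#' Simulation specification
#'
#' @param n_groups Number of distinct insert sequences (groups).
#' @param replicates_per_group Barcode replicates per sequence (default 4).
#' @param profile_length Profile length in bp (default 300).
#' @param p_focused Fraction of groups with a focused (single-TSS) true
#'   shape; the rest are dispersed mixtures (default 0.5).
#' @param dispersed_spread SD in bp of the dispersed shape's Gaussian
#'   component (default 20).
#' @param depth Mean reads per insert (default 1000).
#' @param sigma SD of the lognormal per-barcode scale factor on the log
#'   scale (default 0.2).
#' @param shape_noise SD of the per-replicate, per-position lognormal
#'   perturbation of the true shape before Poisson sampling (default 0.25).
#'   This models barcode-specific overdispersion beyond counting noise —
#'   the variability that motivates redundant barcoding in the first
#'   place; set to 0 for pure Poisson replicates.
#' @param activity_sd SD (log scale) of the per-group lognormal activity
#'   factor multiplying `depth` (default 1). Real promoters span orders of
#'   magnitude in expression; this spread is what makes abundance an
#'   informative feature for the outlier model. Set to 0 for uniform
#'   depth.
#' @param seed Integer seed; a fixed seed reproduces the data set exactly.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_groups = 100, replicates_per_group = 4,
                     profile_length = 300, p_focused = 0.5,
                     dispersed_spread = 20, depth = 1000, sigma = 0.2,
                     shape_noise = 0.25, activity_sd = 1, seed = 1L) {
  stopifnot(n_groups >= 1, replicates_per_group >= 1, profile_length >= 50,
            p_focused >= 0, p_focused <= 1, dispersed_spread > 0,
            depth > 0, sigma >= 0, shape_noise >= 0, activity_sd >= 0)
  structure(
    list(n_groups = as.integer(n_groups),
         replicates_per_group = as.integer(replicates_per_group),
         profile_length = as.integer(profile_length),
         p_focused = p_focused,
         dispersed_spread = dispersed_spread,
         depth = depth,
         sigma = sigma,
         shape_noise = shape_noise,
         activity_sd = activity_sd,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# a true unit-mass shape: focused = single base; dispersed = a random
# mixture of 2-4 Gaussian modes around the focal position. Broad promoters
# are typically multimodal with group-specific fine structure, so each
# dispersed group gets its own mode count, offsets, widths and weights
# rather than a shared template.
true_shape <- function(length, focal, focused, spread) {
  if (focused) {
    # sharp promoters carry a dominant main TSS plus promoter-specific
    # minor satellite initiation within a few bp; everything stays inside
    # the +/-10 bp focus window, so the focus ratio at the main TSS is 1
    v <- numeric(length)
    main_w <- stats::runif(1, 0.6, 0.9)
    v[focal + 1L] <- main_w
    n_sat <- sample(2:4, 1)
    sat_off <- sample(setdiff(-8:8, 0), n_sat)
    sat_w <- stats::rexp(n_sat) + 0.1
    sat_w <- (1 - main_w) * sat_w / sum(sat_w)
    v[focal + 1L + sat_off] <- sat_w
    return(v)
  }
  pos <- 0:(length - 1L)
  n_modes <- sample(2:4, 1)
  offsets <- stats::runif(n_modes, -2 * spread, 2 * spread)
  sds <- stats::runif(n_modes, spread / 6, spread * 0.75)
  weights <- stats::rexp(n_modes) + 0.2
  weights <- weights / sum(weights)
  v <- numeric(length)
  for (m in seq_len(n_modes)) {
    v <- v + weights[m] * stats::dnorm(pos, focal + offsets[m], sds[m])
  }
  v / sum(v)
}

#' Simulate true shapes and barcode-replicate TSS profiles
#'
#' Draws one true unit profile per group (focused or dispersed), then for
#' each barcode replicate perturbs the shape with per-position lognormal
#' noise (`shape_noise`), draws a lognormal scale factor
#' `exp(N(0, sigma^2))` and Poisson counts with mean
#' `depth * scale * replicate_shape`.
#'
#' @param spec A [sim_spec()].
#' @return A list with `true_profiles` (per group, unit state),
#'   `replicate_profiles` (per insert, raw counts), `groups` (named map
#'   insert id -> group id), `focused` (named logical per group) and
#'   `activity` (named per-group depth factor).
#' @export
simulate_profiles <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  L <- spec$profile_length
  margin <- 25L # keep focal TSSs away from the edges
  group_ids <- sprintf("group%03d", seq_len(spec$n_groups))
  focused <- stats::runif(spec$n_groups) < spec$p_focused
  # inserts are designed around their most active TSS, so the main TSS
  # sits at a common offset (mid-profile) with only small jitter; shapes
  # differ in fine structure, not in gross position
  focal <- pmin(pmax(round(stats::rnorm(spec$n_groups, L / 2, 3)),
                     margin), L - margin - 1L)
  activity <- exp(stats::rnorm(spec$n_groups, 0, spec$activity_sd))
  true_profiles <- vector("list", spec$n_groups)
  replicate_profiles <- list()
  groups <- character(0)
  for (g in seq_len(spec$n_groups)) {
    shape <- true_shape(L, focal[g], focused[g], spec$dispersed_spread)
    true_profiles[[g]] <- tss_profile(shape, state = "unit", total_raw = 1)
    for (r in seq_len(spec$replicates_per_group)) {
      id <- sprintf("%s_bc%d", group_ids[g], r)
      scale <- exp(stats::rnorm(1, 0, spec$sigma))
      rep_shape <- if (spec$shape_noise > 0) {
        perturbed <- shape * exp(stats::rnorm(L, 0, spec$shape_noise))
        perturbed / sum(perturbed)
      } else {
        shape
      }
      counts <- stats::rpois(L, spec$depth * activity[g] * scale * rep_shape)
      replicate_profiles[[id]] <- tss_profile(
        counts, region = region(id, 0L, L, "+"), state = "raw"
      )
      groups[id] <- group_ids[g]
    }
  }
  names(true_profiles) <- group_ids
  names(focused) <- group_ids
  names(activity) <- group_ids
  list(true_profiles = true_profiles,
       replicate_profiles = replicate_profiles,
       groups = groups,
       focused = focused,
       activity = activity)
}

#' Simulate paired RNA/DNA barcode count tables
#'
#' DNA (plasmid copy) counts are lognormal-dispersed Poisson draws around
#' `dna_depth`; RNA counts couple each insert's activity to its DNA
#' abundance times a per-group activity level, so RNA/DNA ratios estimate
#' activity.
#'
#' @param spec A [sim_spec()].
#' @param groups Named map insert id -> group id from [simulate_profiles()].
#' @param dna_depth Mean DNA reads per insert (default 500).
#' @param activity Optional named vector of per-group relative activities;
#'   defaults to lognormal draws.
#' @return An `abundance_table` with raw columns, plus an
#'   `activity` attribute with the true per-group values.
#' @export
simulate_abundance <- function(spec, groups, dna_depth = 500,
                               activity = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  ids <- names(groups)
  gids <- unique(groups)
  if (is.null(activity)) {
    activity <- stats::setNames(exp(stats::rnorm(length(gids), 0, 1)), gids)
  }
  dna <- stats::rpois(length(ids), dna_depth * exp(stats::rnorm(length(ids), 0, spec$sigma)))
  rna <- stats::rpois(length(ids), dna * activity[groups[ids]] *
                        exp(stats::rnorm(length(ids), 0, spec$sigma)))
  out <- data.frame(insert_id = ids, rna_raw = rna, dna_raw = dna,
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  attr(out, "activity") <- activity
  out
}

# deterministic 11-mer barcodes: index coded in base 4
make_barcodes <- function(n) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(11)
    for (j in 11:1) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}

#' Build an insert library matching simulated profiles
#'
#' @param groups Named map insert id -> group id from [simulate_profiles()].
#' @param profile_length Insert length in bp.
#' @return An [insert_library()] with deterministic unique 11-mer barcodes.
#' @export
simulate_library <- function(groups, profile_length = 300) {
  ids <- names(groups)
  insert_library(
    insert_id = ids,
    group_id = unname(groups[ids]),
    barcode = make_barcodes(length(ids)),
    sequence_length = profile_length
  )
}

#' Emit SAM alignments and barcode reads that reproduce given profiles
#'
#' Writes a SAM file with one single-end read-1 record per counted 5' end,
#' positioned so that re-quantifying with [count_tss()] returns exactly the
#' input counts (plus-strand targets place read starts at the counted base;
#' minus-strand targets place read ends there, with the reverse flag set).
#' Barcode reads are returned as a character vector with one entry per
#' RNA/DNA count.
#'
#' @param profiles Named list of integer-valued raw [tss_profile()]s.
#' @param library An [insert_library()] covering the profile names.
#' @param path Output SAM path.
#' @param read_length Read length in bp (default 26, shortened at insert
#'   edges so alignments stay inside the reference).
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(profiles, library, path, read_length = 26) {
  stopifnot(inherits(library, "insert_library"))
  missing <- setdiff(names(profiles), library$insert_id)
  if (length(missing)) {
    stop(sprintf("simulate_reads: profiles not in library: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  lens <- stats::setNames(library$sequence_length, library$insert_id)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", library$insert_id,
            library$sequence_length)
  )
  chunks <- vector("list", length(profiles))
  for (pi in seq_along(profiles)) {
    p <- profiles[[pi]]
    counts <- p$values
    if (any(counts != round(counts))) {
      stop(sprintf("simulate_reads: non-integer counts in profile %s",
                   names(profiles)[pi]))
    }
    ref <- p$region$ref_name
    L <- lens[[ref]]
    nz <- which(counts > 0)
    if (!length(nz)) next
    offsets <- nz - 1L
    k <- counts[nz]
    if (p$region$strand == "+") {
      pos1 <- p$region$start + offsets + 1L # 1-based 5' end
      len <- pmin(read_length, L - pos1 + 1L)
      flag <- 0L
      start1 <- pos1
    } else {
      # stored offset counts from the 3' end of the reference region
      end1 <- p$region$end - offsets # 1-based 5' end (= alignment end)
      len <- pmin(read_length, end1)
      flag <- 16L
      start1 <- end1 - len + 1L
    }
    chunks[[pi]] <- rep(sprintf(
      "\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
      flag, ref, start1, len, strrep("A", len)
    ), k)
  }
  records <- unlist(chunks, use.names = FALSE)
  if (is.null(records)) records <- character(0)
  if (length(records)) {
    records <- paste0(sprintf("read%07d", seq_along(records)), records)
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Expand an abundance table into per-read barcode sequences
#'
#' @param table An `abundance_table` with raw counts.
#' @param library An [insert_library()].
#' @param source `"rna"` or `"dna"`.
#' @return Character vector with each insert's barcode repeated by its raw
#'   count, suitable for [count_barcodes()].
#' @export
simulate_barcode_reads <- function(table, library, source = c("rna", "dna")) {
  source <- match.arg(source)
  col <- paste0(source, "_raw")
  stopifnot(col %in% names(table))
  bc <- stats::setNames(library$barcode, library$insert_id)
  rep(bc[table$insert_id], table[[col]])
}
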