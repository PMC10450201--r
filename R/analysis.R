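# Replicate-variance statistics, ranking benchmarks, nucleotide-frequency
# matrices and per-TSS contribution classification.

#' Barcode-replicate variance and outlier detection
#'
#' Measures the dispersion of transcription levels among barcode replicates
#' of the same insert sequence. Each insert's log2 DNA-normalized RNA level
#' is zero-centered by subtracting its group median, the standard deviation
#' of the pooled centered values is computed, and inserts at least
#' `sd_threshold` standard deviations from their group center are flagged as
#' outliers. Log ratios use a 0.5 pseudocount on both CPM columns so zero
#' counts stay finite; the outlier set is invariant under any global
#' multiplicative scaling of the ratios.
#'
#' @param table A normalized `abundance_table` (see [normalize_abundance()])
#'   with `rna_cpm` and `dna_cpm` columns.
#' @param groups Named character vector mapping `insert_id` to `group_id`,
#'   or `NULL` to use a `group_id` column in `table`.
#' @param sd_threshold Outlier cutoff in pooled standard deviations
#'   (default 3).
#' @return A list of class `group_variance_result` with `centered` (named
#'   vector of centered log2 ratios), `sd_global`, `sd_fold`
#'   (`2^sd_global`, dispersion expressed as fold change around the
#'   median), and `outlier_ids`.
#' @export
barcode_variance <- function(table, groups = NULL, sd_threshold = 3) {
  stopifnot(all(c("insert_id", "rna_cpm", "dna_cpm") %in% names(table)))
  if (is.null(groups)) {
    if (!"group_id" %in% names(table)) {
      stop("barcode_variance: supply 'groups' or a group_id column")
    }
    groups <- stats::setNames(table$group_id, table$insert_id)
  }
  missing <- setdiff(table$insert_id, names(groups))
  if (length(missing)) {
    stop(sprintf("barcode_variance: no group for inserts: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  usable <- is.finite(table$rna_cpm) & is.finite(table$dna_cpm)
  if (!all(usable)) {
    warning(sprintf("barcode_variance: dropping %d inserts with undefined ratios",
                    sum(!usable)))
    table <- table[usable, , drop = FALSE]
  }
  log_ratio <- log2((table$rna_cpm + 0.5) / (table$dna_cpm + 0.5))
  names(log_ratio) <- table$insert_id
  gid <- groups[table$insert_id]
  med <- tapply(log_ratio, gid, stats::median)
  centered <- log_ratio - as.vector(med[gid])
  sd_global <- stats::sd(centered)
  outliers <- if (sd_global > 0) {
    names(centered)[abs(centered) >= sd_threshold * sd_global]
  } else {
    character(0)
  }
  structure(
    list(centered = centered, sd_global = sd_global,
         sd_fold = 2^sd_global, sd_threshold = sd_threshold,
         outlier_ids = outliers),
    class = "group_variance_result"
  )
}

#' @export
print.group_variance_result <- function(x, ...) {
  cat(sprintf(
    "<group_variance_result> %d inserts, pooled SD = %.4f (%.2f-fold), %d outliers (>= %g SD)\n",
    length(x$centered), x$sd_global, x$sd_fold, length(x$outlier_ids),
    x$sd_threshold
  ))
  invisible(x)
}

#' Barcode-replicate rank recovery from a score matrix
#'
#' Benchmarks a dissimilarity metric by how well it reunites barcode
#' replicates: for each insert, all inserts are ranked by ascending score
#' against it (self included — the self score of 0 ranks first; remaining
#' ties broken by insert id) and the group members found in the `top_n` most
#' similar are counted. With groups of size `top_n`, a perfect metric
#' recovers all `top_n` members (self plus `top_n - 1` replicates).
#'
#' @param matrix Square symmetric score matrix with insert ids as dimnames.
#' @param groups Named character vector mapping insert id to group id.
#' @param top_n List length examined per insert (default 4, matching 4-fold
#'   barcode replication).
#' @return A list of class `rank_recovery_result` with `per_insert_hits`
#'   (named integer vector) and `recovery_rate` (mean hits / `top_n`).
#' @export
rank_recovery <- function(matrix, groups, top_n = 4) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  ids <- rownames(matrix)
  if (is.null(ids)) stop("rank_recovery: matrix must have insert-id dimnames")
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop(sprintf("rank_recovery: no group for inserts: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  gsize <- table(groups[ids])
  if (any(gsize != top_n)) {
    warning(sprintf("rank_recovery: %d group(s) do not have size top_n = %d",
                    sum(gsize != top_n), top_n))
  }
  hits <- vapply(seq_along(ids), function(i) {
    ord <- order(matrix[i, ], ids) # ascending score, ties by id
    top <- ids[ord][seq_len(min(top_n, length(ids)))]
    sum(groups[top] == groups[ids[i]])
  }, numeric(1))
  names(hits) <- ids
  structure(
    list(per_insert_hits = hits, top_n = top_n,
         recovery_rate = mean(hits) / top_n),
    class = "rank_recovery_result"
  )
}

#' @export
print.rank_recovery_result <- function(x, ...) {
  cat(sprintf("<rank_recovery_result> top-%d recovery rate %.4f over %d inserts\n",
              x$top_n, x$recovery_rate, length(x$per_insert_hits)))
  invisible(x)
}

#' Three-population replicate consistency summary
#'
#' Splits shape scores into the three populations used to judge
#' reproducibility of initiation patterns: (A) scores between identical
#' inserts in two replicate experiments (true positives), (B) per-insert
#' average scores between barcode replicates within an experiment, and (C)
#' per-insert average scores against all non-replicates within the
#' experiment (true negatives).
#'
#' @param within Square symmetric within-experiment score matrix with insert
#'   ids as dimnames.
#' @param cross Cross-experiment score matrix (same ids on both dimensions);
#'   its diagonal is population A.
#' @param groups Named character vector mapping insert id to group id.
#' @return A list of class `replicate_consistency_result` with numeric
#'   vectors `A`, `B`, `C` and a `summary` data.frame (median and IQR per
#'   population).
#' @export
replicate_consistency_groups <- function(within, cross, groups) {
  ids <- rownames(within)
  if (is.null(ids)) stop("replicate_consistency_groups: matrices need dimnames")
  if (!identical(ids, rownames(cross)) || !identical(ids, colnames(cross))) {
    stop("replicate_consistency_groups: insert ids differ between matrices")
  }
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop(sprintf("replicate_consistency_groups: no group for: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  gid <- groups[ids]
  A <- diag(cross)
  same <- outer(gid, gid, "==")
  diag(same) <- NA # exclude self-comparisons from both B and C
  B <- vapply(seq_along(ids), function(i) {
    mean(within[i, which(same[i, ])])
  }, numeric(1))
  C <- vapply(seq_along(ids), function(i) {
    mean(within[i, which(!same[i, ])])
  }, numeric(1))
  names(A) <- names(B) <- names(C) <- ids
  pops <- list(A = A, B = B, C = C)
  summary <- data.frame(
    population = names(pops),
    n = vapply(pops, function(v) sum(is.finite(v)), numeric(1)),
    median = vapply(pops, function(v) stats::median(v, na.rm = TRUE), numeric(1)),
    iqr = vapply(pops, function(v) stats::IQR(v, na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  structure(c(pops, list(summary = summary)),
            class = "replicate_consistency_result")
}

#' Position-specific nucleotide frequency matrix around TSS anchors
#'
#' Builds the 4 x (2*flank + 1) frequency matrix of A/C/G/T around a set of
#' TSS anchor positions, the representation used to reveal core promoter
#' elements (Initiator at 0, TATA near -30). `N` bases are excluded from the
#' column denominators; anchors whose flanks run off their sequence are
#' skipped with a warning.
#'
#' @param sequences Character vector of uppercase ACGTN sequences.
#' @param anchors List of integer vectors (0-based TSS offsets per
#'   sequence), or a single integer vector with one anchor per sequence.
#' @param flank Flank size in bp on each side of the anchor (default 30).
#' @return Numeric matrix with rows `A`, `C`, `G`, `T` and columns named by
#'   offset `-flank..flank`; each column with coverage sums to 1.
#' @export
nucleotide_frequency <- function(sequences, anchors, flank = 30) {
  if (!is.list(anchors)) anchors <- as.list(anchors)
  stopifnot(length(anchors) == length(sequences))
  bases <- c("A", "C", "G", "T")
  width <- 2L * flank + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(bases, as.character(-flank:flank)))
  skipped <- 0L
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[[i]], "")[[1]]
    for (anchor in anchors[[i]]) {
      lo <- anchor - flank # 0-based
      hi <- anchor + flank
      if (lo < 0L || hi >= length(chars)) {
        skipped <- skipped + 1L
        next
      }
      window <- chars[(lo + 1L):(hi + 1L)]
      for (j in seq_len(width)) {
        b <- window[j]
        if (b %in% bases) counts[b, j] <- counts[b, j] + 1
      }
    }
  }
  if (skipped > 0L) {
    warning(sprintf("nucleotide_frequency: skipped %d anchor(s) too close to a sequence end",
                    skipped))
  }
  totals <- colSums(counts)
  freq <- sweep(counts, 2, ifelse(totals > 0, totals, 1), "/")
  freq
}

#' Classify per-position TSS contribution between two assays
#'
#' Compares the relative contribution of each position to its profile's
#' total signal between two unit-normalized profiles of the same region
#' (e.g. MPRA vs endogenous). A position is labeled `x_higher` when its
#' contribution in `profile_x` is at least `fold` times its contribution in
#' `profile_y` (boundary inclusive; any positive value beats an exact zero),
#' `y_higher` symmetrically, otherwise `comparable`.
#'
#' @param profile_x,profile_y Equal-length [tss_profile()]s; promoted to
#'   unit state internally.
#' @param fold Fold-change threshold (default 3).
#' @return Character vector of labels, one per position.
#' @export
classify_tss_contribution <- function(profile_x, profile_y, fold = 3) {
  check_pair(profile_x, profile_y)
  x <- prepare_unit(profile_x, "profile_x")$values
  y <- prepare_unit(profile_y, "profile_y")$values
  labels <- rep("comparable", length(x))
  # boundary inclusive; the (1 - 1e-9) guard keeps exact fold multiples
  # inclusive under floating-point rounding
  labels[x > 0 & x >= fold * y * (1 - 1e-9)] <- "x_higher"
  labels[y > 0 & y >= fold * x * (1 - 1e-9)] <- "y_higher"
  labels
}
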