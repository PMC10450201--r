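# Turning alignments into TSS profiles and barcode abundance tables.

#' Insert library record table
#'
#' Validates an MPRA insert library: one row per insert with a unique 11-mer
#' barcode, a `group_id` shared by barcode replicates of the same sequence,
#' and the offsets of the core region within longer inserts.
#'
#' @param insert_id Character vector of unique insert ids.
#' @param group_id Sequence-identity group (barcode replicates share one).
#' @param barcode Character vector of barcodes over ACGT (11-mers by
#'   convention); must be unique within the library.
#' @param sequence_length Integer insert lengths.
#' @param core_start,core_end 0-based half-open offsets of the core region
#'   within each insert; default the whole insert.
#' @return A `data.frame` of class `insert_library`.
#' @export
insert_library <- function(insert_id, group_id, barcode, sequence_length,
                           core_start = 0L, core_end = sequence_length) {
  n <- length(insert_id)
  if (n == 0L) stop("insert_library: empty library")
  stopifnot(length(group_id) == n, length(barcode) == n)
  sequence_length <- rep_len(as.integer(sequence_length), n)
  if (anyDuplicated(insert_id)) stop("insert_library: duplicate insert ids")
  if (anyDuplicated(barcode)) stop("insert_library: duplicate barcodes")
  if (any(grepl("[^ACGT]", barcode))) {
    stop("insert_library: barcodes must be over {A,C,G,T}")
  }
  core_start <- rep_len(as.integer(core_start), n)
  core_end <- rep_len(as.integer(core_end), n)
  bad <- core_start < 0L | core_start >= core_end | core_end > sequence_length
  if (any(bad)) {
    stop(sprintf("insert_library: invalid core offsets for %s",
                 paste(insert_id[bad], collapse = ", ")))
  }
  out <- data.frame(
    insert_id = as.character(insert_id),
    group_id = as.character(group_id),
    barcode = as.character(barcode),
    sequence_length = sequence_length,
    core_start = core_start,
    core_end = core_end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("insert_library", "data.frame")
  out
}

# open SAM transparently: Rsamtools reads BAM, so convert on the fly
as_bam_path <- function(path) {
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
    paste0(dest, ".bam")
  } else {
    path
  }
}

#' Count read-1 5' ends into TSS profiles
#'
#' Builds one single-nucleotide TSS profile per target region from aligned
#' 5'-end sequencing reads (SAM or BAM). The counted position is the 5' end
#' of read 1: the alignment start for plus-strand alignments and the
#' alignment end for minus-strand alignments. Only reads on the target's
#' strand are counted. Unmapped, secondary and supplementary alignments are
#' dropped; for paired data only first-in-pair reads are used; duplicates
#' are kept (5' libraries pile up legitimately). Profiles are returned in
#' transcription orientation: minus-strand target profiles are reversed
#' relative to reference coordinates.
#'
#' @param path Path to a SAM or BAM file.
#' @param targets List of [region()] targets (named list names override
#'   `ref_name` for output names).
#' @return Named list of raw [tss_profile()]s, one per target.
#' @export
count_tss <- function(path, targets) {
  if (inherits(targets, "region")) targets <- list(targets)
  stopifnot(length(targets) > 0L)
  bam <- as_bam_path(path)
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  ga <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(flag = flags, what = "flag")
  )
  flag <- S4Vectors::mcols(ga)$flag
  paired <- bitwAnd(flag, 0x1) != 0L
  first <- bitwAnd(flag, 0x40) != 0L
  ga <- ga[!paired | first]
  ref <- as.character(GenomicAlignments::seqnames(ga))
  strand <- as.character(GenomicAlignments::strand(ga))
  # 5' end in 1-based reference coordinates
  five_prime <- ifelse(strand == "+",
                       GenomicAlignments::start(ga),
                       GenomicAlignments::end(ga))
  out <- vector("list", length(targets))
  nm <- names(targets)
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    stopifnot(inherits(tg, "region"))
    n <- region_length(tg)
    sel <- ref == tg$ref_name & strand == tg$strand &
      five_prime > tg$start & five_prime <= tg$end
    counts <- tabulate(five_prime[sel] - tg$start, nbins = n)
    if (tg$strand == "-") counts <- rev(counts)
    out[[i]] <- tss_profile(counts, region = tg, state = "raw")
  }
  names(out) <- if (!is.null(nm) && all(nzchar(nm))) {
    nm
  } else {
    vapply(targets, function(t) t$ref_name, character(1))
  }
  out
}

#' Count exact barcode matches into an abundance table
#'
#' Tallies reads onto library inserts by exact barcode identity (the library
#' uses distance-separated barcodes by design, so no error correction is
#' applied). Reads matching no barcode are counted in the `unassigned`
#' attribute, so `sum(counts) + unassigned == length(reads)`.
#'
#' @param reads Character vector of observed barcode sequences (e.g. the
#'   barcode portion of read 2).
#' @param library An [insert_library()].
#' @param source `"rna"` or `"dna"`; names the count column.
#' @return A `data.frame` with `insert_id` and `<source>_raw` columns and an
#'   `unassigned` attribute.
#' @export
count_barcodes <- function(reads, library, source = c("rna", "dna")) {
  source <- match.arg(source)
  stopifnot(inherits(library, "insert_library"))
  idx <- match(reads, library$barcode)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(library))
  out <- data.frame(
    insert_id = library$insert_id,
    stringsAsFactors = FALSE
  )
  out[[paste0(source, "_raw")]] <- counts
  attr(out, "unassigned") <- sum(is.na(idx))
  out
}

#' Build a joint RNA/DNA abundance table
#'
#' Merges per-source raw barcode counts into one table keyed by insert id.
#'
#' @param rna,dna `data.frame`s from [count_barcodes()] (or any frame with
#'   `insert_id` and `rna_raw` / `dna_raw`).
#' @return A `data.frame` of class `abundance_table` with raw columns.
#' @export
abundance_table <- function(rna, dna) {
  stopifnot("insert_id" %in% names(rna), "insert_id" %in% names(dna),
            "rna_raw" %in% names(rna), "dna_raw" %in% names(dna))
  out <- merge(rna[c("insert_id", "rna_raw")], dna[c("insert_id", "dna_raw")],
               by = "insert_id", all = FALSE, sort = TRUE)
  if (nrow(out) == 0L) stop("abundance_table: no shared insert ids")
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' CPM and RNA/DNA normalization of an abundance table
#'
#' Transforms raw RNA and DNA barcode counts to counts per million to remove
#' sequencing-depth differences, then expresses each insert's transcription
#' level as the ratio of its CPM RNA abundance to its CPM DNA (plasmid copy)
#' abundance. The ratio is undefined (`NA`) where DNA CPM is zero.
#'
#' @param table An `abundance_table` with `rna_raw` and `dna_raw`.
#' @param rna_total,dna_total Library totals used as CPM denominators;
#'   default to the column sums over the table.
#' @return The table with `rna_cpm`, `dna_cpm` and `ratio` columns added.
#' @export
normalize_abundance <- function(table, rna_total = NULL, dna_total = NULL) {
  stopifnot(all(c("rna_raw", "dna_raw") %in% names(table)))
  if (is.null(rna_total)) rna_total <- sum(table$rna_raw)
  if (is.null(dna_total)) dna_total <- sum(table$dna_raw)
  if (rna_total <= 0 || dna_total <= 0) {
    stop("normalize_abundance: zero library total")
  }
  table$rna_cpm <- table$rna_raw * (1e6 / rna_total)
  table$dna_cpm <- table$dna_raw * (1e6 / dna_total)
  table$ratio <- ifelse(table$dna_cpm > 0, table$rna_cpm / table$dna_cpm, NA_real_)
  table
}

#' Quantile normalization of count columns
#'
#' Classic quantile normalization: each column's sorted values are replaced
#' by the across-column mean of sorted values, restored to the original
#' order; tied values receive the mean of their tied reference quantiles.
#' Delegates to `limma::normalizeQuantiles`.
#'
#' @param columns Numeric matrix or data.frame of two or more equal-length
#'   columns.
#' @return A numeric matrix of the same shape whose columns share identical
#'   sorted values.
#' @export
quantile_normalize <- function(columns) {
  m <- as.matrix(columns)
  if (ncol(m) < 2L) stop("quantile_normalize: need at least two columns")
  if (!is.numeric(m)) stop("quantile_normalize: non-numeric input")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}
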