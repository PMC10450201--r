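# Readers and writers: insert libraries (FASTA + TSV), profile TSVs,
# bedgraph tracks, bias tables and serialized outlier models.

# fixed float formatting so emitted files are byte-stable across runs
fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         formatC(x, format = "g", digits = 6))
}

#' Read an insert library from FASTA plus metadata TSV
#'
#' The FASTA provides insert sequences; the TSV provides one row per insert
#' with columns `insert_id`, `group_id`, `barcode` and optionally
#' `core_start`/`core_end` (0-based half-open offsets of the core region).
#' FASTA ids and metadata ids must match 1:1 and barcodes must be unique.
#'
#' @param fasta_path Path to the insert FASTA.
#' @param metadata_path Path to the tab-separated metadata file with header.
#' @return An [insert_library()] with a `sequences` attribute (named
#'   character vector).
#' @export
read_library <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("insert_id", "group_id", "barcode")
  if (!all(required %in% names(meta))) {
    stop(sprintf("read_library: metadata must have columns: %s",
                 paste(required, collapse = ", ")))
  }
  seq_ids <- sub("\\s.*$", "", names(seqs))
  if (!setequal(seq_ids, meta$insert_id) ||
      length(seq_ids) != nrow(meta)) {
    stop("read_library: FASTA ids and metadata insert_ids must match 1:1")
  }
  sequences <- stats::setNames(as.character(seqs), seq_ids)[meta$insert_id]
  lib <- insert_library(
    insert_id = meta$insert_id,
    group_id = meta$group_id,
    barcode = meta$barcode,
    sequence_length = nchar(sequences),
    core_start = if ("core_start" %in% names(meta)) meta$core_start else 0L,
    core_end = if ("core_end" %in% names(meta)) meta$core_end
               else nchar(sequences)
  )
  attr(lib, "sequences") <- sequences
  lib
}

#' Write TSS profiles as a single-nucleotide bedgraph track
#'
#' Emits one 0-based half-open single-base interval per nonzero position,
#' in reference coordinates. Minus-strand profiles (stored 5'-to-3' on the
#' transcribed strand) are mapped back to reference coordinates; by
#' convention one file is written per strand, so all profiles passed in one
#' call must share a strand.
#'
#' @param profiles List of [tss_profile()]s on a single strand.
#' @param path Output path.
#' @param track_header Emit a `track type=bedGraph` line first (default
#'   `FALSE`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profiles, path, track_header = FALSE) {
  if (is_tss_profile(profiles)) profiles <- list(profiles)
  strands <- vapply(profiles, function(p) p$region$strand, character(1))
  if (length(unique(strands)) > 1L) {
    stop("write_bedgraph: one file per strand; profiles mix strands")
  }
  lines <- character(0)
  if (track_header) lines <- "track type=bedGraph"
  for (p in profiles) {
    nz <- which(p$values != 0)
    if (!length(nz)) next
    offsets <- nz - 1L
    if (p$region$strand == "+") {
      starts <- p$region$start + offsets
    } else {
      starts <- p$region$end - 1L - offsets
    }
    ord <- order(starts)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", p$region$ref_name,
                              starts[ord], starts[ord] + 1L,
                              fmt_num(p$values[nz][ord])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-nucleotide bedgraph file
#'
#' @param path Path to a bedgraph written by [write_bedgraph()] (or any
#'   bedgraph restricted to single-base intervals).
#' @return A `data.frame` with `ref_name`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(ref_name = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  parts <- strsplit(lines, "\t")
  data.frame(
    ref_name = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    value = as.numeric(vapply(parts, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Serialize TSS profiles to a TSV file
#'
#' One row per profile: `ref_name`, `start`, `end`, `strand`, comma-joined
#' `values`, `state`, `total_raw`.
#'
#' @param profiles Named list of [tss_profile()]s (names become `name`
#'   column; defaults to ref_name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  if (is_tss_profile(profiles)) profiles <- list(profiles)
  nm <- names(profiles)
  if (is.null(nm)) {
    nm <- vapply(profiles, function(p) p$region$ref_name, character(1))
  }
  rows <- vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    paste(nm[i], p$region$ref_name, p$region$start, p$region$end,
          p$region$strand, paste(fmt_num(p$values), collapse = ","),
          p$state, fmt_num(p$total_raw), sep = "\t")
  }, character(1))
  writeLines(
    c("name\tref_name\tstart\tend\tstrand\tvalues\tstate\ttotal_raw", rows),
    path
  )
  invisible(path)
}

#' Read TSS profiles from a TSV written by [write_profiles_tsv()]
#'
#' @param path Input path.
#' @return Named list of [tss_profile()]s.
#' @export
read_profiles_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("profile TSV not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(values = "character"))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tss_profile(
      as.numeric(strsplit(tab$values[i], ",")[[1]]),
      region = region(tab$ref_name[i], tab$start[i], tab$end[i],
                      tab$strand[i]),
      state = tab$state[i],
      total_raw = tab$total_raw[i]
    )
  })
  names(out) <- tab$name
  out
}

#' Read a fragment-size bias table
#'
#' @param path TSV with columns `size` and `efficiency` (header required).
#' @return A [fit_bias_curve()] object.
#' @export
read_bias_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("size", "efficiency") %in% names(tab))) {
    stop("read_bias_table: need columns 'size' and 'efficiency'")
  }
  fit_bias_curve(tab$size, tab$efficiency)
}

#' Save a fitted shape-outlier model to a JSON file
#'
#' Serializes the feature scaler, SVM hyperparameters, support vectors and
#' coefficients, and the calibration anchors into one versioned JSON file
#' that [load_outlier_model()] restores exactly.
#'
#' @param model A [fit_outlier_model()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_outlier_model <- function(model, path) {
  stopifnot(inherits(model, "shape_outlier_model"))
  fit <- model$svm
  payload <- list(
    format = "tssshape-ocsvm",
    version = 1L,
    center = as.list(model$center),
    scale = as.list(model$scale),
    nu = model$nu,
    gamma = model$gamma,
    dv_hi = model$dv_hi,
    dv_lo = model$dv_lo,
    wip_grid = model$wip_grid,
    threshold = model$threshold,
    n_train = model$n_train,
    support_vectors = apply(fit$SV, 1, as.numeric, simplify = FALSE),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a shape-outlier model saved by [save_outlier_model()]
#'
#' Reconstructs a scoring-equivalent model from the serialized support
#' vectors and RBF coefficients (the decision function is recomputed
#' directly, without refitting).
#'
#' @param path Path to the JSON model file.
#' @return An object of class `shape_outlier_model` whose [outlier_score()]
#'   values match the original model.
#' @export
load_outlier_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "tssshape-ocsvm")) {
    stop("load_outlier_model: not a tssshape OCSVM model file")
  }
  sv <- payload$support_vectors
  sv <- if (is.list(sv)) do.call(rbind, lapply(sv, as.numeric)) else as.matrix(sv)
  model <- structure(
    list(
      svm = NULL,
      sv = sv,
      coefs = as.numeric(payload$coefs),
      rho = as.numeric(payload$rho),
      center = unlist(payload$center),
      scale = unlist(payload$scale),
      nu = payload$nu,
      gamma = payload$gamma,
      dv_hi = payload$dv_hi,
      dv_lo = payload$dv_lo,
      wip_grid = as.numeric(payload$wip_grid),
      threshold = payload$threshold,
      n_train = payload$n_train
    ),
    class = "shape_outlier_model"
  )
  model
}

# RBF one-class decision values computed from serialized support vectors
decision_from_sv <- function(model, z) {
  k <- vapply(seq_len(nrow(model$sv)), function(i) {
    exp(-model$gamma * rowSums(sweep(z, 2, model$sv[i, ])^2))
  }, numeric(nrow(z)))
  if (is.null(dim(k))) k <- matrix(k, nrow = nrow(z))
  as.numeric(k %*% model$coefs - model$rho)
}
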