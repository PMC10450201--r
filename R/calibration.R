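# Calibrating "significantly different shape" calls.
#
# WIP scores quantify how different two profiles are, but whether a
# difference is significant depends on how reproducible shapes are between
# replicates at a given expression level. A one-class SVM is trained on
# replicate-pair features (WIP score, mean quantile-normalized abundance):
# everything inside normal replicate variation is an inlier, and a new pair
# is scored 0 (fully within replicate variation) to 1 (fully outside).
# Pairs with outlier score > 0.5 (strictly) are called significantly
# different; the calibration pins the SVM decision frontier to 0.5 so the
# threshold coincides with the fitted boundary.

#' Replicate-pair training features
#'
#' One feature pair per promoter shared by two replicate experiments: the
#' WIP score between the two replicate profiles, and `log2(mean of the two
#' quantile-normalized abundances + 1)`. Promoters failing the minimum-read
#' filter in either replicate are dropped before scoring.
#'
#' @param profiles_a,profiles_b Named lists of [tss_profile()]s for the two
#'   replicates; names are promoter ids and must match across replicates.
#' @param abundance_a,abundance_b Numeric vectors of raw abundance counts
#'   named by promoter id (quantile-normalized across the two replicates
#'   internally).
#' @param min_reads Minimum raw read total per replicate (default 25).
#' @param max_window WIP window parameter K (default 5).
#' @param min_promoters Minimum number of surviving promoters (default 50).
#' @return A `data.frame` with `id`, `wip`, `mean_abundance` (log2 scale).
#' @export
build_training_features <- function(profiles_a, profiles_b,
                                    abundance_a, abundance_b,
                                    min_reads = 25, max_window = 5,
                                    min_promoters = 50) {
  ids <- names(profiles_a)
  if (is.null(ids) || is.null(names(profiles_b))) {
    stop("build_training_features: profile lists must be named by promoter id")
  }
  missing_b <- setdiff(ids, names(profiles_b))
  if (length(missing_b)) {
    stop(sprintf("build_training_features: ids missing from replicate B: %s",
                 paste(utils::head(missing_b, 5), collapse = ", ")))
  }
  if (!all(ids %in% names(abundance_a)) || !all(ids %in% names(abundance_b))) {
    stop("build_training_features: abundance vectors must cover all promoter ids")
  }
  qn <- quantile_normalize(cbind(a = abundance_a[ids], b = abundance_b[ids]))
  keep <- vapply(ids, function(id) {
    passes_min_reads(profiles_a[[id]], min_reads) &&
      passes_min_reads(profiles_b[[id]], min_reads)
  }, logical(1))
  ids <- ids[keep]
  if (length(ids) < min_promoters) {
    stop(sprintf(
      "build_training_features: only %d promoters pass the %d-read filter (need >= %d)",
      length(ids), min_reads, min_promoters
    ))
  }
  wip <- vapply(ids, function(id) {
    wip_score(profiles_a[[id]], profiles_b[[id]], max_window)$value
  }, numeric(1))
  mean_ab <- log2(rowMeans(qn[keep, , drop = FALSE]) + 1)
  data.frame(id = ids, wip = unname(wip), mean_abundance = unname(mean_ab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the one-class SVM shape-outlier model
#'
#' Trains an RBF one-class SVM on replicate features standardized to z-scores.
#' `nu` bounds the fraction of training (replicate) pairs treated as
#' outliers, and so doubles as the expected replicate false-positive rate.
#' Raw SVM decision values (positive = inlier) are mapped to a calibrated
#' outlier score in [0, 1] by a piecewise-linear monotone map anchored on the
#' training decision-value range, with the decision frontier (decision value
#' 0) pinned to 0.5 and clipping beyond the training extremes. Scoring is
#' made monotone in the WIP direction by a one-sided envelope: a pair is
#' only as outlying as the most inlier-like decision value found at any
#' equal-or-greater WIP (evaluated over a fixed grid of upper-half training
#' WIP quantiles), so a pair can never be flagged while more dissimilar
#' pairs at the same abundance are considered normal.
#'
#' @param features `data.frame` from [build_training_features()] (columns
#'   `wip`, `mean_abundance`).
#' @param nu One-class SVM nu parameter (default 0.05).
#' @param gamma RBF kernel width; default `1/2` (two standardized features),
#'   the usual 1/n_features scaling.
#' @param seed Integer seed fixed before fitting for a deterministic model.
#' @return An object of class `shape_outlier_model`.
#' @export
fit_outlier_model <- function(features, nu = 0.05, gamma = 0.5, seed = 1L) {
  stopifnot(all(c("wip", "mean_abundance") %in% names(features)))
  x <- as.matrix(features[, c("wip", "mean_abundance")])
  if (nrow(x) < 2L) stop("fit_outlier_model: need at least 2 training points")
  if (anyNA(x) || any(!is.finite(x))) {
    stop("fit_outlier_model: non-finite training features")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (all(scale == 0)) {
    stop("fit_outlier_model: zero variance in both feature dimensions")
  }
  scale[scale == 0] <- 1 # a flat dimension carries no information
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  set.seed(as.integer(seed))
  fit <- e1071::svm(z, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, z, decision.values = TRUE),
             "decision.values")[, 1]
  # calibration anchors: most-inlier and most-outlier training decisions
  dv_hi <- max(dv, 0)
  dv_lo <- min(dv, 0)
  structure(
    list(
      svm = fit,
      center = center,
      scale = scale,
      nu = nu,
      gamma = gamma,
      dv_hi = dv_hi,
      dv_lo = dv_lo,
      wip_grid = unname(unique(stats::quantile(
        x[, "wip"], probs = seq(0.5, 1, length.out = 65)
      ))),
      threshold = 0.5,
      n_train = nrow(z)
    ),
    class = "shape_outlier_model"
  )
}

#' @export
print.shape_outlier_model <- function(x, ...) {
  cat(sprintf(
    "<shape_outlier_model> one-class SVM (RBF, nu=%.3g, gamma=%.3g), %d training pairs\n",
    x$nu, x$gamma, x$n_train
  ))
  cat(sprintf("  decision-value anchors [%.4g, %.4g]; threshold %.2f\n",
              x$dv_lo, x$dv_hi, x$threshold))
  invisible(x)
}

# map raw decision values (positive = inlier) to [0,1] outlier scores:
# 0.5 at the frontier, linear to 0 at the most-inlier training point and to
# 1 at the most-outlier training point, clipped beyond.
calibrate_decision <- function(model, dv) {
  hi <- model$dv_hi
  lo <- model$dv_lo
  score <- ifelse(
    dv >= 0,
    if (hi > 0) 0.5 * (1 - dv / hi) else 0.5,
    if (lo < 0) 0.5 + 0.5 * (dv / lo) else 1
  )
  pmin(1, pmax(0, score))
}

#' Outlier score of a profile-pair feature
#'
#' Scores a (WIP, abundance) feature pair against the trained replicate
#' model: 0 means completely within normal replicate variation, 1 completely
#' outside.
#'
#' @param model A fitted [fit_outlier_model()].
#' @param wip WIP score(s) of the pair(s).
#' @param mean_abundance Mean quantile-normalized abundance on the log2
#'   scale, as produced by [build_training_features()].
#' @return Numeric outlier score(s) in [0, 1].
#' @export
outlier_score <- function(model, wip, mean_abundance) {
  stopifnot(inherits(model, "shape_outlier_model"))
  wip <- as.numeric(wip)
  mean_abundance <- as.numeric(mean_abundance)
  if (length(mean_abundance) == 1L) {
    mean_abundance <- rep(mean_abundance, length(wip))
  }
  stopifnot(length(wip) == length(mean_abundance))
  if (anyNA(wip) || anyNA(mean_abundance) ||
      any(!is.finite(c(wip, mean_abundance)))) {
    stop("outlier_score: non-finite features")
  }
  grid <- model$wip_grid
  gmax <- grid[length(grid)]
  # one-sided monotone envelope: evaluate the decision value at every grid
  # WIP >= the query (whole grid for queries below the median replicate
  # WIP; the query itself beyond the training maximum, where the RBF
  # decision value decreases monotonically anyway) and keep the maximum
  pts <- lapply(seq_along(wip), function(i) {
    w <- if (wip[i] >= gmax) wip[i] else grid[grid >= wip[i]]
    cbind(wip = w, mean_abundance = mean_abundance[i])
  })
  stacked <- do.call(rbind, pts)
  idx <- rep.int(seq_along(wip), vapply(pts, nrow, integer(1)))
  z <- sweep(sweep(stacked, 2, model$center), 2, model$scale, "/")
  dv_all <- if (is.null(model$svm)) {
    # model restored from serialization: evaluate the decision function
    # directly from the stored support vectors
    decision_from_sv(model, z)
  } else {
    attr(stats::predict(model$svm, z, decision.values = TRUE),
         "decision.values")[, 1]
  }
  dv <- as.vector(tapply(dv_all, idx, max))
  unname(calibrate_decision(model, dv))
}

#' Call whether two TSS profiles differ significantly in shape
#'
#' Computes the WIP score between two profiles, forms the model feature with
#' the supplied abundances, and calls the pair significantly different when
#' the calibrated outlier score strictly exceeds the threshold (0.5 by
#' default; a score of exactly 0.5 is not significant).
#'
#' @param model A fitted [fit_outlier_model()].
#' @param a,b [tss_profile()]s; both must pass the minimum-read filter.
#' @param abundance_a,abundance_b Quantile-normalized abundance counts for
#'   the two profiles (raw scale; the log2 transform is applied internally).
#' @param min_reads Minimum raw read total (default 25).
#' @param max_window WIP window parameter K (default 5).
#' @return A list with `wip`, `score` and `is_different`.
#' @export
call_significant <- function(model, a, b, abundance_a, abundance_b,
                             min_reads = 25, max_window = 5) {
  stopifnot(inherits(model, "shape_outlier_model"))
  if (!passes_min_reads(a, min_reads) || !passes_min_reads(b, min_reads)) {
    stop(sprintf("call_significant: profile below the %d-read filter", min_reads))
  }
  wip <- wip_score(a, b, max_window)$value
  feat_ab <- log2(mean(c(abundance_a, abundance_b)) + 1)
  score <- outlier_score(model, wip, feat_ab)
  list(wip = wip, score = score, is_different = score > model$threshold)
}

#' Between-replicate classification disagreement of the outlier model
#'
#' Measures model stability as the frequency with which the same promoter is
#' labeled differently in two replicate runs (e.g. inlier in replicate 1 but
#' outlier in replicate 2). Accuracy is `1 - disagreement`.
#'
#' @param calls_a,calls_b Logical vectors of `is_different` calls named by
#'   promoter id (or equal-length unnamed vectors in matching order).
#' @return A list with `disagreement` and `accuracy` in [0, 1].
#' @export
model_accuracy <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    missing <- setdiff(names(calls_a), names(calls_b))
    if (length(missing)) {
      stop(sprintf("model_accuracy: ids missing from second call set: %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    stop("model_accuracy: call vectors differ in length and are unnamed")
  }
  disagreement <- mean(calls_a != calls_b)
  list(disagreement = disagreement, accuracy = 1 - disagreement)
}
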