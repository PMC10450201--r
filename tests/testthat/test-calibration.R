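# replicate-pair-like features: WIP mass piles up near zero with a heavy
# right tail, abundance roughly log-normal
make_features <- function(n = 300, seed = 1) {
  set.seed(seed)
  data.frame(wip = rexp(n, rate = 1 / 3), mean_abundance = rnorm(n, 8, 1))
}

test_that("build_training_features pairs replicates and applies filters", {
  spec <- sim_spec(n_groups = 60, replicates_per_group = 2, depth = 400,
                   sigma = 0.1, seed = 30)
  rf <- replicate_features(spec)
  expect_equal(nrow(rf$features), 60) # depth 400 >> 25-read filter
  expect_true(all(rf$features$wip >= 0))
  expect_true(all(is.finite(rf$features$mean_abundance)))

  # identical replicates give all-zero WIP features
  ids <- names(rf$profiles_a)
  same <- build_training_features(rf$profiles_a, rf$profiles_a,
                                  rf$abundance_a, rf$abundance_a)
  expect_equal(same$wip, rep(0, length(ids)))

  # a promoter with 24 reads in one replicate is excluded
  shallow <- rf$profiles_a
  shallow[[ids[1]]] <- tss_profile(replace(numeric(300), 150, 24))
  feats <- build_training_features(shallow, rf$profiles_b,
                                   rf$abundance_a, rf$abundance_b)
  expect_equal(nrow(feats), 59)
  expect_false(ids[1] %in% feats$id)
})

test_that("build_training_features reports unmatched ids and small input", {
  spec <- sim_spec(n_groups = 55, replicates_per_group = 2, depth = 300,
                   seed = 31)
  rf <- replicate_features(spec)
  broken <- rf$profiles_b[-3]
  expect_error(
    build_training_features(rf$profiles_a, broken,
                            rf$abundance_a, rf$abundance_b),
    "missing from replicate B"
  )
  expect_error(
    build_training_features(rf$profiles_a[1:10], rf$profiles_b[1:10],
                            rf$abundance_a, rf$abundance_b),
    "pass the 25-read filter"
  )
})

test_that("fitted model flags about nu of its own training set", {
  feats <- make_features(400, seed = 2)
  model <- fit_outlier_model(feats, nu = 0.05, seed = 5)
  scores <- outlier_score(model, feats$wip, feats$mean_abundance)
  flagged <- mean(scores > 0.5)
  expect_lte(abs(flagged - 0.05), 0.05)
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("model fitting is deterministic and rejects degenerate features", {
  feats <- make_features(200, seed = 3)
  m1 <- fit_outlier_model(feats, seed = 9)
  m2 <- fit_outlier_model(feats, seed = 9)
  s1 <- outlier_score(m1, feats$wip, feats$mean_abundance)
  s2 <- outlier_score(m2, feats$wip, feats$mean_abundance)
  expect_identical(s1, s2)

  flat <- data.frame(wip = rep(1, 100), mean_abundance = rep(2, 100))
  expect_error(fit_outlier_model(flat), "zero variance")
})

test_that("outlier scores are calibrated around the decision frontier", {
  feats <- make_features(500, seed = 4)
  model <- fit_outlier_model(feats, seed = 1)
  # an identical-profile pair (wip 0) at the training median abundance is
  # in-distribution
  expect_lte(outlier_score(model, 0, median(feats$mean_abundance)), 0.5)
  # a WIP far beyond anything in training is a certain outlier
  expect_gte(outlier_score(model, max(feats$wip) * 50,
                           median(feats$mean_abundance)), 0.99)
  # scores stay in [0,1] even for absurd inputs
  crazy <- outlier_score(model, c(0, 1e6), c(-100, 100))
  expect_true(all(crazy >= 0 & crazy <= 1))
  # monotone non-decreasing in wip at fixed abundance over the support
  grid <- seq(0, max(feats$wip), length.out = 50)
  sc <- outlier_score(model, grid, rep(median(feats$mean_abundance), 50))
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("call_significant uses a strict 0.5 threshold and the read filter", {
  feats <- make_features(300, seed = 6)
  model <- fit_outlier_model(feats, seed = 2)
  p <- tss_profile(replace(numeric(300), 120:140, 5))
  res <- call_significant(model, p, p, 100, 100)
  expect_equal(res$wip, 0)
  expect_false(res$is_different)

  # a score of exactly the threshold is not significant
  model_stub <- model
  model_stub$threshold <- res$score
  expect_false(call_significant(model_stub, p, p, 100, 100)$is_different)

  shallow <- tss_profile(replace(numeric(300), 150, 10))
  expect_error(call_significant(model, shallow, p, 10, 100), "filter")
})

test_that("model_accuracy counts label disagreement between replicates", {
  a <- c(p1 = TRUE, p2 = FALSE, p3 = TRUE, p4 = FALSE)
  expect_equal(model_accuracy(a, a)$disagreement, 0)
  expect_equal(model_accuracy(a, !a)$disagreement, 1)
  b <- a
  b["p3"] <- FALSE
  expect_equal(model_accuracy(a, b)$disagreement, 0.25)
  expect_equal(model_accuracy(a, b)$accuracy, 0.75)
  expect_error(model_accuracy(a, b[1:2]), "missing")
})

test_that("serialized models reproduce scores exactly", {
  feats <- make_features(250, seed = 8)
  model <- fit_outlier_model(feats, seed = 3)
  path <- tempfile(fileext = ".json")
  save_outlier_model(model, path)
  restored <- load_outlier_model(path)
  grid_w <- seq(0, 20, length.out = 40)
  grid_a <- seq(4, 12, length.out = 40)
  expect_equal(outlier_score(restored, grid_w, grid_a),
               outlier_score(model, grid_w, grid_a), tolerance = 1e-10)
  expect_equal(restored$threshold, 0.5)
})
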