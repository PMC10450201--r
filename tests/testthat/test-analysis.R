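# abundance table whose log2 pseudocounted ratios are exactly `log_ratios`
table_with_log_ratios <- function(log_ratios, groups, dna_cpm = 1000) {
  data.frame(
    insert_id = names(log_ratios),
    group_id = groups,
    rna_cpm = 2^log_ratios * (dna_cpm + 0.5) - 0.5,
    dna_cpm = dna_cpm,
    stringsAsFactors = FALSE
  )
}

test_that("barcode_variance centers log ratios by the group median", {
  lr <- c(a1 = 1, a2 = 2, a3 = 3, a4 = 4)
  tab <- table_with_log_ratios(lr, rep("g1", 4))
  res <- barcode_variance(tab)
  expect_equal(unname(res$centered[c("a1", "a2", "a3", "a4")]),
               c(-1.5, -0.5, 0.5, 1.5))
})

test_that("internally identical groups have zero dispersion, no outliers", {
  lr <- c(a1 = 2, a2 = 2, b1 = 5, b2 = 5)
  tab <- table_with_log_ratios(lr, c("g1", "g1", "g2", "g2"))
  res <- barcode_variance(tab)
  expect_equal(res$sd_global, 0)
  expect_length(res$outlier_ids, 0)
})

test_that("a single large spike is the only insert flagged", {
  set.seed(44)
  n_groups <- 30
  lr <- rnorm(n_groups * 4, sd = 0.1)
  ids <- sprintf("g%02d_b%d", rep(1:n_groups, each = 4), 1:4)
  names(lr) <- ids
  lr["g05_b2"] <- lr["g05_b2"] + 10 * sd(lr)
  tab <- table_with_log_ratios(lr, rep(sprintf("g%02d", 1:n_groups), each = 4))
  res <- barcode_variance(tab)
  expect_identical(res$outlier_ids, "g05_b2")
})

test_that("outlier set is invariant under global ratio scaling", {
  set.seed(45)
  lr <- rnorm(80, sd = 0.2)
  names(lr) <- sprintf("i%02d", 1:80)
  lr[17] <- 4
  groups <- rep(sprintf("g%02d", 1:20), each = 4)
  base <- barcode_variance(table_with_log_ratios(lr, groups))
  shifted <- barcode_variance(table_with_log_ratios(lr + log2(7), groups))
  expect_identical(base$outlier_ids, shifted$outlier_ids)
  expect_equal(base$sd_global, shifted$sd_global)
})

test_that("rank recovery is perfect for identical-profile groups", {
  set.seed(50)
  shapes <- replicate(5, random_profile(40), simplify = FALSE)
  profiles <- list()
  groups <- character(0)
  for (g in 1:5) {
    for (r in 1:4) {
      id <- sprintf("g%d_b%d", g, r)
      profiles[[id]] <- shapes[[g]]
      groups[id] <- sprintf("g%d", g)
    }
  }
  m <- score_matrix(profiles, "wip")
  res <- rank_recovery(m, groups, top_n = 4)
  expect_equal(res$recovery_rate, 1)
})

test_that("singleton shapes with non-replicate neighbors recover only self", {
  # every insert is a distinct delta, interleaved so that each insert's
  # nearest positions (lowest EMD) belong to other groups: only the
  # self-comparison lands in the top 4
  profiles <- list()
  groups <- character(0)
  for (r in 1:4) {
    for (g in 1:4) {
      id <- sprintf("g%d_b%d", g, r)
      profiles[[id]] <- delta_profile(10 + 10 * (4 * (r - 1) + g - 1),
                                      L = 200)
      groups[id] <- sprintf("g%d", g)
    }
  }
  m <- score_matrix(profiles, "emd")
  res <- rank_recovery(m, groups, top_n = 4)
  expect_equal(res$recovery_rate, 1 / 4)
  expect_true(all(res$per_insert_hits == 1))
})

test_that("rank recovery is invariant under insert relabeling", {
  set.seed(51)
  spec <- sim_spec(n_groups = 10, depth = 300, seed = 52)
  sim <- simulate_profiles(spec)
  m <- score_matrix(sim$replicate_profiles, "wip")
  base <- rank_recovery(m, sim$groups)
  perm <- sample(nrow(m))
  m2 <- m[perm, perm]
  expect_equal(rank_recovery(m2, sim$groups)$recovery_rate,
               base$recovery_rate)
})

test_that("replicate consistency partitions scores into A, B and C", {
  set.seed(53)
  spec <- sim_spec(n_groups = 8, depth = 500, sigma = 0.1, seed = 54)
  sim <- simulate_profiles(spec)
  ids <- names(sim$replicate_profiles)
  within <- score_matrix(sim$replicate_profiles, "wip")
  res <- replicate_consistency_groups(within, within, sim$groups)
  # identical "experiments": population A is the zero diagonal
  expect_equal(unname(res$A), rep(0, length(ids)))
  # B and C per-insert averages cover group size 3 and the rest
  expect_equal(res$summary$n, c(32, 32, 32))
  # replicate noise is smaller than genuine shape differences
  expect_lt(median(res$B), median(res$C))
  expect_error(
    replicate_consistency_groups(within, within[rev(ids), rev(ids)],
                                 sim$groups),
    "ids differ"
  )
})

test_that("nucleotide frequencies sum to one and honor anchors", {
  expect_equal(
    nucleotide_frequency(strrep("A", 21), 10, flank = 10)["A", ],
    setNames(rep(1, 21), as.character(-10:10))
  )
  one <- nucleotide_frequency("ACGTACGTACG", 5, flank = 2)
  expect_equal(colSums(one), setNames(rep(1, 5), as.character(-2:2)))
  expect_equal(one["C", "0"], 1) # base at offset 5 is C

  two <- nucleotide_frequency(c("AAAAA", "CCCCC"), c(2, 2), flank = 1)
  expect_equal(unname(two["A", "0"]), 0.5)
  expect_equal(unname(two["C", "0"]), 0.5)

  expect_warning(
    nucleotide_frequency("ACGT", 1, flank = 3),
    "skipped"
  )
  # N bases drop out of the denominator
  nn <- nucleotide_frequency("ANA", 1, flank = 1)
  expect_equal(unname(nn["A", "0"]), 0)
  expect_equal(unname(colSums(nn)), c(1, 0, 1))
})

test_that("contribution classification applies the inclusive 3x rule", {
  x <- tss_profile(c(0.3, 0.2, 0.1, 0.4), state = "unit", total_raw = 100)
  y <- tss_profile(c(0.1, 0.2, 0.0, 0.7), state = "unit", total_raw = 100)
  labels <- classify_tss_contribution(x, y)
  expect_equal(labels, c("x_higher", "comparable", "x_higher", "comparable"))
  # boundary: exactly 3x is included; symmetric direction flagged too
  x2 <- tss_profile(c(0.6, 0.1, 0.3), state = "unit", total_raw = 10)
  y2 <- tss_profile(c(0.2, 0.5, 0.3), state = "unit", total_raw = 10)
  expect_equal(classify_tss_contribution(x2, y2),
               c("x_higher", "y_higher", "comparable"))
  expect_error(classify_tss_contribution(
    tss_profile(numeric(3) + 0), x2
  ), "degenerate")
})
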