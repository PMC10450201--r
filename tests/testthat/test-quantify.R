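test_that("count_tss counts read-1 5' ends per base on the target strand", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(insA = 100L), c(
    sam_record("r1", 0L, "insA", 6, "10M"), # plus: 5' end at 0-based 5
    sam_record("r2", 0L, "insA", 6, "10M"),
    sam_record("r3", 0L, "insA", 6, "10M"),
    sam_record("r4", 16L, "insA", 6, "10M") # minus: 5' end at alignment end
  ))
  p <- count_tss(sam, list(region("insA", 0L, 100L, "+")))[[1]]
  expect_equal(p$values[6], 3) # 0-based position 5
  expect_equal(sum(p$values), 3) # minus-strand read not counted on +
  expect_identical(p$state, "raw")

  m <- count_tss(sam, list(region("insA", 0L, 100L, "-")))[[1]]
  # alignment spans 6..15 (1-based); minus 5' end at 0-based 14, and the
  # stored vector is 5'->3' on the minus strand (reversed)
  expect_equal(m$values[100 - 14], 1)
  expect_equal(sum(m$values), 1)
})

test_that("count_tss drops secondary/supplementary/unmapped and read 2", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(insA = 50L), c(
    sam_record("k1", 0L, "insA", 3, "5M"),       # kept
    sam_record("k2", 0x1 + 0x40, "insA", 3, "5M"), # paired read 1: kept
    sam_record("d1", 0x100, "insA", 3, "5M"),    # secondary
    sam_record("d2", 0x800, "insA", 3, "5M"),    # supplementary
    sam_record("d3", 0x1 + 0x80, "insA", 3, "5M") # read 2
  ))
  p <- count_tss(sam, list(region("insA", 0L, 50L, "+")))[[1]]
  expect_equal(sum(p$values), 2)
  expect_equal(p$values[3], 2)
})

test_that("count_tss conserves reads and handles empty input", {
  set.seed(8)
  sam <- tempfile(fileext = ".sam")
  pos <- sample(1:80, 40, replace = TRUE)
  write_test_sam(sam, c(insA = 100L),
                 vapply(seq_along(pos), function(i) {
                   sam_record(paste0("r", i), 0L, "insA", pos[i], "10M")
                 }, character(1)))
  p <- count_tss(sam, list(region("insA", 0L, 100L, "+")))[[1]]
  expect_equal(sum(p$values), 40)
  expect_equal(p$values, tabulate(pos, 100))

  empty <- tempfile(fileext = ".sam")
  write_test_sam(empty, c(insA = 100L), character(0))
  p0 <- count_tss(empty, list(region("insA", 0L, 100L, "+")))[[1]]
  expect_equal(sum(p0$values), 0)
})

test_that("count_barcodes matches exactly and tallies the rest", {
  lib <- insert_library(
    insert_id = c("x", "y"),
    group_id = c("g1", "g1"),
    barcode = c("AAAAAAAAAAA", "CCCCCCCCCCC"),
    sequence_length = c(150L, 150L)
  )
  reads <- c(rep("AAAAAAAAAAA", 10), rep("CCCCCCCCCCC", 4),
             "AAAAAAAAAAT", "GGGGGGGGGGG") # 1-mismatch is unassigned
  tab <- count_barcodes(reads, lib, "rna")
  expect_equal(tab$rna_raw[tab$insert_id == "x"], 10)
  expect_equal(tab$rna_raw[tab$insert_id == "y"], 4)
  expect_equal(attr(tab, "unassigned"), 2)
  expect_equal(sum(tab$rna_raw) + attr(tab, "unassigned"), length(reads))
})

test_that("insert_library rejects duplicate barcodes and bad cores", {
  expect_error(
    insert_library(c("a", "b"), c("g", "g"),
                   c("AAAAAAAAAAA", "AAAAAAAAAAA"), c(100L, 100L)),
    "duplicate barcodes"
  )
  expect_error(
    insert_library("a", "g", "AAAAAAAAAAA", 100L, core_start = 50L,
                   core_end = 150L),
    "core"
  )
})

test_that("normalize_abundance computes CPM and RNA/DNA ratios", {
  tab <- abundance_table(
    data.frame(insert_id = c("a", "b"), rna_raw = c(100L, 0L)),
    data.frame(insert_id = c("a", "b"), dna_raw = c(50L, 0L))
  )
  out <- normalize_abundance(tab, rna_total = 1e6, dna_total = 1e6)
  expect_equal(out$ratio[out$insert_id == "a"], 2)
  expect_true(is.na(out$ratio[out$insert_id == "b"])) # dna == 0 undefined

  expect_error(normalize_abundance(tab, rna_total = 0), "zero library total")
})

test_that("CPM columns sum to 1e6 and ratios survive depth doubling", {
  set.seed(15)
  tab <- abundance_table(
    data.frame(insert_id = sprintf("i%02d", 1:40),
               rna_raw = rpois(40, 200)),
    data.frame(insert_id = sprintf("i%02d", 1:40),
               dna_raw = rpois(40, 150) + 1L)
  )
  out <- normalize_abundance(tab)
  expect_equal(sum(out$rna_cpm), 1e6)
  expect_equal(sum(out$dna_cpm), 1e6)

  doubled <- tab
  doubled$rna_raw <- 2L * doubled$rna_raw
  doubled$dna_raw <- 2L * doubled$dna_raw
  expect_equal(normalize_abundance(doubled)$ratio, out$ratio)
})

test_that("quantile normalization replaces sorted values by their means", {
  out <- quantile_normalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
  expect_equal(unname(out[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "b"]), c(1.5, 3, 4.5))

  same <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(same), same)

  # tie-free columns end up with exactly identical sorted values
  set.seed(3)
  m <- cbind(runif(50, 0, 30), runif(50, 0, 300), runif(50, 0, 3))
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(sort(qn[, 1]), sort(qn[, 3]))
  expect_equal(mean(qn[, 1]), mean(qn[, 2]))

  # tied counts share the mean of their tied reference quantiles
  tied <- quantile_normalize(cbind(c(1, 1, 2), c(5, 6, 7)))
  expect_equal(tied[1, 1], tied[2, 1])
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "two columns")
})
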