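# Shared fixtures: all test data is generated in code.

# unit-mass single-base profile at 0-based offset i
delta_profile <- function(i, L = 20, mass = 1) {
  v <- numeric(L)
  v[i + 1L] <- mass
  tss_profile(v)
}

random_profile <- function(L, zero_frac = 0.5) {
  v <- stats::runif(L)
  v[stats::runif(L) < zero_frac] <- 0
  if (sum(v) == 0) v[sample.int(L, 1)] <- 1
  tss_profile(v)
}

# independent 1D minimum-cost transport: move mass between the leftmost
# unmatched supply and demand; optimal for convex per-unit cost |i - j|
emd_transport_oracle <- function(a, b) {
  a <- a / sum(a)
  b <- b / sum(b)
  i <- 1L
  j <- 1L
  cost <- 0
  while (i <= length(a) && j <= length(b)) {
    if (a[i] <= 1e-15) { i <- i + 1L; next }
    if (b[j] <= 1e-15) { j <- j + 1L; next }
    m <- min(a[i], b[j])
    cost <- cost + m * abs(i - j)
    a[i] <- a[i] - m
    b[j] <- b[j] - m
  }
  cost
}

# WIP + abundance features for matched profile lists, using raw read
# totals as the abundance counts
profile_pair_features <- function(pa, pb, min_promoters = 20) {
  aa <- vapply(pa, function(p) p$total_raw, numeric(1))
  ab <- vapply(pb, function(p) p$total_raw, numeric(1))
  build_training_features(pa, pb, aa, ab, min_promoters = min_promoters)
}

# one replicate-pair feature set from a fresh simulation: replicate 1 vs 2
# of every group, with raw read totals as the abundance counts
replicate_features <- function(spec) {
  sim <- simulate_profiles(spec)
  gids <- names(sim$true_profiles)
  prof_a <- stats::setNames(
    sim$replicate_profiles[paste0(gids, "_bc1")], gids
  )
  prof_b <- stats::setNames(
    sim$replicate_profiles[paste0(gids, "_bc2")], gids
  )
  ab_a <- vapply(prof_a, function(p) p$total_raw, numeric(1))
  ab_b <- vapply(prof_b, function(p) p$total_raw, numeric(1))
  list(
    features = build_training_features(prof_a, prof_b, ab_a, ab_b),
    sim = sim,
    profiles_a = prof_a,
    profiles_b = prof_b,
    abundance_a = ab_a,
    abundance_b = ab_b
  )
}

# write a small SAM file from header lines + alignment tuples
write_test_sam <- function(path, refs, records) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, ref, pos1, cigar, seq = NULL) {
  if (is.null(seq)) {
    len <- sum(as.integer(regmatches(cigar,
      gregexpr("[0-9]+(?=M)", cigar, perl = TRUE))[[1]]))
    seq <- strrep("A", len)
  }
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
          qname, flag, ref, pos1, cigar, seq)
}
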