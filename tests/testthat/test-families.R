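test_that("hamming distance is a metric on fixed-length strings", {
  expect_equal(hamming("GATCA", "GATCA"), 0L)
  expect_equal(hamming("GATCA", "GATCC"), 1L)
  expect_equal(hamming("ACGT", "TGCA"), 4L)  # complement at every position
  expect_error(hamming("ACGT", "ACGTT"), "unequal")
  set.seed(21)
  seqs <- apply(matrix(sample(c("A", "C", "G", "T"), 30 * 9, TRUE), 30), 1,
                paste, collapse = "")
  d <- hamming_matrix(seqs)
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  for (i in 1:15) {
    ijk <- sample(30, 3)
    expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]])
  }
})

test_that("mismatch distributions split pairs by family with full counts", {
  sigs <- c("AAAA", "AAAT", "TTTT", "TTTA")
  fams <- c("f1", "f1", "f2", "f2")
  dist <- mismatch_distributions(sigs, fams)
  expect_equal(attr(dist, "n_within"), 2L)   # two families of two
  expect_equal(attr(dist, "n_between"), 4L)
  expect_equal(sum(dist$within), 2L)
  expect_equal(sum(dist$between), 4L)
  # three identical members: all mass at zero
  d0 <- mismatch_distributions(c("AAAA", "AAAA", "AAAA", "CCCC"),
                               c("f", "f", "f", "g"))
  expect_equal(d0$within[d0$mismatches == 0], 3L)
  expect_equal(sum(d0$within[-1]), 0L)
  # single family: between side empty, flagged
  expect_warning(d1 <- mismatch_distributions(c("AAAA", "AAAT"), c("f", "f")),
                 "family")
  expect_equal(attr(d1, "n_between"), 0L)
})

test_that("threshold calibration picks the gap and fails on null input", {
  # perfectly separated planted distributions: within at 0..5, between at 8+
  ds <- generate_dataset(small_sim_config(seed = 31))
  tr <- ds$truth
  dist <- mismatch_distributions(tr$signature, tr$family)
  cal <- calibrate_threshold(dist)
  gap_lo <- max(dist$mismatches[dist$within > 0])
  gap_hi <- min(dist$mismatches[dist$between > 0])
  expect_gte(cal$threshold, gap_lo)
  expect_lt(cal$threshold, gap_hi)
  expect_equal(cal$table$misclassified[cal$table$t == cal$threshold], 0L)
  # indistinguishable distributions: no significant threshold
  same <- structure(data.frame(mismatches = 0:8,
                               within = c(0, 0, 5, 5, 5, 5, 0, 0, 0),
                               between = c(0, 0, 5, 5, 5, 5, 0, 0, 0)),
                    n_within = 20L, n_between = 20L,
                    class = c("mismatch_distribution", "data.frame"))
  expect_error(calibrate_threshold(same), "no threshold")
})

test_that("single linkage clusters by components with deterministic names", {
  # chain: a-b at 1, b-c at 1, a-c at 2 > t joins through b
  sigs <- c("AAAAA", "AAAAT", "AAATT", "GGGGG")
  out <- cluster_families(sigs, t = 1)
  expect_equal(out$family[1:3], rep("AAAAA", 3))
  expect_equal(out$family[4], "GGGGG")
  # all close: one family of three
  tight <- cluster_families(c("AAAAA", "AAAAT", "AAATA"), t = 2)
  expect_equal(length(unique(tight$family)), 1L)
  # input order invariance
  perm <- c(3, 1, 4, 2)
  out_perm <- cluster_families(sigs[perm], t = 1)
  expect_true(same_partition(
    stats::setNames(out$family, out$signature)[sigs],
    stats::setNames(out_perm$family, out_perm$signature)[sigs]))
  # t = 0 groups identical sequences only; t >= L gives one family
  expect_equal(length(unique(cluster_families(sigs, 0)$family)), 4L)
  expect_equal(length(unique(cluster_families(sigs, 5)$family)), 1L)
  # raising t never increases the family count
  set.seed(33)
  rnd <- unique(apply(matrix(sample(c("A", "C", "G", "T"), 40 * 6, TRUE), 40),
                      1, paste, collapse = ""))
  n_fam <- vapply(0:6, function(t) {
    length(unique(cluster_families(rnd, t)$family))
  }, numeric(1))
  expect_true(all(diff(n_fam) <= 0))
  # agrees with the naive merging oracle
  for (t in c(1, 2, 3)) {
    got <- cluster_families(rnd, t)
    expect_true(same_partition(got$family, cluster_oracle(rnd, t)))
  }
})

test_that("family size histogram counts size classes and large families", {
  singles <- data.frame(signature = letters[1:5], family = letters[1:5])
  h1 <- family_size_histogram(singles)
  expect_equal(h1$histogram, data.frame(size = 1L, n_families = 5L))
  mixed <- data.frame(signature = as.character(1:13),
                      family = rep(c("a", "b", "c"), c(3, 3, 7)))
  h2 <- family_size_histogram(mixed, large_cutoff = 5L)
  expect_equal(h2$histogram,
               data.frame(size = c(3L, 7L), n_families = c(2L, 1L)))
  expect_equal(h2$largest, 7L)
  expect_equal(h2$n_large, 1L)
})

test_that("planted families are recovered exactly by clustering at t = 5", {
  ds <- generate_dataset(small_sim_config(seed = 35, n_genes = 250L,
                                          n_families = 100L))
  tr <- ds$truth
  got <- cluster_families(tr$signature, t = 5)
  expect_true(same_partition(
    stats::setNames(got$family, got$signature)[tr$signature], tr$family))
  # histogram of the recovered assignment equals the planted family sizes
  h <- family_size_histogram(got)
  planted <- table(factor(as.integer(table(tr$family))))
  expect_equal(h$histogram$n_families, as.integer(planted))
})
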