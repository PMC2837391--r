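test_that("config validation names the violated constraint", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, library_depth = 0), "depth")
  expect_error(simulation_config(seed = 1, de_fraction = 1.4), "de_fraction")
  expect_error(simulation_config(seed = 1, within_family_max_mm = 8,
                                 between_family_min_mm = 8), "within_family")
  expect_error(simulation_config(seed = 1, signature_length = 4), "anchor")
  expect_error(simulation_config(seed = 1, n_genes = 100,
                                 exclusive_counts = c(X = 200)),
               "exclusive_counts")
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- small_sim_config(seed = 101)
  d1 <- tempfile()
  d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("counts.tsv", "unigenes.fasta", "annotations.tsv",
              "ground_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted structure obeys the declared invariants", {
  cfg <- small_sim_config(seed = 102)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  # depth conservation
  expect_true(all(colSums(ds$counts[-1]) == cfg$library_depth))
  # signatures all anchored and unique; non-noise ones in exactly one unigene
  expect_true(all(startsWith(tr$signature, "GATC")))
  expect_false(anyDuplicated(ds$counts$signature) > 0)
  unis <- as.character(ds$unigenes)
  n_hits <- vapply(tr$signature,
                   function(s) sum(vapply(unis, grepl, logical(1),
                                          pattern = s, fixed = TRUE)),
                   numeric(1))
  expect_true(all(n_hits == 1))
  # mismatch geometry: exhaustive all-pairs check
  d <- hamming_matrix(tr$signature)
  same <- outer(tr$family, tr$family, "==")
  ut <- upper.tri(d)
  expect_lte(max(d[ut & same]), cfg$within_family_max_mm)
  expect_gte(min(d[ut & !same]), cfg$between_family_min_mm)
  # exclusive genes: configured number, zero expected TPM elsewhere
  for (cc in names(cfg$exclusive_counts)) {
    rows <- tr[!is.na(tr$exclusive_to) & tr$exclusive_to == cc, ]
    expect_equal(nrow(rows), unname(cfg$exclusive_counts[cc]))
    other <- setdiff(cfg$condition_labels, cc)
    expect_true(all(rows[paste0("expected_tpm_", other)] == 0))
    expect_true(all(rows[[paste0("expected_tpm_", cc)]] > 0))
  }
  # planted expected-TPM ratios equal the planted fold changes
  de_n <- tr[tr$de_N != "none", ]
  expect_equal(log2(de_n$expected_tpm_N / de_n$expected_tpm_F),
               de_n$log2fc_N, tolerance = 1e-12)
  expect_true(all(tr$expected_tpm_F >= 0))
})

test_that("a null configuration is flat across conditions", {
  cfg <- small_sim_config(seed = 103, de_fraction = 0,
                          exclusive_counts = c(F = 0L, N = 0L, P = 0L,
                                               X = 0L))
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  tpm <- as.matrix(tr[paste0("expected_tpm_", cfg$condition_labels)])
  expect_true(all(abs(tpm - tpm[, 1]) < 1e-9))
})

test_that("realized TPM tracks expected TPM across seeds", {
  diffs <- vapply(1:20, function(s) {
    cfg <- small_sim_config(seed = 300 + s, n_background = 50L,
                            n_ambiguous = 5L, n_homopolymer = 5L)
    ds <- generate_dataset(cfg)
    expr <- qc_pipeline(ds$counts)
    g <- ds$truth[ds$truth$role == "gene" & is.na(ds$truth$exclusive_to), ][1, ]
    expr$tpm[g$signature, "F"] - g$expected_tpm_F
  }, numeric(1))
  expect_lte(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("family planting honours custom mismatch regimes", {
  cfg <- small_sim_config(seed = 104)
  set.seed(104)
  # singleton request
  single <- plant_family_signatures(1L, cfg)
  expect_equal(lengths(single), 1L)
  # two default families: cross distances verified exhaustively
  two <- plant_family_signatures(c(3L, 4L), cfg)
  cross <- hamming_matrix(two[[1]], two[[2]])
  expect_gte(min(cross), cfg$between_family_min_mm)
  within <- hamming_matrix(two[[2]])
  expect_lte(max(within), cfg$within_family_max_mm)
  # six signatures with 1-2 pairwise mismatches (translation elongation
  # factor style family)
  cfg_ef <- small_sim_config(seed = 105, within_family_max_mm = 2L,
                             between_family_min_mm = 8L)
  set.seed(105)
  ef <- plant_family_signatures(6L, cfg_ef)[[1]]
  d <- hamming_matrix(ef)
  off_diag <- d[upper.tri(d)]
  expect_true(all(off_diag >= 1 & off_diag <= 2))
  # infeasible: more members than the mismatch budget can host
  expect_error(plant_family_signatures(200L, cfg_ef), "infeasible")
})

test_that("datasets round-trip through the writers and readers", {
  cfg <- small_sim_config(seed = 106)
  ds <- generate_dataset(cfg)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$annotations, ds$annotations)
  expect_equal(as.character(back$unigenes), as.character(ds$unigenes))
  expect_equal(back$truth$signature, ds$truth$signature)
  # referential integrity: FASTA headers carry the annotated unigene ids
  expect_setequal(names(back$unigenes), back$annotations$unigene)
  # empty dataset: valid files, empty tables back
  cfg0 <- simulation_config(seed = 1, n_genes = 0L, n_families = 0L,
                            exclusive_counts = c(X = 0L), n_ballast = 0L,
                            n_ambiguous = 0L, n_homopolymer = 0L,
                            n_background = 0L)
  dir0 <- tempfile()
  write_dataset(generate_dataset(cfg0), dir0)
  empty <- read_dataset(dir0)
  expect_equal(nrow(empty$counts), 0L)
  expect_equal(length(empty$unigenes), 0L)
})
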