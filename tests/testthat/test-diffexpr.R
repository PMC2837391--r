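test_that("fisher_2x2 handles ties, symmetry and the hand-enumerable table", {
  expect_identical(fisher_2x2(500, 500, 1e6), 1)
  # [[5,5],[0,10]]: 6 tables with margins N=20, row=10, col=5; two extreme
  # tables each 252/15504
  expect_equal(fisher_2x2(5, 0, scale = 10), 504 / 15504, tolerance = 1e-12)
  # symmetry
  for (pair in list(c(7, 2), c(120, 80), c(4038, 2534))) {
    expect_equal(fisher_2x2(pair[1], pair[2], 1e4),
                 fisher_2x2(pair[2], pair[1], 1e4), tolerance = 1e-12)
  }
  # monotone in |x_t - x_c| at fixed control
  p_grid <- fisher_2x2(seq(100, 200, by = 10), 100, 1e4)
  expect_true(all(diff(p_grid) <= 1e-12))
  # input validation
  expect_error(fisher_2x2(-1, 5, 100), "0, scale")
  expect_error(fisher_2x2(101, 5, 100), "0, scale")
  expect_error(fisher_2x2(2.5, 5, 100), "integer")
})

test_that("fisher_2x2 agrees with enumeration and with stats::fisher.test", {
  set.seed(42)
  for (i in 1:60) {
    scale <- sample(10:250, 1)
    a <- sample(0:scale, 1)
    c_ <- sample(0:scale, 1)
    p <- fisher_2x2(a, c_, scale)
    expect_equal(p, fisher_oracle(a, scale - a, c_, scale - c_),
                 tolerance = 1e-12)
    expect_equal(p,
                 fisher.test(matrix(c(a, c_, scale - a, scale - c_), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment matches the step-up definition and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)                   # m = 1
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5)) # monotone cap
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # order of distinct raw p preserved
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("log2 fold change reproduces printed magnitudes and flags zeros", {
  expect_equal(round(log2_fold_change(4038, 2534), 1), 0.7)
  expect_equal(round(log2_fold_change(636, 291), 2), 1.13)
  expect_equal(log2_fold_change(50, 50), 0)
  expect_true(is.na(log2_fold_change(0, 10)))
  expect_true(is.na(log2_fold_change(10, 0)))
})

test_that("pairwise DE classifies planted differences and spares equality", {
  tpm <- rbind(flat = c(500, 500, 500, 500),
               up4x = c(500, 2000, 500, 500),
               weak = c(500, 520, 500, 500))
  colnames(tpm) <- c("F", "N", "P", "X")
  expr <- structure(list(tpm = tpm,
                         totals = c(F = 1e6, N = 1e6, P = 1e6, X = 1e6),
                         tpm_scale = 1e6), class = "mpss_expr")
  de <- run_pairwise_de(expr)
  expect_equal(nrow(de), 9L)  # 3 signatures x 3 treatments
  flat <- de[de$signature == "flat", ]
  expect_true(all(!flat$significant))
  expect_true(all(flat$raw_p == 1))
  up <- de[de$signature == "up4x" & de$treatment == "N", ]
  expect_true(up$significant)
  expect_equal(up$direction, "up")
  expect_equal(up$log2fc, 2)
  expect_false(de[de$signature == "weak" & de$treatment == "N", "significant"])
  # BH is applied within each treatment-control family
  n_pair <- de[de$treatment == "N", ]
  expect_equal(n_pair$adj_p, bh_oracle(n_pair$raw_p), tolerance = 1e-12)
  expect_error(run_pairwise_de(expr, de_config(control = "Z")), "control")
})

test_that("fisher p-values are valid under a multinomial null", {
  # the test operates on TPM-scale integers with totals fixed at the scale,
  # so the null draws use a depth equal to the scale (the sequencing regime
  # the method is built for)
  set.seed(11)
  probs <- rlnorm(400)
  probs <- probs / sum(probs)
  x1 <- as.integer(rmultinom(1, 1e6, probs))
  x2 <- as.integer(rmultinom(1, 1e6, probs))
  tpm1 <- round(x1 / sum(x1) * 1e6)
  tpm2 <- round(x2 / sum(x2) * 1e6)
  p <- fisher_2x2(tpm1, tpm2, 1e6)
  expect_lte(mean(p < 0.05), 0.06)
  expect_equal(sum(p < 1e-10), 0L)
})

test_that("exclusive signatures are those expressed in exactly one library", {
  tpm <- rbind(only4 = c(0, 0, 0, 9),
               everywhere = c(4, 4, 4, 4),
               two = c(4, 0, 4, 0))
  colnames(tpm) <- c("F", "N", "P", "X")
  expr <- structure(list(tpm = tpm, totals = c(F = 1, N = 1, P = 1, X = 1),
                         tpm_scale = 1e6), class = "mpss_expr")
  ex <- find_exclusive(expr)
  expect_equal(ex$X, "only4")
  expect_equal(lengths(ex)[c("F", "N", "P")], c(F = 0L, N = 0L, P = 0L))
})

test_that("DE summary partitions calls into intersection regions", {
  tpm <- rbind(x_only = c(500, 500, 500, 4000),
               np = c(500, 4000, 4000, 500),
               all3 = c(500, 4000, 4000, 4000))
  colnames(tpm) <- c("F", "N", "P", "X")
  expr <- structure(list(tpm = tpm,
                         totals = c(F = 1e6, N = 1e6, P = 1e6, X = 1e6),
                         tpm_scale = 1e6), class = "mpss_expr")
  de <- run_pairwise_de(expr)
  s <- summarize_de(de)
  regions <- stats::setNames(s$regions$count, s$regions$region)
  expect_equal(unname(regions["X"]), 1L)
  expect_equal(unname(regions["N&P"]), 1L)
  expect_equal(unname(regions["N&P&X"]), 1L)
  expect_equal(sum(s$regions$count), s$n_de)
  per <- s$per_treatment
  expect_equal(per$up + per$down, per$total)
})
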