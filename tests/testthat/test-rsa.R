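test_that("ROI extraction indexes voxels in canonical order", {
  vol <- array(seq_len(3 * 2 * 2 * 4), dim = c(3, 2, 2, 4))  # x, y, z, item
  mask <- roi_mask("two_voxels", rbind(c(2, 1, 0), c(0, 0, 1)),
                   volume_dim = c(3, 2, 2))
  pat <- extract_roi_patterns(vol, mask)
  # canonical order sorts (0,0,1) before (2,1,0)
  expect_equal(pat$patterns[, 1], vol[1, 1, 2, ])
  expect_equal(pat$patterns[, 2], vol[3, 2, 1, ])

  permuted <- roi_mask("two_voxels", rbind(c(0, 0, 1), c(2, 1, 0)),
                       volume_dim = c(3, 2, 2))
  expect_equal(extract_roi_patterns(vol, permuted)$patterns, pat$patterns)

  all_idx <- as.matrix(expand.grid(x = 0:2, y = 0:1, z = 0:1))
  full <- extract_roi_patterns(vol, roi_mask("all", all_idx,
                                             volume_dim = c(3, 2, 2)))
  expect_equal(dim(full$patterns), c(4, 12))
  expect_equal(sort(full$patterns[1, ]), as.vector(vol[, , , 1]))

  flat <- t(matrix(vol, 12, 4))  # items x all-voxels, column-major voxel order
  expect_equal(extract_roi_patterns(flat, mask)$patterns, pat$patterns)
  expect_error(extract_roi_patterns(vol, roi_mask("oob",
                                                  rbind(c(9, 0, 0), c(8, 0, 0)),
                                                  volume_dim = NULL)),
               "bounds")
  expect_error(roi_mask("empty", matrix(numeric(), 0, 3)), "non-empty")
})

test_that("fisher z is the inverse hyperbolic tangent with domain guards", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))   # 0.549306...
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), ">= 1")
  expect_error(fisher_z(-1.2), ">= 1")
})

test_that("pairwise similarity matches a textbook double-loop oracle", {
  set.seed(42)
  m1 <- matrix(rnorm(12), 3, 4)
  m2 <- matrix(rnorm(12), 3, 4)
  res <- pairwise_cross_language_ps(m1, m2)
  expect_equal(res$ps_z, pairwise_ps_naive(m1, m2), tolerance = 1e-12)
  expect_equal(res$n_pairs, 9)
  expect_equal(res$n_voxels, 4)
})

test_that("pairwise similarity recovers the generating shared fraction", {
  bank <- make_latent_patterns(20, 20, 5000, 0.5, seed = 31)
  res <- pairwise_cross_language_ps(bank$patterns_L1, bank$patterns_L2)
  expect_lt(abs(res$ps_z - atanh(0.5)), 0.04)

  null_bank <- make_latent_patterns(20, 20, 5000, 0, seed = 32)
  res0 <- pairwise_cross_language_ps(null_bank$patterns_L1,
                                     null_bank$patterns_L2)
  expect_lt(abs(res0$ps_z), 0.03)
})

test_that("similarity is monotone in the shared fraction", {
  est <- vapply(c(0.1, 0.3, 0.5, 0.7), function(rho) {
    bank <- make_latent_patterns(12, 12, 5000, rho, seed = 33)
    pairwise_cross_language_ps(bank$patterns_L1, bank$patterns_L2)$ps_z
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("pairwise similarity is invariant to item order and affine pattern maps", {
  bank <- make_latent_patterns(8, 8, 200, 0.4, seed = 34)
  base <- pairwise_cross_language_ps(bank$patterns_L1, bank$patterns_L2)
  shuf <- pairwise_cross_language_ps(bank$patterns_L1[sample(8), ],
                                     bank$patterns_L2[8:1, ])
  expect_equal(shuf$ps_z, base$ps_z)
  affine <- pairwise_cross_language_ps(3.7 * bank$patterns_L1 + 11,
                                       bank$patterns_L2)
  expect_equal(affine$ps_z, base$ps_z, tolerance = 1e-12)
})

test_that("degenerate correlations are guarded, with an explicit clip escape", {
  m <- matrix(rnorm(20), 4, 5)
  expect_error(pairwise_cross_language_ps(m, m), "\\+/-1")
  clipped <- pairwise_cross_language_ps(m, m, clip = TRUE)
  expect_true(is.finite(clipped$ps_z))
  flat <- m
  flat[2, ] <- 1
  expect_error(pairwise_cross_language_ps(flat, m), "zero-variance.*2")
  expect_error(pairwise_cross_language_ps(m, matrix(rnorm(8), 4, 2)),
               "3 voxels|voxel counts")
})

test_that("averaged-pattern similarity behaves on deterministic patterns", {
  m1 <- rbind(c(1, -1, 0, 0.5), c(1, -1, 0, 0.5))
  expect_error(averaged_pattern_ps(m1, 2 * m1), "\\+/-1")
  ok <- averaged_pattern_ps(m1, 2 * m1, clip = TRUE)
  expect_equal(ok$n_pairs, 1)
  expect_gt(ok$ps_z, 10)   # clipped perfect correlation

  # orthogonal zero-mean mean patterns
  a <- rbind(c(1, -1, 1, -1), c(1, -1, 1, -1))
  b <- rbind(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(averaged_pattern_ps(a, b)$ps_z, 0)
})

test_that("averaging patterns before correlating amplifies the shared signal", {
  wins <- 0
  for (i in 1:50) {
    bank <- make_latent_patterns(30, 30, 5000, 0.5, seed = 400 + i)
    avg <- averaged_pattern_ps(bank$patterns_L1, bank$patterns_L2)$ps_z
    pw <- pairwise_cross_language_ps(bank$patterns_L1, bank$patterns_L2)$ps_z
    if (avg >= pw) wins <- wins + 1
  }
  expect_gte(wins, 45)
})
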