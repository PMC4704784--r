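test_that("PSF pixel formula and validation", {
  expect_equal(psf_pixels(488, 1.3, 120), (0.8 * 488 / 1.3) / 120)
  expect_equal(psf_pixels(488, 1.3, (0.8 * 488 / 1.3)), 1.0)
  expect_error(psf_pixels(-488, 1.3, 120),
               class = "bbenrich_validation_error")
  expect_error(psf_pixels(488, 0, 120), class = "bbenrich_validation_error")
})

test_that("Pearson: identity, anti-correlation, and summation oracle", {
  set.seed(41)
  dims <- c(2L, 10L, 10L)
  ch1 <- array(runif(prod(dims), 0, 4095), dims)
  mask <- array(TRUE, dims)
  expect_equal(coloc_pearson(ch1, ch1, mask), 1.0)
  expect_equal(coloc_pearson(ch1, max(ch1) - ch1, mask), -1.0)
  ch2 <- array(runif(prod(dims), 0, 4095), dims)
  expect_equal(coloc_pearson(ch1, ch2, mask),
               oracle_pearson(ch1[mask], ch2[mask]), tolerance = 1e-12)
  expect_warning(r <- coloc_pearson(ch1, array(7, dims), mask), "constant")
  expect_true(is.na(r))
})

test_that("Pearson is invariant under positive affine transforms", {
  set.seed(43)
  dims <- c(1L, 12L, 12L)
  ch1 <- array(runif(prod(dims)), dims)
  ch2 <- array(runif(prod(dims)), dims)
  mask <- array(TRUE, dims)
  r0 <- coloc_pearson(ch1, ch2, mask)
  expect_equal(coloc_pearson(3.7 * ch1 + 11, ch2, mask), r0,
               tolerance = 1e-12)
  expect_equal(coloc_pearson(ch1, 0.2 * ch2 + 5, mask), r0,
               tolerance = 1e-12)
})

test_that("scramble p is seed-reproducible and saturates for structured pairs", {
  pair <- generate_coloc_pair(1.0, seed = 2)
  p1 <- scramble_p(pair$ch1, pair$ch2, pair$mask, block_pixels = 3,
                   n_iterations = 100, seed = 7)
  p2 <- scramble_p(pair$ch1, pair$ch2, pair$mask, block_pixels = 3,
                   n_iterations = 100, seed = 7)
  expect_identical(p1, p2)
  # identical-source structured channels: observed R beats every scramble
  expect_equal(p1, 1.0)
  # single-iteration determinism
  q1 <- scramble_p(pair$ch1, pair$ch2, pair$mask, 3, 1, seed = 123)
  q2 <- scramble_p(pair$ch1, pair$ch2, pair$mask, 3, 1, seed = 123)
  expect_identical(q1, q2)
  expect_true(q1 %in% c(0, 1))
})

test_that("scramble p needs at least two blocks", {
  dims <- c(1L, 4L, 4L)
  set.seed(1)
  a <- array(runif(16), dims); b <- array(runif(16), dims)
  expect_error(scramble_p(a, b, array(TRUE, dims), block_pixels = 4,
                          n_iterations = 10, seed = 1),
               class = "bbenrich_degenerate_input")
})

test_that("Manders coefficients: overlap extremes and hand-computed toy", {
  dims <- c(1L, 1L, 10L)
  mask <- array(TRUE, dims)
  # perfectly overlapping above-threshold signals
  a <- array(c(0, 0, 5, 5, 9, 9, 0, 0, 0, 0), dims)
  m <- manders(a, a, mask, t1 = 1, t2 = 1)
  expect_equal(unname(m), c(1, 1))
  # fully disjoint
  b <- array(c(9, 9, 0, 0, 0, 0, 0, 0, 0, 0), dims)
  c2 <- array(c(0, 0, 0, 0, 0, 0, 9, 9, 0, 0), dims)
  expect_equal(unname(manders(b, c2, mask, 1, 1)), c(0, 0))
  # hand-summed 10-voxel configuration, thresholds t1 = t2 = 10
  ch1 <- array(c(20, 15, 0, 40, 5, 0, 25, 0, 0, 10), dims)
  ch2 <- array(c(30, 0, 12, 50, 20, 0, 0, 11, 0, 40), dims)
  # ch1 > 10 at voxels 1,2,4,7 (sum 100); of those ch2 > 10 at 1,4 (sum 60)
  # ch2 > 10 at voxels 1,3,4,5,8,10 (sum 163); of those ch1 > 10 at 1,4 (80)
  m2 <- manders(ch1, ch2, mask, 10, 10)
  expect_equal(unname(m2[1]), 60 / 100)
  expect_equal(unname(m2[2]), 80 / 163)
  expect_warning(m3 <- manders(array(0, dims), ch2, mask, 10, 10), "Manders")
  expect_true(is.na(m3[1]))
})

test_that("Manders is bounded and monotone in the partner threshold", {
  set.seed(77)
  dims <- c(1L, 16L, 16L)
  ch1 <- array(rpois(prod(dims), 40), dims)
  ch2 <- array(rpois(prod(dims), 40), dims)
  mask <- array(TRUE, dims)
  prev <- Inf
  for (t2 in c(10, 30, 40, 50, 70)) {
    m <- suppressWarnings(manders(ch1, ch2, mask, t1 = 20, t2 = t2))
    expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
    expect_lte(m["m1"], prev)
    prev <- m["m1"]
  }
})

test_that("colocalize bundles all statistics with the PSF block size", {
  pair <- generate_coloc_pair(0.75, seed = 3)
  res <- colocalize(pair$ch1, pair$ch2, pair$mask,
                    lambda_ex = 488, numerical_aperture = 1.3,
                    pixel_size_nm = 120, t1 = 200, t2 = 200,
                    n_iterations = 50, seed = 11)
  expect_s3_class(res, "coloc_result")
  expect_equal(res$psf_pixels, 3L)  # round(2.503)
  expect_equal(res$n_iterations, 50L)
  expect_true(res$pearson_r > 0 && res$pearson_r <= 1)
  expect_true(res$p_scramble >= 0 && res$p_scramble <= 1)
  expect_true(all(c(res$manders_m1, res$manders_m2) >= 0))
})
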