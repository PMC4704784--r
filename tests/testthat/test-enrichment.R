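test_that("sphere partition classifies voxels by the published radii", {
  # 1-D line of voxels at 0.1 um pitch along x, center at origin
  vs <- c(0.1, 0.1, 0.1)
  dims <- c(1L, 1L, 80L)
  cyto <- array(TRUE, dims)
  part <- partition_cytoplasm(cyto, matrix(c(0, 0, 0), 1), 4.8, 6.0, vs)
  d_of <- function(x_idx) (x_idx - 1) * 0.1
  # d = 4.7 -> adjacent; 5.5 -> shell; 6.1 -> nonadjacent
  expect_true(part$adjacent[1, 1, which(abs(d_of(1:80) - 4.7) < 1e-9)])
  expect_true(part$shell[1, 1, which(abs(d_of(1:80) - 5.5) < 1e-9)])
  expect_true(part$nonadjacent[1, 1, which(abs(d_of(1:80) - 6.1) < 1e-9)])
  # boundary semantics (d == r is inclusive for both radii), checked on a
  # grid whose distances are exactly representable (0.25 um pitch)
  vs2 <- c(0.25, 0.25, 0.25)
  cyto2 <- array(TRUE, c(1L, 1L, 40L))
  part2 <- partition_cytoplasm(cyto2, matrix(c(0, 0, 0), 1), 4.5, 6.0, vs2)
  expect_true(part2$adjacent[1, 1, 19])     # d = 18 * 0.25 = 4.5 exactly
  expect_true(part2$shell[1, 1, 20])        # d = 4.75
  expect_true(part2$shell[1, 1, 25])        # d = 24 * 0.25 = 6.0 exactly
  expect_true(part2$nonadjacent[1, 1, 26])  # d = 6.25
})

test_that("multiple centers use the minimum distance (nest radii)", {
  vs <- c(0.5, 0.5, 0.5)
  dims <- c(1L, 1L, 41L)
  cyto <- array(TRUE, dims)
  centers <- rbind(c(0, 0, 0), c(0, 0, 10))  # 10 um apart along x
  part <- partition_cytoplasm(cyto, centers, 1.2, 2.4, vs)
  # voxel 1.0 um from the second center
  expect_true(part$adjacent[1, 1, which(abs((0:40) * 0.5 - 9.0) < 1e-9)])
  expect_true(part$adjacent[1, 1, which(abs((0:40) * 0.5 - 1.0) < 1e-9)])
  # midpoint (5 um from both) is nonadjacent
  expect_true(part$nonadjacent[1, 1, which(abs((0:40) * 0.5 - 5.0) < 1e-9)])
})

test_that("partition equals the brute-force distance oracle and is disjoint", {
  set.seed(17)
  vs <- c(0.53, 0.4, 0.4)
  dims <- c(9L, 11L, 11L)
  cyto <- array(runif(prod(dims)) < 0.8, dims)
  centers <- rbind(c(1.5, 1.2, 1.0), c(3.0, 3.0, 3.5))
  part <- partition_cytoplasm(cyto, centers, 1.2, 2.4, vs)
  for (lin in which(cyto)) {
    v <- arrayInd(lin, dims)
    d <- min(apply(centers, 1, function(cc)
      sqrt(sum((((v - 1) * vs) - cc)^2))))
    expect_identical(part$adjacent[lin], d <= 1.2)
    expect_identical(part$nonadjacent[lin], d > 2.4)
    expect_identical(part$shell[lin], d > 1.2 && d <= 2.4)
  }
  expect_false(any(part$adjacent & part$shell))
  expect_false(any(part$adjacent & part$nonadjacent))
  expect_false(any(part$shell & part$nonadjacent))
  expect_identical(part$adjacent | part$shell | part$nonadjacent, cyto)
  expect_error(partition_cytoplasm(cyto, matrix(numeric(0), 0, 3), 1.2, 2.4,
                                   vs),
               class = "bbenrich_no_centrosome")
})

test_that("regional means are plain arithmetic means per region", {
  dims <- c(2L, 4L, 4L)
  expch <- array(100, dims)
  masks <- list(nuclear = array(FALSE, dims))
  masks$nuclear[1, 1:2, 1:2] <- TRUE
  part <- list(adjacent = array(FALSE, dims), shell = array(FALSE, dims),
               nonadjacent = array(FALSE, dims))
  part$adjacent[2, 1:2, 1:2] <- TRUE
  part$nonadjacent[2, 3:4, 3:4] <- TRUE
  rm1 <- regional_means(expch, masks, part)
  expect_equal(c(rm1$mean_nuclear, rm1$mean_adjacent, rm1$mean_nonadjacent),
               c(100, 100, 100))
  expch[masks$nuclear] <- 10
  expch[part$adjacent] <- 40
  expch[part$nonadjacent] <- 20
  rm2 <- regional_means(expch, masks, part)
  expect_equal(c(rm2$mean_nuclear, rm2$mean_adjacent, rm2$mean_nonadjacent),
               c(10, 40, 20))
  # full-precision agreement with a voxel-list summation oracle
  set.seed(3)
  expch[] <- runif(prod(dims), 0, 4095)
  rm3 <- regional_means(expch, masks, part)
  vox <- which(part$adjacent)
  expect_equal(rm3$mean_adjacent, sum(expch[vox]) / length(vox))
  # empty region flagged
  part$adjacent[] <- FALSE
  rm4 <- regional_means(expch, masks, part)
  expect_true(is.na(rm4$mean_adjacent))
  expect_true("empty_region_adjacent" %in% rm4$qc_flags)
})

test_that("fold enrichment arithmetic, null case, and QC contract", {
  expect_equal(fold_enrichment(30, 15, 5)$fold, 2.5)
  expect_equal(fold_enrichment(20, 20, 5)$fold, 1.0)
  und <- fold_enrichment(20, 5, 5)  # denominator 0
  expect_true(is.na(und$fold))
  expect_true("undefined_fold" %in% und$qc_flags)
  neg <- fold_enrichment(20, 3, 5)  # denominator negative
  expect_true(is.na(neg$fold))
  expect_true("negative_norm" %in% neg$qc_flags)
})

test_that("fold is invariant under affine intensity rescaling", {
  set.seed(12)
  for (i in 1:20) {
    m <- sort(runif(3, 10, 100))  # nuclear < nonadjacent < adjacent
    f0 <- fold_enrichment(m[3], m[2], m[1])$fold
    g <- runif(1, 0.2, 5); c0 <- runif(1, -5, 50)
    f1 <- fold_enrichment(g * m[3] + c0, g * m[2] + c0, g * m[1] + c0)$fold
    expect_equal(f1, f0, tolerance = 1e-12)
  }
})

test_that("noiseless cleft analysis recovers the generative factor within 5%", {
  spec <- synthetic_spec("oocyte_cleft", enrichment_factor = 2,
                         noise = list(poisson = FALSE, gaussian_sd = 0),
                         voxel_size = c(0.53, 0.4, 0.4))
  g <- generate_oocyte(spec, seed = 4)
  res <- analyze_cleft(g$stack, g$rois$units[[1]],
                       synthetic_default_config("cleft"))
  expect_false(res$skipped)
  expect_equal(res$n_centrosomes, 1L)
  expect_lt(abs(res$fold - 2) / 2, 0.05)
})

test_that("uniform experimental channel gives fold near 1", {
  spec <- synthetic_spec("uniform_control", voxel_size = c(0.53, 0.4, 0.4))
  g <- generate_oocyte(spec, seed = 5)
  res <- analyze_cleft(g$stack, g$rois$units[[1]],
                       synthetic_default_config("cleft"))
  expect_lt(abs(res$fold - 1), 0.1)
})

test_that("an ROI that excludes the punctum is skipped with a QC flag", {
  spec <- synthetic_spec("oocyte_cleft", voxel_size = c(0.53, 0.4, 0.4))
  g <- generate_oocyte(spec, seed = 6)
  sq <- square_polygon(1, 6, 1, 6)  # far corner, no cell, no punctum
  unit <- roi_unit("corner", "oocyte",
                   list(list(z = 0L, x = sq$x, y = sq$y),
                        list(z = 1L, x = sq$x, y = sq$y)))
  res <- analyze_cleft(g$stack, unit, synthetic_default_config("cleft"))
  expect_true(res$skipped)
  expect_true("no_centrosome" %in% res$qc_flags)
  expect_true(is.na(res$fold))
})

test_that("nest analysis uses all centrosomes and tolerates a missing one", {
  spec <- synthetic_spec("nest", n_cells = 4, enrichment_factor = 1.6,
                         voxel_size = c(0.53, 0.3, 0.3),
                         missing_punctum = 2L)
  g <- generate_nest(spec, seed = 9)
  res <- analyze_nest(g$stack, g$rois$units[[1]],
                      synthetic_default_config("nest"))
  expect_false(res$skipped)
  expect_equal(res$n_centrosomes, 3L)  # one cell rendered without punctum
  expect_true(is.finite(res$fold))
})

test_that("group average fold drops undefined folds", {
  mk <- function(f) structure(list(fold = f), class = "enrichment_result")
  av <- average_fold(list(mk(2), mk(NA_real_), mk(3)))
  expect_equal(av$mean_fold, 2.5)
  expect_equal(av$n_used, 2L)
  expect_equal(av$n_dropped, 1L)
})
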