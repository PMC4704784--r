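test_that("axis-aligned square rasterizes to exactly the covered centers", {
  sq <- square_polygon(2, 5, 2, 5)
  polys <- lapply(0:3, function(z) list(z = z, x = sq$x, y = sq$y))
  unit <- roi_unit("u1", "oocyte", polys)
  mask <- rasterize_unit(unit, c(6L, 8L, 8L))
  expect_equal(sum(mask), 4 * 16)
  expect_true(all(mask[1:4, 3:6, 3:6]))
  expect_false(any(mask[5:6, , ]))
})

test_that("empty unit gives an all-false mask", {
  mask <- rasterize_unit(roi_unit("e", "oocyte", list()), c(3L, 5L, 5L))
  expect_false(any(mask))
})

test_that("rasterization matches the even-odd point-in-polygon oracle", {
  for (seed in 1:6) {
    p <- random_simple_polygon(seed)
    polys <- list(list(z = 0L, x = p$x, y = p$y),
                  list(z = 2L, x = p$x + 0.7, y = p$y - 0.4))
    unit <- roi_unit(paste0("r", seed), "oocyte", polys)
    dims <- c(3L, 15L, 15L)
    expect_identical(rasterize_unit(unit, dims), oracle_rasterize(polys, dims),
                     info = paste("seed", seed))
  }
})

test_that("rasterization is idempotent and slice-bound checked", {
  p <- random_simple_polygon(99)
  unit <- roi_unit("u", "oocyte", list(list(z = 1L, x = p$x, y = p$y)))
  m1 <- rasterize_unit(unit, c(2L, 15L, 15L))
  expect_identical(m1, rasterize_unit(unit, c(2L, 15L, 15L)))
  bad <- roi_unit("b", "oocyte", list(list(z = 5L, x = p$x, y = p$y)))
  expect_error(rasterize_unit(bad, c(2L, 15L, 15L)),
               class = "bbenrich_validation_error")
})

test_that("self-intersecting polygons are rejected", {
  # bowtie
  expect_error(roi_unit("x", "oocyte",
                        list(list(z = 0L, x = c(0, 4, 0, 4),
                                  y = c(0, 4, 4, 0)))),
               class = "bbenrich_validation_error")
  # simple square passes
  expect_silent(roi_unit("ok", "oocyte",
                         list(list(z = 0L, x = c(0, 4, 4, 0),
                                   y = c(0, 0, 4, 4)))))
})

test_that("JSON ROI dialect round-trips", {
  p <- random_simple_polygon(3)
  rois <- roi_set(list(
    roi_unit("oo1", "oocyte", list(list(z = 0L, x = p$x, y = p$y))),
    roi_unit("nest1", "nest", list(list(z = 1L, x = p$x + 1, y = p$y),
                                   list(z = 2L, x = p$x, y = p$y + 2)))))
  path <- file.path(tempdir(), "rois.json")
  write_roi_json(rois, path)
  back <- read_roi_json(path)
  expect_equal(length(back$units), 2L)
  expect_equal(back$units[[2]]$kind, "nest")
  expect_equal(back$units[[2]]$polygons[[1]]$x, p$x + 1)
  expect_equal(back$units[[1]]$polygons[[1]]$z, 0L)
})

test_that("ImageJ ROI records round-trip through directory and zip", {
  # integer vertices: the ImageJ record stores short integers
  sq <- list(x = c(2, 9, 9, 2), y = c(3, 3, 8, 8))
  rois <- roi_set(list(
    roi_unit("cellA", "oocyte", list(list(z = 0L, x = sq$x, y = sq$y),
                                     list(z = 1L, x = sq$x + 2, y = sq$y))),
    roi_unit("cellB", "oocyte", list(list(z = 4L, x = sq$x, y = sq$y + 1)))))
  dir <- file.path(tempdir(), "ij_rois")
  unlink(dir, recursive = TRUE)
  write_imagej_rois(rois, dir)
  back <- read_imagej_rois(dir)
  nm <- vapply(back$units, `[[`, character(1), "name")
  expect_setequal(nm, c("cellA", "cellB"))
  ua <- back$units[[which(nm == "cellA")]]
  expect_equal(length(ua$polygons), 2L)
  zs <- sort(vapply(ua$polygons, `[[`, integer(1), "z"))
  expect_equal(zs, c(0L, 1L))
  pa <- ua$polygons[[which(zs == 0L)]]
  expect_equal(sort(pa$x), sort(round(sq$x)))
  expect_equal(sort(pa$y), sort(round(sq$y)))
  # zip archive path (archive built with an external tool)
  zip_path <- file.path(tempdir(), "ij_rois.zip")
  unlink(zip_path)
  status <- system2("python", c("-c", shQuote(sprintf(
    "import zipfile, glob, os; z = zipfile.ZipFile('%s', 'w'); [z.write(f, os.path.basename(f)) for f in glob.glob('%s/*.roi')]; z.close()",
    zip_path, dir))))
  expect_equal(status, 0L)
  back_zip <- read_imagej_rois(zip_path)
  expect_setequal(vapply(back_zip$units, `[[`, character(1), "name"),
                  c("cellA", "cellB"))
})

test_that("rasterized ImageJ ROIs equal the JSON-dialect rasterization", {
  sq <- list(x = c(3, 7, 7, 3), y = c(2, 2, 6, 6))
  unit <- roi_unit("u", "oocyte", list(list(z = 0L, x = sq$x, y = sq$y)))
  dir <- file.path(tempdir(), "ij_eq")
  unlink(dir, recursive = TRUE)
  write_imagej_rois(roi_set(list(unit)), dir)
  back <- read_imagej_rois(dir)$units[[1]]
  dims <- c(1L, 12L, 12L)
  expect_identical(rasterize_unit(back, dims), rasterize_unit(unit, dims))
})
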