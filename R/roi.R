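#' ROI units: hand-drawn per-slice polygon outlines
#'
#' An ROI unit names one analysis unit (a single oocyte or a whole nest) and
#' carries one closed polygon per z-slice. Coordinate conventions follow the
#' usual ROI tooling: polygon vertices are in pixel units, integer
#' coordinates address pixel centers, and voxel indices are 0-based
#' `(z, y, x)`.
#'
#' @param name unit identifier.
#' @param kind `"oocyte"` or `"nest"`.
#' @param polygons list of `list(z =, x =, y =)` entries: `z` is the 0-based
#'   slice index, `x`/`y` the polygon vertices (the closing edge back to the
#'   first vertex is implicit).
#' @return an object of class `roi_unit`.
#' @export
roi_unit <- function(name, kind = c("oocyte", "nest"), polygons = list()) {
  kind <- match.arg(kind)
  for (p in polygons) {
    if (is.null(p$z) || is.null(p$x) || is.null(p$y))
      stopf("each polygon needs z, x and y")
    if (length(p$x) != length(p$y))
      stopf("polygon x and y lengths differ (unit '%s', slice %d)",
            name, p$z)
    if (length(p$x) >= 3 && polygon_self_intersects(p$x, p$y))
      stopf("self-intersecting polygon in unit '%s', slice %d", name, p$z,
            class = "bbenrich_validation_error")
  }
  structure(list(name = name, kind = kind, polygons = polygons),
            class = "roi_unit")
}

#' @param units list of [roi_unit()] objects.
#' @rdname roi_unit
#' @export
roi_set <- function(units) {
  if (!all(vapply(units, inherits, logical(1), "roi_unit")))
    stopf("units must be roi_unit objects")
  structure(list(units = units), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set with %d unit(s):\n", length(x$units)))
  for (u in x$units)
    cat(sprintf("  %s [%s], %d slice polygon(s)\n", u$name, u$kind,
                length(u$polygons)))
  invisible(x)
}

## even-odd self-intersection guard: any two non-adjacent edges crossing
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  seg_int <- function(i, j) {
    p1 <- c(xs[i], ys[i]); p2 <- c(xs[i + 1], ys[i + 1])
    p3 <- c(xs[j], ys[j]); p4 <- c(xs[j + 1], ys[j + 1])
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (seg_int(i, j)) return(TRUE)
    }
  FALSE
}

#' Rasterize an ROI unit to a 3-D binary mask
#'
#' A voxel is in-mask iff its (y, x) pixel center lies strictly inside that
#' slice's polygon (even-odd rule); slices without a polygon are all-FALSE.
#'
#' @param unit a [roi_unit()].
#' @param dims stack dimensions `(nz, ny, nx)`.
#' @return 3-D logical array.
#' @export
rasterize_unit <- function(unit, dims) {
  if (!inherits(unit, "roi_unit")) stopf("unit must be a roi_unit")
  mask <- array(FALSE, dims)
  if (length(unit$polygons) == 0L) return(mask)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  pts <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)))
  for (p in unit$polygons) {
    z <- p$z + 1L  # 0-based slice -> 1-based array index
    if (z < 1L || z > nz)
      stopf("polygon slice %d outside stack (nz = %d)", p$z, nz,
            class = "bbenrich_validation_error")
    if (length(p$x) < 3) next
    if (polygon_self_intersects(p$x, p$y))
      stopf("self-intersecting polygon in unit '%s', slice %d",
            unit$name, p$z, class = "bbenrich_validation_error")
    inside <- mgcv::in.out(cbind(c(p$x, p$x[1]), c(p$y, p$y[1])), pts)
    mask[z, , ] <- mask[z, , ] | t(matrix(inside, nx, ny))
  }
  mask
}

# ---- JSON ROI dialect (the internal model) --------------------------------

#' Read / write the JSON ROI dialect
#'
#' The JSON form is the package's canonical ROI representation:
#' `{"units": [{"name":, "kind":, "polygons": [{"z":, "x": [], "y": []}]}]}`
#' with 0-based slice indices and pixel-center vertex coordinates.
#'
#' @param path file path.
#' @return `read_roi_json`: a [roi_set()].
#' @export
read_roi_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  units <- lapply(doc$units, function(u) {
    polys <- lapply(u$polygons, function(p)
      list(z = as.integer(p$z), x = as.numeric(unlist(p$x)),
           y = as.numeric(unlist(p$y))))
    roi_unit(u$name, u$kind %||% "oocyte", polys)
  })
  roi_set(units)
}

#' @param rois a [roi_set()].
#' @rdname read_roi_json
#' @export
write_roi_json <- function(rois, path) {
  doc <- list(units = lapply(rois$units, function(u)
    list(name = u$name, kind = u$kind,
         polygons = lapply(u$polygons, function(p)
           list(z = p$z, x = p$x, y = p$y)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- ImageJ ROI format (polygon records) ----------------------------------

## Minimal reader/writer for ImageJ ".roi" polygon records (types 0 polygon,
## 7 freehand). Big-endian; header: "Iout", version (short), type (byte),
## top/left/bottom/right (shorts at offset 8), nCoords (short at 16),
## header2 offset (int at 56); coordinates at offset 64 as shorts relative
## to (left, top). The z position is taken from header2 (+8) when present,
## else from a leading "<slice>-" prefix of the file name (both 1-based).

read_imagej_roi_bytes <- function(raw, name) {
  con <- rawConnection(raw)
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) stopf("'%s' is not an ImageJ ROI", name)
  readBin(con, "integer", 1, 2, endian = "big")         # version
  type <- readBin(con, "integer", 1, 1, signed = FALSE)
  readBin(con, "integer", 1, 1, signed = FALSE)          # filler
  top <- readBin(con, "integer", 1, 2, endian = "big")
  left <- readBin(con, "integer", 1, 2, endian = "big")
  readBin(con, "integer", 2, 2, endian = "big")          # bottom, right
  n <- readBin(con, "integer", 1, 2, endian = "big")
  if (!type %in% c(0L, 7L))
    stopf("unsupported ImageJ ROI type %d in '%s' (only polygon/freehand)",
          type, name)
  seek(con, 56)
  h2 <- readBin(con, "integer", 1, 4, endian = "big")
  seek(con, 64)
  xr <- readBin(con, "integer", n, 2, endian = "big")
  yr <- readBin(con, "integer", n, 2, endian = "big")
  zpos <- 0L
  if (h2 > 0 && length(raw) >= h2 + 12) {
    seek(con, h2 + 8)
    zpos <- readBin(con, "integer", 1, 4, endian = "big")
  }
  if (zpos == 0L) {
    m <- regmatches(name, regexpr("^[0-9]+", name))
    if (length(m) == 1L && nchar(m) > 0) zpos <- as.integer(m)
  }
  if (zpos == 0L)
    stopf("cannot determine slice for ROI '%s' (no position, no name prefix)",
          name)
  list(z = zpos - 1L, x = xr + left, y = yr + top)
}

#' Read ImageJ ROIs (zip archive, directory, or single .roi)
#'
#' Accepts the archives interactive ROI tools export. File names are
#' expected as `<unit>_<anything>.roi` to group slices into units; ROIs
#' whose names carry no `<unit>_` prefix form one unit per file. Only
#' polygon-type records are supported.
#'
#' @param path `.zip` archive, directory of `.roi` files, or one `.roi`.
#' @param kind unit kind to assign (`"oocyte"` or `"nest"`).
#' @return a [roi_set()].
#' @export
read_imagej_rois <- function(path, kind = "oocyte") {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.roi$", full.names = TRUE)
    names(files) <- basename(files)
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("rois")
    utils::unzip(path, exdir = exdir)
    files <- list.files(exdir, pattern = "\\.roi$", full.names = TRUE,
                        recursive = TRUE)
    names(files) <- basename(files)
  } else {
    files <- stats::setNames(path, basename(path))
  }
  if (length(files) == 0L) stopf("no .roi files found at %s", path)
  recs <- lapply(names(files), function(nm)
    read_imagej_roi_bytes(readBin(files[[nm]], "raw",
                                  file.size(files[[nm]])), nm))
  base <- sub("\\.roi$", "", names(files))
  unit_of <- ifelse(grepl("_", base), sub("_[^_]*$", "", base), base)
  sets <- split(recs, unit_of)
  roi_set(lapply(names(sets), function(u)
    roi_unit(u, kind, unname(sets[[u]]))))
}

write_imagej_roi_bytes <- function(poly, name) {
  x <- round(poly$x); y <- round(poly$y)
  left <- min(x); top <- min(y)
  n <- length(x)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL, useBytes = TRUE)
  writeBin(228L, con, 2, endian = "big")                   # version
  writeBin(as.raw(c(0L, 0L)), con)                         # type=0 polygon
  writeBin(as.integer(c(top, left, max(y) + 1, max(x) + 1, n)), con, 2,
           endian = "big")
  writeBin(raw(64 - 18), con)                              # pad to coords...
  seek(con, 56)
  h2 <- 64L + 4L * n
  writeBin(h2, con, 4, endian = "big")
  seek(con, 64)
  writeBin(as.integer(x - left), con, 2, endian = "big")
  writeBin(as.integer(y - top), con, 2, endian = "big")
  writeBin(integer(2), con, 4, endian = "big")             # header2 start
  writeBin(as.integer(poly$z + 1L), con, 4, endian = "big")  # z position
  writeBin(integer(10), con, 4, endian = "big")
  rawConnectionValue(con)
}

#' @param rois a [roi_set()]; polygon coordinates are rounded to integer
#'   pixels (the ImageJ record stores shorts).
#' @param dir output directory (created if needed); one
#'   `<unit>_z<slice>.roi` file per slice polygon.
#' @rdname read_imagej_rois
#' @export
write_imagej_rois <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (u in rois$units)
    for (p in u$polygons) {
      f <- file.path(dir, sprintf("%s_z%04d.roi", u$name, p$z + 1L))
      writeBin(write_imagej_roi_bytes(p, u$name), f)
    }
  invisible(dir)
}
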