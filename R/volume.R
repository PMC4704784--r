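#' Multi-channel 3-D intensity volume
#'
#' A `volume_stack` holds one 3-D intensity array per channel role together
#' with the physical voxel spacing and the acquisition bit depth. Arrays are
#' indexed `[z, y, x]`; all channels share one grid. Intensities must lie in
#' `[0, 2^bit_depth - 1]`.
#'
#' @param channels named list of 3-D numeric arrays; names are channel roles
#'   (e.g. `"experimental"`, `"gamma_tubulin"`, `"dapi"`).
#' @param voxel_size numeric `(dz, dy, dx)` in um (confocal stacks here use a
#'   z-step of 0.53 um; the xy pitch depends on zoom and must be supplied).
#' @param bit_depth integer, intensity bit depth (default 12).
#' @return an object of class `volume_stack`.
#' @export
#' @examples
#' a <- array(0, c(4, 8, 8))
#' vs <- volume_stack(list(dapi = a, gamma_tubulin = a), c(0.53, 0.2, 0.2))
#' dim(vs)
volume_stack <- function(channels, voxel_size, bit_depth = 12L) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a non-empty named list of 3-D arrays")
  dims <- dim(channels[[1]])
  if (length(dims) != 3L) stopf("channel arrays must be 3-D (z, y, x)")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), dims))
      stopf("channel '%s' shape differs from the first channel", nm,
            class = "bbenrich_format_error")
    if (any(!is.finite(ch)) || any(ch < 0))
      stopf("channel '%s' has negative or non-finite intensities", nm)
    if (any(ch > 2^bit_depth - 1))
      stopf("channel '%s' exceeds the %d-bit range", nm, bit_depth)
  }
  structure(list(channels = channels,
                 voxel_size = check_voxel_size(voxel_size),
                 bit_depth = as.integer(bit_depth)),
            class = "volume_stack")
}

#' @export
dim.volume_stack <- function(x) dim(x$channels[[1]])

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("volume_stack: %d channel(s) [%s], %d x %d x %d (z,y,x), %d-bit\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("voxel size (um): dz=%g dy=%g dx=%g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Channel accessor
#'
#' @param stack a [volume_stack()].
#' @param role channel role name.
#' @return the 3-D intensity array for that role.
#' @export
get_channel <- function(stack, role) {
  ch <- stack$channels[[role]]
  if (is.null(ch))
    stopf("channel role '%s' not present (have: %s)", role,
          paste(names(stack$channels), collapse = ", "),
          class = "bbenrich_config_error")
  ch
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF stack into a volume_stack
#'
#' Pages are expected interleaved channel-fastest: page `(z - 1) * nc + c`
#' holds channel `c` of slice `z` (the layout [write_stack()] produces).
#' Voxel size, channel roles and bit depth can be given explicitly or read
#' from the JSON sidecar `<path>.json` written by [write_stack()]; explicit
#' arguments win.
#'
#' @param path TIFF file path.
#' @param channel_roles named integer vector or list mapping role -> 1-based
#'   channel index within a slice.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param bit_depth intensity bit depth (default 12).
#' @return a [volume_stack()].
#' @export
load_stack <- function(path, channel_roles = NULL, voxel_size = NULL,
                       bit_depth = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  channel_roles <- channel_roles %||% meta$channel_roles
  voxel_size <- voxel_size %||% meta$voxel_size
  bit_depth <- bit_depth %||% meta$bit_depth %||% 12L
  if (is.null(channel_roles))
    stopf("channel_roles must be supplied (no sidecar metadata found)",
          class = "bbenrich_config_error")
  if (is.null(voxel_size))
    stopf("voxel_size must be supplied (no sidecar metadata found)",
          class = "bbenrich_config_error")
  roles <- unlist(channel_roles)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nc <- length(roles)
  if (length(pages) %% nc != 0L)
    stopf("%d TIFF pages are not divisible by %d channel roles",
          length(pages), nc, class = "bbenrich_config_error")
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  for (p in pages)
    if (nrow(p) != ny || ncol(p) != nx)
      stopf("TIFF pages differ in shape", class = "bbenrich_format_error")
  channels <- lapply(roles, function(ci) {
    a <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- pages[[(z - 1L) * nc + ci]]
    a
  })
  names(channels) <- names(roles)
  volume_stack(channels, voxel_size, bit_depth)
}

#' Write a volume_stack as a multi-page TIFF (plus JSON sidecar)
#'
#' Pages are written channel-fastest (see [load_stack()]), 16 bits per
#' sample, intensities unmodified. Voxel size, channel roles and bit depth go
#' to `<path>.json` because the TIFF writer does not persist a description
#' tag.
#'
#' @param stack a [volume_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  nc <- length(stack$channels)
  pages <- vector("list", d[1] * nc)
  for (z in seq_len(d[1]))
    for (ci in seq_len(nc))
      pages[[(z - 1L) * nc + ci]] <- stack$channels[[ci]][z, , ] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  jsonlite::write_json(
    list(channel_roles = as.list(stats::setNames(seq_len(nc),
                                                 names(stack$channels))),
         voxel_size = stack$voxel_size,
         bit_depth = stack$bit_depth),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
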