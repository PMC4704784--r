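# Brute-force reference implementations used as independent oracles.
# All deliberately scalar / loop-based and separate from the package code.

# even-odd crossing point-in-polygon (vertices px, py; point x, y)
oracle_point_in_polygon <- function(px, py, x, y) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(polygons, dims) {
  mask <- array(FALSE, dims)
  for (p in polygons) {
    z <- p$z + 1L
    for (iy in seq_len(dims[2]))
      for (ix in seq_len(dims[3]))
        if (oracle_point_in_polygon(p$x, p$y, ix - 1, iy - 1))
          mask[z, iy, ix] <- TRUE
  }
  mask
}

# BFS flood-fill connected-component labeling
oracle_label <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 offs)
  lab <- array(0L, dims)
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- list(arrayInd(start, dims)[1, ])
    lab[start] <- nextlab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1L) || any(w > dims)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nextlab
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# labelings agree iff they induce the same voxel partition
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0]; f2 <- lab2[lab2 > 0]
  if (!identical(lab1 > 0, lab2 > 0)) return(FALSE)
  length(unique(paste(f1, f2))) == length(unique(f1)) &&
    length(unique(paste(f1, f2))) == length(unique(f2))
}

# scalar-loop anisotropic EDT (distance to nearest background voxel center)
# and centroid of the global-argmax set, in um
oracle_edt_center <- function(voxel_set, voxel_size) {
  lo <- apply(voxel_set, 2, min) - 1L
  hi <- apply(voxel_set, 2, max) + 1L
  dl <- hi - lo + 1L
  box <- array(FALSE, dl)
  box[sweep(voxel_set, 2, lo - 1L)] <- TRUE
  dt <- rep(NA_real_, nrow(voxel_set))
  for (i in seq_len(nrow(voxel_set))) {
    v <- voxel_set[i, ]
    best <- Inf
    for (z in seq_len(dl[1])) for (y in seq_len(dl[2])) for (x in seq_len(dl[3])) {
      if (box[z, y, x]) next
      g <- c(z, y, x) + lo - 1L
      d2 <- sum(((g - v) * voxel_size)^2)
      if (d2 < best) best <- d2
    }
    dt[i] <- sqrt(best)
  }
  sel <- dt >= max(dt) - 1e-9
  colMeans(sweep(voxel_set[sel, , drop = FALSE] - 1, 2, voxel_size, `*`))
}

# random connected blob grown from a seed voxel
random_blob <- function(dims, n_target, seed, connectivity = 6L) {
  set.seed(seed)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  vox <- matrix(ceiling(dims / 2), 1)
  seen <- new.env()
  assign(paste(vox[1, ], collapse = ","), TRUE, envir = seen)
  while (nrow(vox) < n_target) {
    v <- vox[sample.int(nrow(vox), 1), ]
    w <- v + offs[sample.int(nrow(offs), 1), ]
    if (any(w < 1L) || any(w > dims)) next
    key <- paste(w, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      vox <- rbind(vox, w)
    }
  }
  vox
}

# textbook two-pass Pearson
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

square_polygon <- function(x0, x1, y0, y1) {
  list(x = c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
       y = c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5))
}

random_simple_polygon <- function(seed, cx = 7, cy = 7, rmin = 2, rmax = 6,
                                  nv = 8) {
  set.seed(seed)
  th <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, rmin, rmax)
  list(x = cx + r * cos(th), y = cy + r * sin(th))  # star-shaped => simple
}
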