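# Low-level 3D raster operations shared by the imaging modules. Physical
# units (um) are handled by the callers; these work in voxel space unless a
# spacing argument says otherwise.

# Shift a 3D array by one voxel along `axis` in direction `dir`, filling
# with `fill`.
.shift3 <- function(a, axis, dir, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected binary erosion / dilation.
erode6 <- function(m) {
  out <- m
  for (ax in 1:3) for (dir in c(-1, 1)) {
    out <- out & .shift3(m, ax, dir, fill = FALSE)
  }
  out
}

dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) for (dir in c(-1, 1)) {
    out <- out | .shift3(m, ax, dir, fill = FALSE)
  }
  out
}

# Erode by a physical rim: repeated 6-connected erosion, step count per axis
# chosen from the voxel size (an axis stops contributing once k * size >=
# rim). Simple and adequate for sub-um rims on near-isotropic xy grids.
erode_rim_um <- function(mask, rim_um, voxel_size) {
  if (all(rim_um <= 0)) return(mask)
  steps <- ceiling(rim_um / voxel_size - 1e-9)
  n <- max(steps)
  out <- mask
  for (k in seq_len(n)) {
    m <- out
    for (ax in 1:3) {
      if (k <= steps[ax]) {
        for (dir in c(-1, 1)) m <- m & .shift3(out, ax, dir, FALSE)
      }
    }
    out <- m
  }
  out
}

# Separable Gaussian blur with edge replication; sigma in voxels per axis.
blur3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    d <- dim(a)
    acc <- array(0, d)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(d[ax]) + j, 1L), d[ax])
      sl <- switch(ax,
                   a[idx, , , drop = FALSE],
                   a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      acc <- acc + w[j + r + 1] * sl
    }
    a <- acc
  }
  a
}

# Otsu threshold on a 256-bin histogram of the supplied intensities.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  abort_if(rng[1] == rng[2], "degenerate (constant) intensities")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sb <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sb)
  breaks[k + 1L]
}

# Background/foreground threshold that descends to the LOWEST bimodal
# split: Otsu can land between dim and bright foreground classes (e.g.
# cytosol vs mitochondria) when the bright class dominates the variance;
# re-applying Otsu to the sub-threshold voxels walks down to the
# background/cell split as long as the sub-split stays strongly bimodal.
background_threshold <- function(values, min_eta = 0.6, min_frac = 0.05) {
  thr <- otsu_threshold(values)
  repeat {
    below <- values[values <= thr]
    if (length(below) < 100 || length(unique(below)) < 10) break
    sub <- tryCatch(otsu_threshold(below), error = function(e) NULL)
    if (is.null(sub)) break
    lo <- below <= sub
    if (!any(lo) || all(lo)) break
    p <- mean(lo)
    eta <- p * (1 - p) * (mean(below[lo]) - mean(below[!lo]))^2 /
      stats::var(below)
    if (!is.finite(eta) || eta < min_eta ||
        sum(lo) < min_frac * length(values)) break
    thr <- sub
  }
  thr
}

# Label 3D connected components: EBImage::bwlabel per z-slice, merged across
# adjacent slices via igraph components. Returns an integer array (0 =
# background).
label_components_3d <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    sl <- EBImage::bwlabel(mask[, , z] * 1)
    sl <- matrix(as.integer(sl), d[1], d[2])
    sl[sl > 0L] <- sl[sl > 0L] + offset
    offset <- max(offset, if (any(sl > 0L)) max(sl) else offset)
    labs[, , z] <- sl
  }
  if (offset == 0L) return(labs)
  edges <- NULL
  for (z in seq_len(d[3] - 1)) {
    a <- labs[, , z]; b <- labs[, , z + 1]
    both <- a > 0L & b > 0L
    if (any(both)) {
      e <- unique(cbind(a[both], b[both]))
      edges <- rbind(edges, e)
    }
  }
  g <- igraph::make_empty_graph(n = offset, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  pos <- labs > 0L
  labs[pos] <- memb[labs[pos]]
  labs
}

largest_component <- function(mask) {
  labs <- label_components_3d(mask)
  if (!any(labs > 0L)) return(array(FALSE, dim(mask)))
  sizes <- tabulate(labs[labs > 0L])
  labs == which.max(sizes)
}

# Fill holes slice-by-slice along z.
fill_holes_z <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[3])) {
    filled <- EBImage::fillHull(mask[, , z] * 1)
    out[, , z] <- as.numeric(filled) > 0
  }
  out
}

#' Exact anisotropic 3D Euclidean distance transform
#'
#' Distance (in physical units) from every voxel to the nearest feature
#' voxel, computed with the separable lower-envelope algorithm, exact up to
#' floating-point rounding for any per-axis voxel spacing.
#'
#' @param mask Logical 3D array; `TRUE` marks feature voxels (distance 0).
#' @param voxel_size Numeric length-3 spacing, um per voxel.
#' @return Numeric 3D array of distances in um (`Inf` if `mask` is empty).
#' @export
distance_transform <- function(mask, voxel_size) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  voxel_size <- as.numeric(voxel_size)
  abort_if(length(voxel_size) != 3L || any(voxel_size <= 0),
           "voxel_size must be 3 positive numbers")
  d2 <- .edt3d_sq(as.logical(mask), dim(mask), voxel_size)
  array(sqrt(d2), dim(mask))
}

# Lantuejoul morphological skeleton with a 6-connected structuring element:
# union over k of erode^k(X) minus opening(erode^k(X)). Not
# homotopy-preserving, but a faithful thin-set density measure.
skeletonize_3d <- function(mask) {
  skel <- array(FALSE, dim(mask))
  ek <- mask
  while (any(ek)) {
    opened <- dilate6(erode6(ek))
    skel <- skel | (ek & !opened)
    ek <- erode6(ek)
  }
  skel
}
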