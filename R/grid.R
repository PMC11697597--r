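#' Voxel CT volume
#'
#' Container for a 3-D scalar grid in Hounsfield units. The array axes follow
#' the patient convention x: right to left, y: anterior to posterior,
#' z: inferior to superior. Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing` in world millimetres.
#'
#' @param voxels 3-D numeric array of HU values in `[-1200, 2000]`.
#' @param spacing length-3 positive numeric, mm per voxel on (x, y, z).
#'   The axial (z) spacing defaults to 2 mm slices.
#' @param origin length-3 numeric, world mm of the first voxel centre.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  rng <- range(voxels)
  if (rng[1] < -1200 - 1e-6 || rng[2] > 2000 + 1e-6)
    stop("HU values must lie within [-1200, 2000]")
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         axes = c("x: right->left", "y: anterior->posterior", "z: inferior->superior")),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$voxels), max(x$voxels), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Binary mask congruent with its parent [ct_volume()] grid.
#'
#' @param voxels logical (or 0/1) 3-D array.
#' @param name label for the structure.
#' @param spacing,origin grid geometry, as in [ct_volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, name = "roi", spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask voxels must be binary")
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  structure(list(voxels = voxels, name = name,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels, %.2f cm^3\n",
              x$name, sum(x$voxels), mask_volume_cm3(x)))
  invisible(x)
}

#' Mask volume in cm^3
#'
#' Volume is voxel count times voxel volume.
#'
#' @param mask an [roi_mask()].
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

check_congruent <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("grids are not congruent (different dimensions)")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("grids are not congruent (different spacing)")
  invisible(TRUE)
}

# World-mm coordinate vectors of voxel centres along each axis.
axis_coords <- function(vol) {
  d <- dim(vol$voxels)
  lapply(1:3, function(ax) vol$origin[ax] + (seq_len(d[ax]) - 1) * vol$spacing[ax])
}

# Integer-shift an array, zero (or `fill`) padding. d is the length-3 shift in
# voxels: out[x] = a[x - d].
shift_array <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  if (is.logical(a)) out <- array(as.logical(fill), dm)
  idx_src <- idx_dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax] - abs(d[ax])
    if (n <= 0) return(out)
    if (d[ax] >= 0) {
      idx_dst[[ax]] <- seq_len(n) + d[ax]; idx_src[[ax]] <- seq_len(n)
    } else {
      idx_dst[[ax]] <- seq_len(n); idx_src[[ax]] <- seq_len(n) - d[ax]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Integer voxel offsets within a physical ball of radius r mm.
ball_offsets <- function(radius_mm, spacing) {
  nmax <- pmax(0L, as.integer(floor(radius_mm / spacing + 1e-9)))
  g <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2], dz = -nmax[3]:nmax[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2 <=
    radius_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Binary erosion by a physical ball. Returns a logical array.
erode_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    if (all(d == 0)) next
    out <- out & shift_array(mask, -d, fill = FALSE)
  }
  out
}

# Binary dilation by a physical ball.
dilate_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    if (all(d == 0)) next
    out <- out | shift_array(mask, d, fill = FALSE)
  }
  out
}

# Trilinear sampling of a 3-D array at fractional voxel coordinates (1-based).
# pts: N x 3 matrix. Points outside the grid return `fill`.
trilinear_sample <- function(arr, pts, fill = 0) {
  dm <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  i0 <- pmin(floor(x), dm[1] - 1L); j0 <- pmin(floor(y), dm[2] - 1L)
  k0 <- pmin(floor(z), dm[3] - 1L)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  n12 <- dm[1] * dm[2]
  base <- i0 + (j0 - 1) * dm[1] + (k0 - 1) * n12
  v000 <- arr[base];               v100 <- arr[base + 1]
  v010 <- arr[base + dm[1]];       v110 <- arr[base + dm[1] + 1]
  v001 <- arr[base + n12];         v101 <- arr[base + n12 + 1]
  v011 <- arr[base + dm[1] + n12]; v111 <- arr[base + dm[1] + n12 + 1]
  val <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out[inside] <- val
  out
}

# Full voxel-centre coordinate arrays (world mm), each as a 3-D array.
coord_arrays <- function(vol) {
  d <- dim(vol$voxels)
  cc <- axis_coords(vol)
  list(
    x = array(rep(cc[[1]], times = d[2] * d[3]), d),
    y = array(rep(rep(cc[[2]], each = d[1]), times = d[3]), d),
    z = array(rep(cc[[3]], each = d[1] * d[2]), d))
}

# Separable Gaussian smoothing of a 3-D array (sigma in voxels per axis).
gaussian_smooth3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  out <- a
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    hw <- max(1L, as.integer(ceiling(2.5 * s)))
    k <- exp(-(( -hw:hw)^2) / (2 * s^2)); k <- k / sum(k)
    acc <- array(0, dim(a))
    for (t in -hw:hw) {
      d <- c(0L, 0L, 0L); d[ax] <- t
      acc <- acc + k[t + hw + 1L] * shift_array(out, d, fill = 0)
    }
    # renormalise near borders so constants stay constant
    w <- array(0, dim(a)); ones <- array(1, dim(a))
    for (t in -hw:hw) {
      d <- c(0L, 0L, 0L); d[ax] <- t
      w <- w + k[t + hw + 1L] * shift_array(ones, d, fill = 0)
    }
    out <- acc / w
  }
  out
}

# Distance (mm) from every voxel to the nearest TRUE voxel of `mask`,
# capped at `cap` mm. Iterative chamfer propagation over the 26-neighbourhood.
distance_to_mask <- function(mask, spacing, cap = 24) {
  if (!any(mask)) return(array(cap, dim(mask)))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  w <- sqrt((offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
              (offs$dz * spacing[3])^2)
  d <- array(cap, dim(mask)); d[mask] <- 0
  max_iter <- ceiling(cap / min(spacing)) + 2L
  for (it in seq_len(max_iter)) {
    d_old <- d
    for (r in seq_len(nrow(offs))) {
      d <- pmin(d, shift_array(d_old, c(offs$dx[r], offs$dy[r], offs$dz[r]),
                               fill = cap) + w[r])
    }
    if (max(abs(d - d_old)) < 1e-9) break
    d_old <- d
  }
  pmin(d, cap)
}

# Signed distance: negative inside the mask, positive outside (mm).
signed_distance <- function(mask, spacing, cap = 24) {
  distance_to_mask(mask, spacing, cap) - distance_to_mask(!mask, spacing, cap)
}
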