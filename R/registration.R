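#' Rigid transform (6 degrees of freedom)
#'
#' Translation (mm) and rotation (degrees) about the patient axes, applied as
#' `p' = Rz Ry Rx (p - center) + center + t`.
#'
#' @param translation_mm length-3 numeric.
#' @param rotation_deg length-3 numeric (about x, y, z).
#' @param center_mm centre of rotation (world mm).
#' @return list of class `rigid_transform`.
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

rigid_is_identity <- function(tr, tol = 1e-9) {
  max(abs(tr$translation_mm)) < tol && max(abs(tr$rotation_deg)) < tol
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Apply a rigid transform to an N x 3 matrix of world points.
apply_rigid_points <- function(pts, tr) {
  R <- rotation_matrix(tr$rotation_deg)
  sweep(t(R %*% t(sweep(pts, 2, tr$center_mm))), 2,
        tr$center_mm + tr$translation_mm, `+`)
}

#' Invert a rigid transform
#' @param tr a [rigid_transform()].
#' @return the inverse transform (same centre of rotation).
#' @export
rigid_invert <- function(tr) {
  R <- rotation_matrix(tr$rotation_deg)
  # p' = R (p - c) + c + t  =>  p = R^-1 (p' - c - t) + c
  # express inverse in the same parameterisation via its matrix form
  Ri <- t(R)
  # find rotation angles of Ri (ZYX Euler extraction)
  ry <- asin(-Ri[3, 1])
  rx <- atan2(Ri[3, 2], Ri[3, 3])
  rz <- atan2(Ri[2, 1], Ri[1, 1])
  t_new <- as.vector(-Ri %*% tr$translation_mm)
  rigid_transform(t_new, c(rx, ry, rz) * 180 / pi, tr$center_mm)
}

# Resample an array through a rigid transform: out(x) = arr(T(x)) for every
# voxel centre x of the same grid.
apply_rigid_to_array <- function(arr, tr, spacing, origin, fill = 0) {
  d <- dim(arr)
  vol <- list(voxels = arr, spacing = spacing, origin = origin)
  cc <- coord_arrays(vol)
  pts <- cbind(as.vector(cc$x), as.vector(cc$y), as.vector(cc$z))
  moved <- apply_rigid_points(pts, tr)
  vox <- cbind((moved[, 1] - origin[1]) / spacing[1] + 1,
               (moved[, 2] - origin[2]) / spacing[2] + 1,
               (moved[, 3] - origin[3]) / spacing[3] + 1)
  array(trilinear_sample(arr, vox, fill = fill), d)
}

#' Rigid bone matching between two CT volumes
#'
#' Six-axis (translation + rotation) registration maximising similarity on
#' bone-thresholded voxels, as used for patient positioning. Minimises the
#' mean squared HU difference over fixed-image bone voxels by Nelder-Mead
#' search, initialised at the bone-centroid offset.
#'
#' @param fixed,moving [ct_volume()] objects containing bone (HU >= 200).
#' @param bone_hu bone threshold.
#' @param n_sample maximum number of bone voxels used.
#' @return the recovered [rigid_transform()] mapping fixed to moving
#'   coordinates.
#' @export
rigid_bone_match <- function(fixed, moving, bone_hu = 200, n_sample = 4000) {
  fb <- fixed$voxels >= bone_hu
  mb <- moving$voxels >= bone_hu
  if (!any(fb) || !any(mb)) stop("no bone voxels above threshold")
  fs <- gaussian_smooth3(fixed$voxels, 1)
  ms <- gaussian_smooth3(moving$voxels, 1)
  # include a one-voxel shell so the edges constrain the match
  fb_d <- fb | shift_array(fb, c(1, 0, 0), FALSE) | shift_array(fb, c(-1, 0, 0), FALSE) |
    shift_array(fb, c(0, 1, 0), FALSE) | shift_array(fb, c(0, -1, 0), FALSE) |
    shift_array(fb, c(0, 0, 1), FALSE) | shift_array(fb, c(0, 0, -1), FALSE)
  idx <- which(fb_d, arr.ind = TRUE)
  if (nrow(idx) > n_sample)
    idx <- idx[seq(1, nrow(idx), length.out = n_sample), , drop = FALSE]
  sp <- fixed$spacing; org <- fixed$origin
  pts <- sweep(sweep(idx - 1, 2, sp, `*`), 2, org, `+`)
  vals_f <- fs[idx]
  cfix <- colMeans(sweep(sweep(which(fb, arr.ind = TRUE) - 1, 2, sp, `*`), 2, org, `+`))
  cmov <- colMeans(sweep(sweep(which(mb, arr.ind = TRUE) - 1, 2, moving$spacing, `*`),
                         2, moving$origin, `+`))
  obj <- function(p) {
    tr <- rigid_transform(p[1:3], p[4:6], cfix)
    moved <- apply_rigid_points(pts, tr)
    vox <- cbind((moved[, 1] - moving$origin[1]) / moving$spacing[1] + 1,
                 (moved[, 2] - moving$origin[2]) / moving$spacing[2] + 1,
                 (moved[, 3] - moving$origin[3]) / moving$spacing[3] + 1)
    v <- trilinear_sample(ms, vox, fill = -1000)
    mean((v - vals_f)^2)
  }
  p0 <- c(cmov - cfix, 0, 0, 0)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1200, reltol = 1e-12))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 600, reltol = 1e-12))
  rigid_transform(fit2$par[1:3], fit2$par[4:6], cfix)
}

downsample2 <- function(a) {
  d <- dim(a)
  a[seq(1, d[1], by = 2), seq(2, d[2], by = 2) - 1, seq(2, d[3], by = 2) - 1]
}

# gradient by central differences (per voxel units)
grad3 <- function(a) {
  list(
    x = (shift_array(a, c(-1, 0, 0), 0) - shift_array(a, c(1, 0, 0), 0)) / 2,
    y = (shift_array(a, c(0, -1, 0), 0) - shift_array(a, c(0, 1, 0), 0)) / 2,
    z = (shift_array(a, c(0, 0, -1), 0) - shift_array(a, c(0, 0, 1), 0)) / 2)
}

#' Deformable registration (demons with structure guidance)
#'
#' Multiresolution demons-style intensity registration with an optional
#' structure term: for each supplied mask pair, signed-distance maps are
#' matched as an extra image channel, emulating a hybrid intensity- and
#' structure-based algorithm. Returns the displacement field on the fixed
#' grid, mapping fixed (planning CT) points to moving (gas CT) points.
#'
#' Regions with no true correspondence (newly appeared gas) are handled by
#' the structure term, which dominates by default.
#'
#' @param fixed,moving [ct_volume()] objects on congruent grids (rigidly
#'   aligned already).
#' @param structures optional list of pairs: each element
#'   `list(fixed = roi_mask, moving = roi_mask)`.
#' @param ground_truth optional `dvf`: when given, it is returned unchanged
#'   (ground-truth bypass mode, decoupling downstream dose conclusions from
#'   registration quality).
#' @param control list: `iter_coarse`, `iter_fine`, `w_intensity`, `w_struct`,
#'   `smooth_sigma` (voxels), `max_step` (voxels/iteration).
#' @return object of class `dvf`: `field` (x,y,z,3 mm), grid geometry, and a
#'   `quality` attribute with the residual trace.
#' @export
deformable_register <- function(fixed, moving, structures = NULL,
                                ground_truth = NULL, control = list()) {
  if (!is.null(ground_truth)) {
    stopifnot(inherits(ground_truth, "dvf"))
    return(ground_truth)
  }
  check_congruent(fixed, moving)
  ctrl <- utils::modifyList(list(iter_coarse = 60, iter_fine = 25,
                                 w_intensity = 0.3, w_struct = 1,
                                 smooth_sigma = 1.2, max_step = 0.45,
                                 sdf_cap = 16), control)
  sp <- fixed$spacing
  chan_f <- list(fixed$voxels / 400)
  chan_m <- list(moving$voxels / 400)
  wts <- ctrl$w_intensity
  if (!is.null(structures)) {
    for (prm in structures) {
      chan_f <- c(chan_f, list(signed_distance(prm$fixed$voxels, sp, ctrl$sdf_cap) / 4))
      chan_m <- c(chan_m, list(signed_distance(prm$moving$voxels, sp, ctrl$sdf_cap) / 4))
      wts <- c(wts, ctrl$w_struct)
    }
  }
  run_level <- function(cf, cm, spacing, u, iters) {
    d <- dim(cf[[1]])
    grads <- lapply(cm, grad3)
    cc <- coord_arrays(list(voxels = cf[[1]], spacing = spacing, origin = c(0, 0, 0)))
    base <- cbind(as.vector(cc$x) / spacing[1] + 1,
                  as.vector(cc$y) / spacing[2] + 1,
                  as.vector(cc$z) / spacing[3] + 1)
    resid_trace <- numeric(iters)
    for (it in seq_len(iters)) {
      pts <- base + cbind(as.vector(u[, , , 1]) / spacing[1],
                          as.vector(u[, , , 2]) / spacing[2],
                          as.vector(u[, , , 3]) / spacing[3])
      # border-replicate sampling: clamping avoids spurious residuals where
      # a displaced sample would leave the volume
      for (ax in 1:3) pts[, ax] <- pmin(pmax(pts[, ax], 1), d[ax])
      dux <- array(0, d); duy <- array(0, d); duz <- array(0, d)
      rtot <- 0
      for (ci in seq_along(cf)) {
        Mw <- array(trilinear_sample(cm[[ci]], pts, fill = 0), d)
        gx <- array(trilinear_sample(grads[[ci]]$x, pts, fill = 0), d) / spacing[1]
        gy <- array(trilinear_sample(grads[[ci]]$y, pts, fill = 0), d) / spacing[2]
        gz <- array(trilinear_sample(grads[[ci]]$z, pts, fill = 0), d) / spacing[3]
        r <- Mw - cf[[ci]]
        rtot <- rtot + wts[ci] * mean(r^2)
        g2 <- gx^2 + gy^2 + gz^2
        denom <- g2 + r^2 + 1e-8
        f <- -r / denom
        dux <- dux + wts[ci] * f * gx
        duy <- duy + wts[ci] * f * gy
        duz <- duz + wts[ci] * f * gz
      }
      resid_trace[it] <- rtot
      # limit the per-iteration step (voxels)
      mag <- sqrt(dux^2 + duy^2 + duz^2)
      sc <- pmin(1, ctrl$max_step / pmax(mag / min(spacing), 1e-9))
      dux <- dux * sc; duy <- duy * sc; duz <- duz * sc
      u[, , , 1] <- gaussian_smooth3(u[, , , 1] + dux, ctrl$smooth_sigma)
      u[, , , 2] <- gaussian_smooth3(u[, , , 2] + duy, ctrl$smooth_sigma)
      u[, , , 3] <- gaussian_smooth3(u[, , , 3] + duz, ctrl$smooth_sigma)
    }
    list(u = u, trace = resid_trace)
  }
  # coarse level (factor 2)
  cf2 <- lapply(chan_f, function(a) downsample2(gaussian_smooth3(a, 1)))
  cm2 <- lapply(chan_m, function(a) downsample2(gaussian_smooth3(a, 1)))
  d2 <- dim(cf2[[1]])
  u2 <- array(0, c(d2, 3))
  lvl2 <- run_level(cf2, cm2, sp * 2, u2, ctrl$iter_coarse)
  if (ctrl$iter_coarse > 4 &&
      mean(utils::tail(lvl2$trace, 3)) > lvl2$trace[1] * 1.05)
    stop("deformable registration diverged at the coarse level; residuals: ",
         paste(signif(lvl2$trace[c(1, length(lvl2$trace))], 4), collapse = " -> "))
  # upsample the field to full resolution
  d1 <- dim(chan_f[[1]])
  u1 <- array(0, c(d1, 3))
  cc1 <- coord_arrays(list(voxels = chan_f[[1]], spacing = sp, origin = c(0, 0, 0)))
  pts_c <- cbind(as.vector(cc1$x) / (2 * sp[1]) + 1,
                 as.vector(cc1$y) / (2 * sp[2]) + 1,
                 as.vector(cc1$z) / (2 * sp[3]) + 1)
  for (k in 1:3)
    u1[, , , k] <- array(trilinear_sample(lvl2$u[, , , k], pts_c, fill = 0), d1)
  lvl1 <- run_level(chan_f, chan_m, sp, u1, ctrl$iter_fine)
  if (ctrl$iter_fine > 4 &&
      mean(utils::tail(lvl1$trace, 3)) > lvl1$trace[1] * 1.05)
    stop("deformable registration diverged at the fine level; residuals: ",
         paste(signif(lvl1$trace[c(1, length(lvl1$trace))], 4), collapse = " -> "))
  out <- structure(list(field = lvl1$u, spacing = sp, origin = fixed$origin),
                   class = "dvf")
  attr(out, "quality") <- list(coarse = lvl2$trace, fine = lvl1$trace)
  out
}

#' @export
print.dvf <- function(x, ...) {
  mag <- sqrt(x$field[, , , 1]^2 + x$field[, , , 2]^2 + x$field[, , , 3]^2)
  cat(sprintf("<dvf> %s voxels, |u| max %.2f mm, mean %.3f mm\n",
              paste(dim(x$field)[1:3], collapse = " x "), max(mag), mean(mag)))
  invisible(x)
}

#' Warp a dose grid through a displacement field
#'
#' Pull-back sampling: `warped(v) = dose(v + DVF(v))` with trilinear
#' interpolation; samples outside the dose grid are 0. The DVF lives on the
#' fixed (planning) grid and maps to the moving (gas CT) frame, so this
#' brings a gas-CT dose onto the planning CT.
#'
#' @param dose a [dose_grid()] (on the moving grid).
#' @param dvf a `dvf` (on the fixed grid).
#' @return warped [dose_grid()] on the fixed grid.
#' @export
warp_dose <- function(dose, dvf) {
  if (!identical(dim(dose$dose), dim(dvf$field)[1:3]))
    stop("dose and DVF grids do not match")
  d <- dim(dose$dose)
  vol <- list(voxels = dose$dose, spacing = dvf$spacing, origin = dvf$origin)
  cc <- coord_arrays(vol)
  pts <- cbind((as.vector(cc$x + dvf$field[, , , 1]) - dose$origin[1]) / dose$spacing[1] + 1,
               (as.vector(cc$y + dvf$field[, , , 2]) - dose$origin[2]) / dose$spacing[2] + 1,
               (as.vector(cc$z + dvf$field[, , , 3]) - dose$origin[3]) / dose$spacing[3] + 1)
  warped <- array(trilinear_sample(dose$dose, pts, fill = 0), d)
  dose_grid(warped, dvf$spacing, dvf$origin, dose$label, dose$per)
}

# Warp a binary mask the same way (threshold 0.5).
warp_mask <- function(mask, dvf) {
  g <- warp_dose(dose_grid(mask$voxels + 0, mask$spacing, mask$origin), dvf)
  roi_mask(g$dose >= 0.5, mask$name, mask$spacing, mask$origin)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1.0 when both masks are empty.
#'
#' @param a,b congruent [roi_mask()] objects.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_congruent(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1.0)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

surface_voxels <- function(mask) {
  core <- mask &
    shift_array(mask, c(1, 0, 0), FALSE) & shift_array(mask, c(-1, 0, 0), FALSE) &
    shift_array(mask, c(0, 1, 0), FALSE) & shift_array(mask, c(0, -1, 0), FALSE) &
    shift_array(mask, c(0, 0, 1), FALSE) & shift_array(mask, c(0, 0, -1), FALSE)
  mask & !core
}

directed_hd <- function(pa, pb) {
  # max over points of pa of the distance to the nearest point of pb
  worst <- 0
  chunk <- 400
  for (i0 in seq(1, nrow(pa), by = chunk)) {
    i1 <- min(i0 + chunk - 1, nrow(pa))
    d2 <- outer(pa[i0:i1, 1], pb[, 1], `-`)^2 +
      outer(pa[i0:i1, 2], pb[, 2], `-`)^2 +
      outer(pa[i0:i1, 3], pb[, 3], `-`)^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}

#' Hausdorff distance between two masks
#'
#' Symmetric maximum of directed max-min distances between surface-voxel
#' centres, in mm.
#'
#' @param a,b congruent nonempty [roi_mask()] objects.
#' @return distance in mm.
#' @export
hausdorff <- function(a, b) {
  check_congruent(a, b)
  if (!any(a$voxels) || !any(b$voxels)) stop("hausdorff requires nonempty masks")
  sa <- which(surface_voxels(a$voxels), arr.ind = TRUE)
  sb <- which(surface_voxels(b$voxels), arr.ind = TRUE)
  pa <- sweep(sweep(sa - 1, 2, a$spacing, `*`), 2, a$origin, `+`)
  pb <- sweep(sweep(sb - 1, 2, b$spacing, `*`), 2, b$origin, `+`)
  max(directed_hd(pa, pb), directed_hd(pb, pa))
}
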