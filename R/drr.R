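#' DRR projection geometry
#'
#' Parallel-ray projection about the superior-inferior axis. Angle 0 views
#' from anterior (rays travel anterior to posterior); the oblique kV imager
#' angles default to 35 and 325 degrees. The image plane axes are u
#' (transverse in-plane) and v (SI, inherited from the CT slice spacing).
#'
#' @param angle_deg projection angle in `[0, 360)`.
#' @param pixel_spacing_mm in-plane pixel spacing (mm).
#' @param step_mm ray-integration step (mm).
#' @return list of class `drr_geometry`.
#' @export
drr_geometry <- function(angle_deg = 35, pixel_spacing_mm = 1, step_mm = 2) {
  if (angle_deg < 0 || angle_deg >= 360) stop("angle must be in [0, 360)")
  if (pixel_spacing_mm <= 0) stop("pixel spacing must be positive")
  structure(list(angle_deg = angle_deg, pixel_spacing_mm = pixel_spacing_mm,
                 step_mm = step_mm), class = "drr_geometry")
}

# Sample points of all rays: returns list(u_mm, v_mm, and the function that
# integrates a 3-D array along the rays).
ray_integrator <- function(vol_dim, spacing, origin, geom) {
  th <- geom$angle_deg * pi / 180
  dir2 <- c(-sin(th), cos(th))      # ray direction, in-plane
  eu <- c(cos(th), sin(th))         # image u axis, in-plane
  ext <- (vol_dim - 1) * spacing
  cx <- origin[1] + ext[1] / 2; cy <- origin[2] + ext[2] / 2
  half <- sqrt(ext[1]^2 + ext[2]^2) / 2 + geom$step_mm
  u_mm <- seq(-half, half, by = geom$pixel_spacing_mm)
  v_mm <- origin[3] + (seq_len(vol_dim[3]) - 1) * spacing[3]
  t_mm <- seq(-half, half, by = geom$step_mm)
  nu <- length(u_mm); nv <- length(v_mm); nt <- length(t_mm)
  # in-plane sample coordinates for each (u, t)
  px <- outer(u_mm * eu[1], t_mm * dir2[1], `+`) + cx  # nu x nt
  py <- outer(u_mm * eu[2], t_mm * dir2[2], `+`) + cy
  ix <- (px - origin[1]) / spacing[1] + 1
  iy <- (py - origin[2]) / spacing[2] + 1
  integrate_fun <- function(arr, reduce = c("sum", "max")) {
    reduce <- match.arg(reduce)
    out <- matrix(0, nu, nv)
    for (k in seq_len(nv)) {
      pts <- cbind(as.vector(ix), as.vector(iy), rep(k, nu * nt))
      vals <- matrix(trilinear_sample(arr, pts, fill = 0), nu, nt)
      out[, k] <- if (reduce == "sum") rowSums(vals) * geom$step_mm
      else apply(vals, 1, max)
    }
    out
  }
  list(u_mm = u_mm, v_mm = v_mm, integrate = integrate_fun)
}

#' Project a CT volume to a DRR
#'
#' Parallel-ray line integral of the attenuation proxy
#' `mu = max(HU + 1000, 0) / 1000` (water 1, air 0) along the configured
#' oblique direction.
#'
#' @param ct a [ct_volume()].
#' @param geom a [drr_geometry()].
#' @return list of class `drr_image`: `pixels` (u x v matrix), `u_mm`,
#'   `v_mm`, `geom`.
#' @export
project_drr <- function(ct, geom = drr_geometry()) {
  if (length(ct$voxels) == 0) stop("empty volume")
  mu <- pmax(ct$voxels + 1000, 0) / 1000
  ri <- ray_integrator(dim(ct$voxels), ct$spacing, ct$origin, geom)
  structure(list(pixels = ri$integrate(mu, "sum"), u_mm = ri$u_mm,
                 v_mm = ri$v_mm, geom = geom), class = "drr_image")
}

#' Project an ROI mask onto the DRR plane
#'
#' Binary shadow: a pixel is set where its ray intersects the mask.
#'
#' @param mask an [roi_mask()].
#' @param geom a [drr_geometry()].
#' @param source optional label of the source CT (pCT or gasCT).
#' @return list of class `projected_roi`: logical `pixels`, `u_mm`, `v_mm`,
#'   `name`, `source`.
#' @export
project_roi <- function(mask, geom = drr_geometry(), source = "pCT") {
  ri <- ray_integrator(dim(mask$voxels), mask$spacing, mask$origin, geom)
  shadow <- ri$integrate(mask$voxels + 0, "max") >= 0.3
  structure(list(pixels = shadow, u_mm = ri$u_mm, v_mm = ri$v_mm,
                 name = mask$name, source = source, geom = geom),
            class = "projected_roi")
}

#' Extract the projected gas area from the gas CT
#'
#' Projects the voxel set with HU inside the gas window (default -1200 to
#' -120) restricted to the gas-CT rectum, giving the binary `Gas_area`
#' shadow on the DRR plane.
#'
#' @param gas_ct gas [ct_volume()].
#' @param rectum_gasct rectum mask on the gas CT.
#' @param geom a [drr_geometry()].
#' @param hu_window length-2 HU window.
#' @return a `projected_roi` named `Gas_area`.
#' @export
extract_gas_area <- function(gas_ct, rectum_gasct, geom = drr_geometry(),
                             hu_window = c(-1200, -120)) {
  if (hu_window[1] > hu_window[2]) stop("inverted HU window")
  if (!identical(dim(gas_ct$voxels), dim(rectum_gasct$voxels)))
    stop("grids are not congruent")
  vox <- gas_ct$voxels >= hu_window[1] & gas_ct$voxels <= hu_window[2] &
    rectum_gasct$voxels
  m <- roi_mask(vox, "Gas_area", gas_ct$spacing, gas_ct$origin)
  out <- project_roi(m, geom, source = "gasCT")
  out$name <- "Gas_area"
  out
}

#' Gas indicators from projected ROIs
#'
#' Three scalar indicators measured on one DRR:
#' * `drr_gas_si`: SI extent (cm) of the gas shadow restricted to the SI span
#'   of the projected PTV;
#' * `drr_gas_side`: maximum transverse (in-plane, perpendicular to SI)
#'   distance (cm) by which gas pixels inside the projected PTV extend
#'   outside the projected rectum;
#' * `drr_gas_area`: their product (cm^2), exactly.
#'
#' All three are zero when the gas shadow does not meet the PTV.
#'
#' @param gas_area `projected_roi` of the gas (from the gas CT).
#' @param ptv_proj,rectum_proj `projected_roi` of PTV and rectum (from the
#'   planning CT), on the same DRR grid.
#' @return list of class `gas_indicators`: `drr_gas_si`, `drr_gas_side`,
#'   `drr_gas_area` (cm / cm / cm^2), `angle_deg`.
#' @export
compute_indicators <- function(gas_area, ptv_proj, rectum_proj) {
  stopifnot(identical(dim(gas_area$pixels), dim(ptv_proj$pixels)),
            identical(dim(gas_area$pixels), dim(rectum_proj$pixels)))
  v_mm <- gas_area$v_mm; u_mm <- gas_area$u_mm
  v_pix <- if (length(v_mm) > 1) v_mm[2] - v_mm[1] else 1
  zero <- structure(list(drr_gas_si = 0, drr_gas_side = 0, drr_gas_area = 0,
                         angle_deg = gas_area$geom$angle_deg),
                    class = "gas_indicators")
  if (!any(ptv_proj$pixels) || !any(gas_area$pixels)) return(zero)
  ptv_rows <- which(apply(ptv_proj$pixels, 2, any))
  v_span <- range(v_mm[ptv_rows])
  gas_in_span <- gas_area$pixels &
    matrix(rep(v_mm >= v_span[1] & v_mm <= v_span[2], each = length(u_mm)),
           length(u_mm), length(v_mm))
  if (!any(gas_in_span)) return(zero)
  rows_gas <- which(apply(gas_in_span, 2, any))
  si_cm <- (diff(range(v_mm[rows_gas])) + v_pix) / 10
  # transverse overreach of gas (inside the PTV shadow) beyond the rectum shadow
  overlap <- gas_area$pixels & ptv_proj$pixels
  side_mm <- 0
  for (k in which(apply(overlap, 2, any))) {
    ur <- u_mm[rectum_proj$pixels[, k]]
    ug <- u_mm[overlap[, k] & !rectum_proj$pixels[, k]]
    if (!length(ug)) next
    if (!length(ur)) next
    d <- vapply(ug, function(u) min(abs(u - ur)), 0)
    side_mm <- max(side_mm, max(d))
  }
  side_cm <- side_mm / 10
  structure(list(drr_gas_si = si_cm, drr_gas_side = side_cm,
                 drr_gas_area = si_cm * side_cm,
                 angle_deg = gas_area$geom$angle_deg),
            class = "gas_indicators")
}

#' @export
print.gas_indicators <- function(x, ...) {
  cat(sprintf("<gas_indicators> angle %g deg: SI %.2f cm, side %.2f cm, area %.2f cm^2\n",
              x$angle_deg, x$drr_gas_si, x$drr_gas_side, x$drr_gas_area))
  invisible(x)
}
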