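#' Phantom specification
#'
#' Geometry and HU parameters for the synthetic pelvic phantom. The phantom is
#' deliberately simplified (ellipsoidal prostate and seminal-vesicle base, a
#' cylindrical rectum abutting the prostate posteriorly, femoral heads, pubic
#' bar and sacrum as bone) so that every derived structure has an analytic
#' volume oracle. All lengths in mm, HU means as in a 120-kV pelvic CT.
#'
#' @param shape grid dimensions (x, y, z) in voxels.
#' @param spacing voxel spacing mm; 2-mm axial slices by default.
#' @param prostate_center,prostate_radii ellipsoid centre / semi-axes (mm).
#' @param sv_radii semi-axes of the seminal-vesicle-base bump included in the
#'   CTV (set to `c(0,0,0)` to omit it).
#' @param sv_offset centre offset of the bump relative to the prostate centre.
#' @param rectum_radius outer radius of the rectal tube (mm).
#' @param rectum_z z-range (mm) of the anatomical rectal tube before cropping.
#' @param hu named HU means: soft tissue, prostate, rectum lumen contents,
#'   bone, air.
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param jitter_frac cohort-level fractional jitter on organ radii (applied
#'   per seed), and `jitter_mm` absolute jitter on centres.
#' @param jitter_mm see above.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 56),
                         spacing = c(2, 2, 2),
                         prostate_center = c(63, 58, 42),
                         prostate_radii = c(22, 20, 20),
                         sv_radii = c(14, 9, 8),
                         sv_offset = c(0, 8, 22),
                         rectum_radius = 11,
                         rectum_z = c(6, 104),
                         hu = c(soft = 40, prostate = 45, lumen = 0,
                                bone = 700, air = -1000),
                         noise_sd = 15,
                         jitter_frac = 0.08,
                         jitter_mm = 2) {
  if (any(prostate_radii <= 0) || rectum_radius <= 0)
    stop("organ radii must be positive")
  ext <- (shape - 1) * spacing
  if (any(prostate_center + prostate_radii > ext) || any(prostate_center - prostate_radii < 0))
    stop("grid too small to contain the prostate")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 prostate_center = prostate_center, prostate_radii = prostate_radii,
                 sv_radii = sv_radii, sv_offset = sv_offset,
                 rectum_radius = rectum_radius, rectum_z = rectum_z,
                 hu = hu, noise_sd = noise_sd,
                 jitter_frac = jitter_frac, jitter_mm = jitter_mm),
            class = "phantom_spec")
}

#' Gas-pocket specification
#'
#' Parameters of the inserted rectal gas pocket and the cohort-scale
#' distribution it is drawn from. The cohort mean/SD default to the bulky-gas
#' volume statistics observed on gas-session CTs (17.54 +/- 11.10 cm^3);
#' session-to-session variability defaults reflect a mean volume variation of
#' about 2.9 cm^3 and positional reproducibility within 5 mm.
#'
#' @param target_volume_cm3 requested pocket volume for a single insertion.
#' @param cohort_mean_cm3,cohort_sd_cm3 gamma-distribution moments used by
#'   [sample_gas_volumes()].
#' @param location_bias named weights for the pocket centre position along the
#'   rectum (superior-dominant by default).
#' @param gas_hu HU assigned inside the pocket; must lie in `[-1200, -120]`.
#' @param distension_mm peak radial distension of the rectal wall (mm).
#' @param fraction_volume_sd_cm3,fraction_shift_mm per-fraction variability
#'   (used by the optional gas-variability mode).
#' @param rescan_noise_sd additional HU noise on the rescanned (gas) CT.
#' @param z_offset_mm deterministic shift of the pocket centre along the
#'   rectum (used by the per-fraction variability option).
#' @return A list of class `gas_spec`.
#' @export
gas_spec <- function(target_volume_cm3 = 17.54,
                     cohort_mean_cm3 = 17.54,
                     cohort_sd_cm3 = 11.10,
                     location_bias = c(superior = 0.75, middle = 0.20, inferior = 0.05),
                     gas_hu = -1000,
                     distension_mm = 3.5,
                     fraction_volume_sd_cm3 = 2.9,
                     fraction_shift_mm = 2.5,
                     rescan_noise_sd = 5,
                     z_offset_mm = 0) {
  if (gas_hu < -1200 || gas_hu > -120)
    stop("gas_hu must lie within [-1200, -120]")
  if (target_volume_cm3 < 0) stop("gas volumes must be non-negative")
  structure(list(target_volume_cm3 = target_volume_cm3,
                 cohort_mean_cm3 = cohort_mean_cm3, cohort_sd_cm3 = cohort_sd_cm3,
                 location_bias = location_bias / sum(location_bias),
                 gas_hu = gas_hu, distension_mm = distension_mm,
                 fraction_volume_sd_cm3 = fraction_volume_sd_cm3,
                 fraction_shift_mm = fraction_shift_mm,
                 rescan_noise_sd = rescan_noise_sd,
                 z_offset_mm = z_offset_mm),
            class = "gas_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipsoid_mask <- function(cc, center, radii) {
  radii <- pmax(radii, 1e-9)
  ((cc$x - center[1]) / radii[1])^2 + ((cc$y - center[2]) / radii[2])^2 +
    ((cc$z - center[3]) / radii[3])^2 <= 1
}

#' Generate a gas-free planning phantom
#'
#' Builds the planning CT (pCT) and its structure set: CTV (prostate plus
#' seminal-vesicle base), rectum cropped 14 mm beyond the CTV ends, 2-mm inner
#' rectal-wall ring, PTV with right/left/anterior margins, and an empty gas
#' mask. Deterministic for a given `(spec, seed)` pair; the seed drives both
#' the HU noise field and the cohort-level geometry jitter.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param ptv_margins_mm named margins passed to [expand_ptv()].
#' @param crop_margin_mm rectum crop margin beyond the CTV z-span (mm).
#' @param wall_thickness_mm rectal-wall ring thickness (mm).
#' @return list with elements `ct` ([ct_volume()]) and `structures`
#'   (class `structure_set`: `ctv`, `ptv`, `rectum`, `rectal_wall`, `gas`),
#'   plus the jittered geometry in `geometry`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1,
                             ptv_margins_mm = c(right = 5, left = 5, anterior = 5,
                                                posterior = 0, inferior = 0, superior = 0),
                             crop_margin_mm = 14, wall_thickness_mm = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(as.integer(seed), {
    d <- spec$shape; sp <- spec$spacing
    vol0 <- ct_volume(array(0, d), spacing = sp)
    cc <- coord_arrays(vol0)
    ext <- (d - 1) * sp

    jf <- spec$jitter_frac; jm <- spec$jitter_mm
    pr <- spec$prostate_radii * (1 + stats::runif(3, -jf, jf))
    pc <- spec$prostate_center + stats::runif(3, -jm, jm)
    rr <- spec$rectum_radius * (1 + stats::runif(1, -jf, jf))
    svr <- spec$sv_radii * (1 + stats::runif(3, -jf, jf))

    body <- ((cc$x - ext[1] / 2) / (0.46 * ext[1]))^2 +
      ((cc$y - ext[2] / 2) / (0.37 * ext[2]))^2 <= 1

    prostate <- ellipsoid_mask(cc, pc, pr)
    sv <- if (all(spec$sv_radii > 0))
      ellipsoid_mask(cc, pc + spec$sv_offset, svr) else array(FALSE, d)
    ctv_vox <- prostate | sv

    # rectal tube abutting the prostate posteriorly
    rect_center_y <- pc[2] + pr[2] + rr
    rect_axis <- c(pc[1], rect_center_y)
    rect_tube <- (cc$x - rect_axis[1])^2 + (cc$y - rect_axis[2])^2 <= rr^2 &
      cc$z >= spec$rectum_z[1] & cc$z <= spec$rectum_z[2]
    lumen <- (cc$x - rect_axis[1])^2 + (cc$y - rect_axis[2])^2 <= (0.6 * rr)^2 &
      rect_tube

    # bone: femoral heads, pubic bar, sacrum
    fem1 <- ellipsoid_mask(cc, c(pc[1] - 42, pc[2], pc[3]), c(13, 13, 13))
    fem2 <- ellipsoid_mask(cc, c(pc[1] + 42, pc[2], pc[3]), c(13, 13, 13))
    pubic <- abs(cc$x - pc[1]) <= 18 & cc$y >= pc[2] - 34 & cc$y <= pc[2] - 26 &
      abs(cc$z - pc[3]) <= 8
    sacrum <- abs(cc$x - pc[1]) <= 16 & cc$y >= rect_center_y + rr + 6 &
      cc$y <= rect_center_y + rr + 16 & cc$z >= pc[3] - 20 & cc$z <= pc[3] + 44
    bone <- (fem1 | fem2 | pubic | sacrum) & body

    hu <- array(spec$hu[["air"]], d)
    hu[body] <- spec$hu[["soft"]]
    hu[lumen] <- spec$hu[["lumen"]]
    hu[prostate] <- spec$hu[["prostate"]]
    hu[bone] <- spec$hu[["bone"]]
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
    hu <- pmin(pmax(hu, -1100), 1500)
    ct <- ct_volume(array(hu, d), spacing = sp)

    ctv <- roi_mask(ctv_vox, "ctv", sp)
    rectum_full <- roi_mask(rect_tube, "rectum", sp)
    rectum <- crop_rectum_to_ctv(rectum_full, ctv, margin_mm = crop_margin_mm)
    wall <- derive_rectal_wall(rectum, thickness_mm = wall_thickness_mm)
    ptv <- expand_ptv(ctv, margins_mm = ptv_margins_mm)
    gas <- roi_mask(array(FALSE, d), "gas", sp)

    structures <- structure(list(ctv = ctv, ptv = ptv, rectum = rectum,
                                 rectal_wall = wall, gas = gas),
                            class = "structure_set")
    list(ct = ct, structures = structures,
         geometry = list(prostate_center = pc, prostate_radii = pr,
                         rectum_axis = rect_axis, rectum_radius = rr))
  })
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %8.2f cm^3\n", nm, mask_volume_cm3(x[[nm]])))
  invisible(x)
}

#' Derive the inner rectal-wall ring
#'
#' The wall is the rectum minus the rectum eroded by a physical ball of
#' `thickness_mm`. If the erosion empties the rectum entirely (a structure
#' thinner than twice the thickness), the wall equals the rectum and a warning
#' is raised.
#'
#' @param rectum an [roi_mask()].
#' @param thickness_mm ring thickness in mm (default 2).
#' @return wall [roi_mask()], a subset of `rectum`.
#' @export
derive_rectal_wall <- function(rectum, thickness_mm = 2) {
  if (!any(rectum$voxels)) stop("rectum mask is empty")
  if (thickness_mm <= 0)
    return(roi_mask(array(FALSE, dim(rectum$voxels)), "rectal_wall",
                    rectum$spacing, rectum$origin))
  core <- erode_ball(rectum$voxels, thickness_mm, rectum$spacing)
  wall <- rectum$voxels & !core
  if (!any(core)) {
    warning("erosion emptied the rectum; wall set equal to the rectum")
    wall <- rectum$voxels
  }
  roi_mask(wall, "rectal_wall", rectum$spacing, rectum$origin)
}

#' Crop the rectum to the CTV z-span plus a margin
#'
#' Keeps axial slices whose centres lie between `margin_mm` inferior to the
#' CTV bottom and `margin_mm` superior to the CTV top (14 mm by default).
#'
#' @param rectum,ctv congruent [roi_mask()] objects.
#' @param margin_mm superior/inferior margin (mm).
#' @return cropped rectum [roi_mask()].
#' @export
crop_rectum_to_ctv <- function(rectum, ctv, margin_mm = 14) {
  check_congruent(rectum, ctv)
  if (!any(rectum$voxels) || !any(ctv$voxels)) stop("masks must be nonempty")
  d <- dim(ctv$voxels)
  zc <- ctv$origin[3] + (seq_len(d[3]) - 1) * ctv$spacing[3]
  has_ctv <- apply(ctv$voxels, 3, any)
  span <- range(zc[has_ctv]) + c(-margin_mm, margin_mm)
  keep <- zc >= span[1] - 1e-9 & zc <= span[2] + 1e-9
  out <- rectum$voxels
  out[, , !keep] <- FALSE
  if (!any(out)) stop("crop produced an empty rectum")
  roi_mask(out, rectum$name, rectum$spacing, rectum$origin)
}

#' Expand the CTV to a PTV with anisotropic margins
#'
#' Directional dilation: each named margin extends the structure in one
#' patient direction only. Margins are quantised to whole voxels
#' (`round(margin / spacing)`).
#'
#' @param ctv an [roi_mask()].
#' @param margins_mm named vector with entries `right`, `left`, `anterior`,
#'   `posterior`, `inferior`, `superior` (missing entries default to 0).
#' @return PTV [roi_mask()], a superset of the CTV.
#' @export
expand_ptv <- function(ctv, margins_mm = c(right = 5, left = 5, anterior = 5)) {
  if (!any(ctv$voxels)) stop("CTV mask is empty")
  if (any(margins_mm < 0)) stop("margins must be non-negative")
  full <- c(right = 0, left = 0, anterior = 0, posterior = 0,
            inferior = 0, superior = 0)
  full[names(margins_mm)] <- margins_mm
  # patient axes: right = -x, left = +x, anterior = -y, posterior = +y,
  # inferior = -z, superior = +z
  dirs <- list(right = c(-1, 0, 0), left = c(1, 0, 0),
               anterior = c(0, -1, 0), posterior = c(0, 1, 0),
               inferior = c(0, 0, -1), superior = c(0, 0, 1))
  out <- ctv$voxels
  for (nm in names(dirs)) {
    dvec <- dirs[[nm]]
    sp_ax <- ctv$spacing[which(dvec != 0)]
    n <- as.integer(round(full[[nm]] / sp_ax))
    if (n < 1) next
    for (s in seq_len(n)) out <- out | shift_array(ctv$voxels, dvec * s, fill = FALSE)
  }
  roi_mask(out, "ptv", ctv$spacing, ctv$origin)
}

# Analytic displacement of the gas deformation model: radial in-plane push
# away from the rectal axis, with an in-plane bump profile peaking at the
# rectal radius and a Gaussian z envelope centred on the pocket.
gas_displacement <- function(x, y, z, axis_xy, zc, r0, amp, sigma_z) {
  dx <- x - axis_xy[1]; dy <- y - axis_xy[2]
  r <- sqrt(dx^2 + dy^2)
  prof <- (r / r0) * exp((1 - (r / r0)^2) / 2)
  envz <- exp(-(z - zc)^2 / (2 * sigma_z^2))
  mag <- amp * prof * envz
  safe_r <- pmax(r, 1e-9)
  list(ux = mag * dx / safe_r, uy = mag * dy / safe_r, uz = 0 * mag)
}

#' Insert a rectal gas pocket into a planning phantom
#'
#' Distends the rectum with a smooth, analytically known radial deformation
#' centred on a gas pocket whose position along the rectum follows the
#' configured location bias (superior-weighted by default). The gas CT is the
#' planning CT pulled back through the deformation, with the pocket painted at
#' the gas HU; the exact displacement field used is returned, so registration
#' and dose-warping accuracy can be judged against ground truth.
#'
#' The pocket is an ellipsoid carved inside the distended rectum; its axial
#' half-length is solved by bisection so the carved voxel volume matches the
#' requested volume. Requests beyond the deformable capacity of the rectum are
#' capped with a warning.
#'
#' @param pct planning [ct_volume()].
#' @param structures `structure_set` from [generate_phantom()].
#' @param gas a [gas_spec()].
#' @param seed integer RNG seed (pocket location sampling).
#' @return list with `gasct` ([ct_volume()]), `gas` (pocket [roi_mask()]),
#'   `dvf` (ground-truth displacement field, class `dvf`), `rectum_gas`
#'   (distended rectum mask on the gas CT), and `achieved_volume_cm3`.
#' @export
insert_gas <- function(pct, structures, gas = gas_spec(), seed = 1) {
  rect <- structures$rectum
  if (!any(rect$voxels)) stop("rectum mask is empty")
  d <- dim(pct$voxels); sp <- pct$spacing
  target <- gas$target_volume_cm3
  zero_dvf <- structure(list(field = array(0, c(d, 3)), spacing = sp,
                             origin = pct$origin), class = "dvf")
  if (target <= 0) {
    return(list(gasct = pct, gas = roi_mask(array(FALSE, d), "gas", sp),
                dvf = zero_dvf, rectum_gas = rect, achieved_volume_cm3 = 0))
  }
  with_seed(as.integer(seed), {
    cc <- coord_arrays(pct)
    zc_axis <- axis_coords(pct)[[3]]
    has_rect <- apply(rect$voxels, 3, any)
    zspan <- range(zc_axis[has_rect])
    # pocket centre along the rectum per location bias
    loc <- sample(names(gas$location_bias), 1, prob = gas$location_bias)
    band <- switch(loc, superior = c(0.62, 0.88), middle = c(0.38, 0.62),
                   inferior = c(0.12, 0.38))
    zc <- zspan[1] + diff(zspan) * stats::runif(1, band[1], band[2])
    zc <- min(max(zc + gas$z_offset_mm, zspan[1] + 4), zspan[2] - 4)
    # rectal axis from the in-plane centroid of the rectum mask
    axis_xy <- c(mean(cc$x[rect$voxels]), mean(cc$y[rect$voxels]))
    r0 <- sqrt(max((cc$x[rect$voxels] - axis_xy[1])^2 +
                     (cc$y[rect$voxels] - axis_xy[2])^2))
    amp <- gas$distension_mm
    a_lat <- r0 + 0.8 * amp
    cz0 <- max(10, target * 1000 / (4 / 3 * pi * a_lat^2))
    sigma_z <- max(8, 0.6 * cz0)

    # pull the planning CT back through T(x) = x + u(x): invert by fixed point
    invert_map <- function() {
      xi <- cc$x; yi <- cc$y
      for (it in 1:8) {
        u <- gas_displacement(xi, yi, cc$z, axis_xy, zc, r0, amp, sigma_z)
        xi <- cc$x - u$ux; yi <- cc$y - u$uy
      }
      list(x = xi, y = yi)
    }
    inv <- invert_map()
    vox <- cbind((as.vector(inv$x) - pct$origin[1]) / sp[1] + 1,
                 (as.vector(inv$y) - pct$origin[2]) / sp[2] + 1,
                 (as.vector(cc$z) - pct$origin[3]) / sp[3] + 1)
    rect_g_vox <- array(trilinear_sample(rect$voxels + 0, vox, fill = 0) >= 0.5, d)
    rect_g <- roi_mask(rect_g_vox, "rectum_gas", sp, pct$origin)

    carve <- function(cz) {
      ell <- ((cc$x - axis_xy[1]) / a_lat)^2 + ((cc$y - axis_xy[2]) / a_lat)^2 +
        ((cc$z - zc) / cz)^2 <= 1
      ell & rect_g_vox
    }
    vol_of <- function(cz) sum(carve(cz)) * prod(sp) / 1000
    cz_max <- 60
    achieved_cap <- vol_of(cz_max)
    if (achieved_cap < target * 0.98) {
      warning(sprintf(
        "requested gas volume %.1f cm^3 exceeds deformable capacity; capped at %.1f cm^3",
        target, achieved_cap))
      cz <- cz_max
    } else {
      lo <- 2; hi <- cz_max
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (vol_of(mid) < target) lo <- mid else hi <- mid
      }
      cz <- hi
    }
    gas_vox <- carve(cz)

    hu_g <- array(trilinear_sample(pct$voxels, vox, fill = pct$voxels[1]), d)
    hu_g[gas_vox] <- gas$gas_hu
    if (gas$rescan_noise_sd > 0)
      hu_g <- hu_g + stats::rnorm(length(hu_g), 0, gas$rescan_noise_sd)
    hu_g <- pmin(pmax(hu_g, -1100), 1500)
    gasct <- ct_volume(hu_g, spacing = sp, origin = pct$origin)

    u <- gas_displacement(cc$x, cc$y, cc$z, axis_xy, zc, r0, amp, sigma_z)
    field <- array(0, c(d, 3))
    mag <- sqrt(u$ux^2 + u$uy^2)
    u$ux[mag < 0.01] <- 0; u$uy[mag < 0.01] <- 0
    field[, , , 1] <- u$ux; field[, , , 2] <- u$uy
    dvf <- structure(list(field = field, spacing = sp, origin = pct$origin),
                     class = "dvf")
    list(gasct = gasct, gas = roi_mask(gas_vox, "gas", sp, pct$origin),
         dvf = dvf, rectum_gas = rect_g,
         achieved_volume_cm3 = sum(gas_vox) * prod(sp) / 1000)
  })
}

#' Uniform-water box fixture
#'
#' A uniform water volume (HU 0) with a centred cubic target, used to check
#' per-field dose uniformity of the optimiser under ideal conditions.
#'
#' @param shape grid dimensions. @param spacing voxel spacing (mm).
#' @param side_mm box target edge length (mm).
#' @return list with `ct`, and `structures` containing `ctv` = `ptv` = box
#'   (no organs at risk).
#' @export
water_box_phantom <- function(shape = c(60, 60, 40), spacing = c(2, 2, 2),
                              side_mm = 36) {
  vol <- ct_volume(array(0, shape), spacing = spacing)
  cc <- coord_arrays(vol)
  ext <- (shape - 1) * spacing
  ctr <- ext / 2
  box <- abs(cc$x - ctr[1]) <= side_mm / 2 & abs(cc$y - ctr[2]) <= side_mm / 2 &
    abs(cc$z - ctr[3]) <= side_mm / 2
  ctv <- roi_mask(box, "ctv", spacing)
  structure_set <- structure(list(ctv = ctv, ptv = roi_mask(box, "ptv", spacing)),
                             class = "structure_set")
  list(ct = vol, structures = structure_set)
}

#' Rectal gas volume by HU windowing
#'
#' Volume of rectum voxels whose HU falls inside the gas window
#' (default -1200 to -120), in cm^3.
#'
#' @param ct a [ct_volume()].
#' @param rectum congruent [roi_mask()].
#' @param hu_window length-2 `(low, high)` HU window.
#' @return volume in cm^3.
#' @export
gas_volume <- function(ct, rectum, hu_window = c(-1200, -120)) {
  if (hu_window[1] > hu_window[2]) stop("hu_window low must not exceed high")
  if (!identical(dim(ct$voxels), dim(rectum$voxels)))
    stop("grids are not congruent")
  inwin <- ct$voxels >= hu_window[1] & ct$voxels <= hu_window[2]
  sum(inwin & rectum$voxels) * prod(ct$spacing) / 1000
}

#' Per-fraction variability of a gas pocket
#'
#' Session-to-session reproducibility option of the generator: returns a
#' jittered copy of a [gas_spec()] whose target volume is perturbed with the
#' configured per-fraction SD (about 2.9 cm^3) and whose pocket centre is
#' shifted along the rectum by up to the configured positional
#' reproducibility (5 mm at most by default).
#'
#' @param gas a [gas_spec()].
#' @param seed integer RNG seed.
#' @return a jittered [gas_spec()].
#' @export
jitter_gas_spec <- function(gas, seed) {
  with_seed(as.integer(seed), {
    out <- gas
    out$target_volume_cm3 <- max(0, gas$target_volume_cm3 +
                                   stats::rnorm(1, 0, gas$fraction_volume_sd_cm3))
    out$z_offset_mm <- gas$z_offset_mm +
      stats::runif(1, -gas$fraction_shift_mm, gas$fraction_shift_mm)
    out
  })
}

#' Draw cohort gas volumes
#'
#' Gamma-distributed bulky-gas volumes with the configured cohort mean and SD
#' (defaults 17.54 and 11.10 cm^3).
#'
#' @param n number of draws.
#' @param gas a [gas_spec()].
#' @return numeric vector of volumes (cm^3).
#' @export
sample_gas_volumes <- function(n, gas = gas_spec()) {
  m <- gas$cohort_mean_cm3; s <- gas$cohort_sd_cm3
  if (m <= 0) return(rep(0, n))
  shape <- (m / s)^2
  stats::rgamma(n, shape = shape, scale = s^2 / m)
}
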