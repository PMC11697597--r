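#' Plan prescription and geometry
#'
#' @param prescription_gy total RBE-weighted prescription (51.6 Gy default).
#' @param n_fx fraction count (12 default; lateral opposed fields, 6 each,
#'   one field per fraction).
#' @param beam_angles gantry angles of the two fields.
#' @param grid_mm dose-grid resolution (equal to the CT grid here).
#' @param spot_pitch_mm lateral spot pitch (mm).
#' @param layer_step_mm energy-layer spacing (mm WEPL).
#' @param sigma_mm lateral spot sigma (mm).
#' @return list of class `plan_spec`.
#' @export
plan_spec <- function(prescription_gy = 51.6, n_fx = 12,
                      beam_angles = c(90, 270), grid_mm = 2,
                      spot_pitch_mm = 5, layer_step_mm = 4, sigma_mm = 4) {
  structure(list(prescription_gy = prescription_gy, n_fx = n_fx,
                 beam_angles = beam_angles, grid_mm = grid_mm,
                 spot_pitch_mm = spot_pitch_mm, layer_step_mm = layer_step_mm,
                 sigma_mm = sigma_mm,
                 per_fx_gy = prescription_gy / n_fx),
            class = "plan_spec")
}

# Build spot and layer placement for one lateral field covering the PTV.
# Spots sit on a (y, z) grid; energy layers are spaced in WEPL so that every
# PTV ray is covered from its proximal to its distal water-equivalent depth.
place_spots <- function(spr, ptv, spec, wepl = NULL, margin_mm = 3) {
  if (!any(ptv$voxels)) stop("PTV is empty")
  if (is.null(wepl)) wepl <- wepl_trace(spr, spec)
  d <- dim(spr$spr)
  yc <- (seq_len(d[2]) - 1) * spr$spacing[2] + spr$origin[2]
  zc <- (seq_len(d[3]) - 1) * spr$spacing[3] + spr$origin[3]
  # per-ray PTV WEPL interval
  ray_any <- apply(ptv$voxels, c(2, 3), any)
  win <- array(Inf, dim(ray_any)); wout <- array(-Inf, dim(ray_any))
  wp <- wepl; wp[!ptv$voxels] <- NA
  win <- apply(wp, c(2, 3), function(v) if (all(is.na(v))) Inf else min(v, na.rm = TRUE))
  wout <- apply(wp, c(2, 3), function(v) if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  jj <- which(apply(ray_any, 1, any)); kk <- which(apply(ray_any, 2, any))
  u_grid <- seq(yc[min(jj)] - spec$spot_pitch_mm, yc[max(jj)] + spec$spot_pitch_mm,
                by = spec$spot_pitch_mm)
  v_grid <- seq(zc[min(kk)] - spec$spot_pitch_mm, zc[max(kk)] + spec$spot_pitch_mm,
                by = spec$spot_pitch_mm)
  rng_all <- range(c(win[is.finite(win)], wout[is.finite(wout)]))
  ranges <- seq(rng_all[1] - margin_mm, rng_all[2] + margin_mm,
                by = spec$layer_step_mm)
  layers <- data.frame(layer = seq_along(ranges), range_mm = ranges)
  spots <- NULL
  for (li in seq_along(ranges)) {
    R <- ranges[li]
    keep_u <- numeric(0); keep_v <- numeric(0)
    for (u in u_grid) for (v in v_grid) {
      j <- which.min(abs(yc - u)); k <- which.min(abs(zc - v))
      # search a small neighbourhood of rays so spots at the lateral margin
      # still get layers matching nearby PTV rays
      j0 <- max(1, j - 2); j1 <- min(d[2], j + 2)
      k0 <- max(1, k - 2); k1 <- min(d[3], k + 2)
      wi <- suppressWarnings(min(win[j0:j1, k0:k1]))
      wo <- suppressWarnings(max(wout[j0:j1, k0:k1]))
      if (is.finite(wi) && R >= wi - margin_mm && R <= wo + margin_mm) {
        keep_u <- c(keep_u, u); keep_v <- c(keep_v, v)
      }
    }
    if (length(keep_u))
      spots <- rbind(spots, data.frame(layer = li, u_mm = keep_u, v_mm = keep_v,
                                       range_mm = R))
  }
  ddt <- lapply(seq_len(nrow(layers)), function(li) depth_dose_table(layers$range_mm[li]))
  list(spec = spec, spots = spots, layers = layers, ddt = ddt,
       weights = rep(1, nrow(spots)))
}

# Influence matrix: columns = spots, rows = sampled voxels, for voxel world
# coordinates shifted by `shift` = c(dy, dz) mm (robust scenario).
influence_matrix <- function(field, wepl, vox_ijk, vol_geom, shift = c(0, 0)) {
  sp <- vol_geom$spacing; org <- vol_geom$origin
  y <- org[2] + (vox_ijk[, 2] - 1) * sp[2] + shift[1]
  z <- org[3] + (vox_ijk[, 3] - 1) * sp[3] + shift[2]
  pts <- cbind(vox_ijk[, 1],
               (y - org[2]) / sp[2] + 1,
               (z - org[3]) / sp[3] + 1)
  w_v <- trilinear_sample(wepl, pts, fill = 1e6)
  n <- nrow(vox_ijk); m <- nrow(field$spots)
  A <- matrix(0, n, m)
  s2 <- 2 * field$spec$sigma_mm^2
  for (li in seq_len(nrow(field$layers))) {
    sel <- which(field$spots$layer == li)
    if (!length(sel)) next
    Dl <- ddt_lookup(field$ddt[[li]], w_v)
    G <- exp(-(outer(y, field$spots$u_mm[sel], `-`)^2 +
                 outer(z, field$spots$v_mm[sel], `-`)^2) / s2)
    A[, sel] <- Dl * G
  }
  A
}

subsample_idx <- function(mask, nmax) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > nmax) idx <- idx[seq(1, nrow(idx), length.out = nmax), , drop = FALSE]
  idx
}

#' Robust single-field-uniform-dose optimisation
#'
#' Optimises the spot weights of each lateral field independently so that the
#' field alone delivers a uniform RBE-weighted dose of one fraction
#' (prescription / fractions) to the PTV, while limiting rectum and
#' rectal-wall dose. The objective is the worst case over discrete
#' isocentre-shift scenarios (nominal and +/- `robust_mm` in the
#' anterior-posterior and superior-inferior directions), minimised by
#' projected gradient on non-negative weights. Biological weighting enters
#' through per-voxel physical targets derived by inverting the MKM relation at
#' the current z1D* estimate, refined once after a first optimisation pass.
#'
#' @param spr planning `spr_volume`.
#' @param structures `structure_set` (uses `ptv`, `rectum`, `rectal_wall`).
#' @param plan a [plan_spec()].
#' @param robust_mm scenario shift magnitude (mm); 2 mm by default.
#' @param params [mkm_params()].
#' @param control list: `max_iter`, `n_ptv`, `n_oar`, penalty weights
#'   `w_under`, `w_over`, `w_oar`, and `oar_frac` (OAR RBE threshold as a
#'   fraction of the per-fraction prescription).
#' @return list of class `cirt_plan`: per-angle fields with optimised weights,
#'   the plan spec and MKM parameters.
#' @export
optimize_sfud <- function(spr, structures, plan = plan_spec(), robust_mm = 2,
                          params = mkm_params(), control = list()) {
  ctrl <- utils::modifyList(list(max_iter = 160, n_ptv = 1600, n_oar = 800,
                                 w_under = 60, w_over = 3, w_oar = 4,
                                 oar_frac = 0.80, refine = TRUE,
                                 spot_margin_mm = 3), control)
  ptv <- structures$ptv
  if (!any(ptv$voxels)) stop("PTV is empty")
  oar_vox <- array(FALSE, dim(spr$spr))
  for (nm in c("rectum", "rectal_wall"))
    if (!is.null(structures[[nm]])) oar_vox <- oar_vox | structures[[nm]]$voxels
  t_rbe <- plan$per_fx_gy
  shifts <- list(c(0, 0), c(robust_mm, 0), c(-robust_mm, 0),
                 c(0, robust_mm), c(0, -robust_mm))
  vol_geom <- list(spacing = spr$spacing, origin = spr$origin)
  fields <- list()
  for (ang in plan$beam_angles) {
    spec <- beam_spec(ang, sigma_mm = plan$sigma_mm,
                      spot_pitch_mm = plan$spot_pitch_mm,
                      layer_step_mm = plan$layer_step_mm)
    wepl <- wepl_trace(spr, spec)
    field <- place_spots(spr, ptv, spec, wepl = wepl,
                         margin_mm = ctrl$spot_margin_mm)
    idx_ptv <- subsample_idx(ptv$voxels, ctrl$n_ptv)
    idx_oar <- subsample_idx(oar_vox, ctrl$n_oar)
    idx <- rbind(idx_ptv, idx_oar)
    is_ptv <- c(rep(TRUE, nrow(idx_ptv)), rep(FALSE, nrow(idx_oar)))
    As <- lapply(shifts, function(sh) influence_matrix(field, wepl, idx, vol_geom, sh))
    # initial per-voxel physical targets from a uniform-weight z1D* estimate:
    # the RBE weighting varies with depth, so a uniform RBE-weighted dose
    # needs a tilted physical dose
    w <- rep(1, nrow(field$spots))
    pd0 <- physical_dose(spr, field, weights = w, wepl = wepl)
    z1_samp <- pd0$z1dstar[cbind(idx_ptv[, 1], idx_ptv[, 2], idx_ptv[, 3])]
    z1_typ <- stats::median(z1_samp[z1_samp > 0])
    z1_samp[z1_samp <= 0] <- z1_typ
    t_phys <- mkm_phys_target(t_rbe, z1_samp, params)
    t_oar_phys <- mkm_phys_target(ctrl$oar_frac * t_rbe, z1_typ, params)
    # smoothed worst case over the robust scenarios (softmax-weighted max),
    # minimised over non-negative weights by L-BFGS-B
    opt_pass <- function(w, iters) {
      n_p <- sum(is_ptv); n_o <- sum(!is_ptv)
      scen_losses <- function(w) {
        lapply(As, function(A) {
          dvec <- as.vector(A %*% w)
          r_u <- pmax(0, t_phys - dvec[is_ptv])
          r_o <- pmax(0, dvec[is_ptv] - t_phys)
          r_oar <- if (n_o) pmax(0, dvec[(n_p + 1):(n_p + n_o)] - t_oar_phys) else numeric(0)
          L <- ctrl$w_under * sum(r_u^2) / n_p + ctrl$w_over * sum(r_o^2) / n_p +
            (if (n_o) ctrl$w_oar * sum(r_oar^2) / n_o else 0)
          list(L = L, r_u = r_u, r_o = r_o, r_oar = r_oar)
        })
      }
      # the optimiser evaluates fn and gr at the same point: cache the
      # scenario residuals between the two calls
      cache <- new.env(parent = emptyenv())
      losses_at <- function(w) {
        if (!is.null(cache$w) && identical(cache$w, w)) return(cache$sl)
        sl <- scen_losses(w)
        cache$w <- w; cache$sl <- sl
        sl
      }
      fn <- function(w) {
        Ls <- vapply(losses_at(w), `[[`, 0, "L")
        mx <- max(Ls)
        rho <- 20 / max(mx, 1e-12)
        mx + log(sum(exp(rho * (Ls - mx)))) / rho
      }
      gr <- function(w) {
        sl <- losses_at(w)
        Ls <- vapply(sl, `[[`, 0, "L")
        mx <- max(Ls)
        rho <- 20 / max(mx, 1e-12)
        sw <- exp(rho * (Ls - mx)); sw <- sw / sum(sw)
        g <- numeric(length(w))
        for (si in seq_along(As)) {
          if (sw[si] < 0.02) next
          gv <- numeric(n_p + n_o)
          gv[seq_len(n_p)] <- 2 * (ctrl$w_over * sl[[si]]$r_o -
                                     ctrl$w_under * sl[[si]]$r_u) / n_p
          if (n_o) gv[(n_p + 1):(n_p + n_o)] <- 2 * ctrl$w_oar * sl[[si]]$r_oar / n_o
          g <- g + sw[si] * as.vector(crossprod(As[[si]], gv))
        }
        g
      }
      fit <- stats::optim(w, fn, gr, method = "L-BFGS-B", lower = 0,
                          control = list(maxit = iters, factr = 1e7))
      pmax(0, fit$par)
    }
    # scale the uniform start to roughly the right magnitude
    d_nom <- as.vector(As[[1]] %*% w)
    w <- w * stats::median(t_phys) / stats::median(d_nom[is_ptv])
    w <- opt_pass(w, ctrl$max_iter)
    if (ctrl$refine) {
      pd1 <- physical_dose(spr, field, weights = w, wepl = wepl)
      z1_samp <- pd1$z1dstar[cbind(idx_ptv[, 1], idx_ptv[, 2], idx_ptv[, 3])]
      z1_typ <- stats::median(z1_samp[z1_samp > 0])
      z1_samp[z1_samp <= 0] <- z1_typ
      t_phys <- mkm_phys_target(t_rbe, z1_samp, params)
      t_oar_phys <- mkm_phys_target(ctrl$oar_frac * t_rbe, z1_typ, params)
      w <- opt_pass(w, ceiling(ctrl$max_iter / 2))
    }
    # final scaling so the PTV median RBE-weighted dose equals one fraction
    pd <- physical_dose(spr, field, weights = w, wepl = wepl)
    Dp <- pd$dose[ptv$voxels]; z1p <- pd$z1dstar[ptv$voxels]
    f <- function(s) {
      stats::median(mkm_rbe_weight(s * Dp, z1p, params)) - t_rbe
    }
    s <- stats::uniroot(f, c(0.3, 3))$root
    field$weights <- w * s
    fields[[as.character(ang)]] <- field
  }
  # coverage renormalisation: scale both fields together until the summed
  # total meets the CTV D99.5 constraint (95% of prescription) with a small
  # margin, if prescription normalisation alone leaves it short
  ctv <- if (!is.null(structures$ctv)) structures$ctv else ptv
  per_field_fx <- plan$n_fx / length(fields)
  finfo <- lapply(fields, function(f) {
    pd <- physical_dose(spr, f)
    list(Dp = pd$dose[ctv$voxels], z1 = pd$z1dstar[ctv$voxels])
  })
  tot_at <- function(s) {
    acc <- 0
    for (f in finfo)
      acc <- acc + per_field_fx * mkm_rbe_weight(s * f$Dp, f$z1, params)
    acc
  }
  cov_short <- function(s) {
    tot <- tot_at(s)
    min(unname(stats::quantile(tot, 0.005, type = 7)) -
          0.95 * plan$prescription_gy * 1.015,
        min(tot) - 0.9283 * plan$prescription_gy * 1.02)
  }
  s_cov <- 1
  if (cov_short(1) < 0)
    s_cov <- if (cov_short(1.6) > 0) stats::uniroot(cov_short, c(1, 1.6))$root else 1.6
  if (s_cov != 1)
    for (nm in names(fields)) fields[[nm]]$weights <- fields[[nm]]$weights * s_cov
  structure(list(fields = fields, plan = plan, params = params,
                 robust_mm = robust_mm), class = "cirt_plan")
}

#' @export
print.cirt_plan <- function(x, ...) {
  cat(sprintf("<cirt_plan> %.1f Gy (RBE) / %d fx, fields at %s deg\n",
              x$plan$prescription_gy, x$plan$n_fx,
              paste(names(x$fields), collapse = "/")))
  for (nm in names(x$fields))
    cat(sprintf("  field %s: %d spots, %d layers\n", nm,
                nrow(x$fields[[nm]]$spots), nrow(x$fields[[nm]]$layers)))
  invisible(x)
}

#' Per-fraction field doses of a plan on a given CT
#'
#' Computes, for each field, the single-fraction physical and RBE-weighted
#' dose with the stored (fixed) spot weights on the supplied stopping-power
#' volume. Used both for the nominal plan (planning CT) and for
#' recalculation on the gas CT.
#'
#' @param plan a `cirt_plan`.
#' @param spr `spr_volume` to calculate on.
#' @return named list per field angle: list(`physical`, `rbe`, `z1dstar`).
#' @export
plan_field_doses <- function(plan, spr) {
  out <- list()
  for (nm in names(plan$fields)) {
    field <- plan$fields[[nm]]
    pd <- physical_dose(spr, field)
    rbe <- mkm_rbe_weight(pd$dose, pd$z1dstar, plan$params)
    out[[nm]] <- list(
      physical = dose_grid(pd$dose, spr$spacing, spr$origin, "physical", "fraction"),
      rbe = dose_grid(rbe, spr$spacing, spr$origin, "rbe_weighted", "fraction"),
      z1dstar = pd$z1dstar)
  }
  out
}

#' Recalculate a fixed plan on another CT
#'
#' All spots, weights and energies are kept; only the traversed
#' stopping-power distribution changes (after optional rigid alignment).
#' No re-optimisation is performed.
#'
#' @param plan a `cirt_plan`.
#' @param spr_other `spr_volume` of the other CT (e.g. the gas CT).
#' @param rigid optional [rigid_transform()] mapping the planning frame to the
#'   other CT frame; identity by default.
#' @return as [plan_field_doses()].
#' @export
recalc_plan <- function(plan, spr_other, rigid = NULL) {
  spr_use <- spr_other
  if (!is.null(rigid) && !rigid_is_identity(rigid)) {
    spr_use$spr <- apply_rigid_to_array(spr_other$spr, rigid, spr_other$spacing,
                                        spr_other$origin)
  }
  plan_field_doses(plan, spr_use)
}
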