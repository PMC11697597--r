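test_that("phantom generation is deterministic per seed and varies across seeds", {
  a <- generate_phantom(phantom_spec(), seed = 3)
  b <- generate_phantom(phantom_spec(), seed = 3)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$structures$rectum$voxels, b$structures$rectum$voxels)
  c <- generate_phantom(phantom_spec(), seed = 4)
  expect_false(identical(a$ct$voxels, c$ct$voxels))
  # same topology: all structures present and nested the same way
  for (st in list(a$structures, c$structures)) {
    expect_true(all(st$ctv$voxels | !st$ctv$voxels))
    expect_true(all(st$ctv$voxels <= st$ptv$voxels))
    expect_true(all(st$rectal_wall$voxels <= st$rectum$voxels))
    expect_gt(mask_volume_cm3(st$ctv), 10)
  }
})

test_that("CTV volume matches the analytic ellipsoid volume", {
  spec <- phantom_spec(prostate_radii = c(20, 20, 20), sv_radii = c(0, 0, 0),
                       jitter_frac = 0, jitter_mm = 0)
  ph <- generate_phantom(spec, seed = 1)
  v_analytic <- 4 / 3 * pi * 2^3   # cm^3 for a 20-mm-radius sphere
  expect_lt(abs(mask_volume_cm3(ph$structures$ctv) - v_analytic) / v_analytic, 0.10)
})

test_that("rectal wall is an annulus of the requested thickness", {
  # solid cylinder radius 10 mm on a 1-mm grid; wall thickness 2 mm
  d <- c(30, 30, 20)
  vol <- ct_volume(array(0, d), spacing = c(1, 1, 1))
  cc <- gasfx:::coord_arrays(vol)
  cyl <- (cc$x - 14)^2 + (cc$y - 14)^2 <= 10^2
  rect <- roi_mask(cyl, "rectum", c(1, 1, 1))
  wall <- derive_rectal_wall(rect, thickness_mm = 2)
  expect_true(all(wall$voxels <= rect$voxels))
  h_cm <- d[3] * 0.1
  v_annulus <- pi * (1.0^2 - 0.8^2) * h_cm   # cm^3, radii in cm
  # one voxel shell tolerance: circumference x thickness x height
  shell <- 2 * pi * 1.0 * 0.1 * h_cm
  expect_lt(abs(mask_volume_cm3(wall) - v_annulus), shell)
  # zero thickness -> empty wall
  expect_equal(sum(derive_rectal_wall(rect, 0)$voxels), 0)
  # single-voxel rectum: erosion empties it, wall falls back to the rectum
  single <- array(FALSE, d); single[5, 5, 5] <- TRUE
  expect_warning(w1 <- derive_rectal_wall(roi_mask(single, "r", c(1, 1, 1)), 2))
  expect_identical(w1$voxels, single)
})

test_that("rectum cropping keeps slices within the CTV span plus margin", {
  d <- c(10, 10, 60)
  mk <- function(zlo, zhi) {
    a <- array(FALSE, d)
    zc <- (seq_len(d[3]) - 1) * 2
    a[4:6, 4:6, zc >= zlo & zc <= zhi] <- TRUE
    roi_mask(a, "m", c(2, 2, 2))
  }
  ctv <- mk(50, 90)
  rectum <- mk(0, 118)
  out <- crop_rectum_to_ctv(rectum, ctv, margin_mm = 14)
  zc <- (seq_len(d[3]) - 1) * 2
  kept <- apply(out$voxels, 3, any)
  expect_identical(kept, zc >= 36 & zc <= 104)
  # margin 0 clips exactly to the CTV span
  out0 <- crop_rectum_to_ctv(rectum, ctv, margin_mm = 0)
  expect_identical(apply(out0$voxels, 3, any), zc >= 50 & zc <= 90)
  # rectum already inside the span is unchanged
  inner <- mk(60, 80)
  expect_identical(crop_rectum_to_ctv(inner, ctv, 14)$voxels, inner$voxels)
})

test_that("PTV expansion is anisotropic and voxel-exact on a box", {
  d <- c(40, 40, 30)
  a <- array(FALSE, d)
  a[16:25, 16:25, 11:20] <- TRUE
  ctv <- roi_mask(a, "ctv", c(1, 1, 1))
  # zero margins: identity
  expect_identical(expand_ptv(ctv, c(right = 0))$voxels, ctv$voxels)
  ptv <- expand_ptv(ctv, c(right = 5, left = 5, anterior = 5))
  idx <- which(ptv$voxels, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(11, 30))  # x extended 5 both ways
  expect_equal(range(idx[, 2]), c(11, 25))  # y extended anterior (-y) only
  expect_equal(range(idx[, 3]), c(11, 20))  # z untouched
  expect_true(all(ctv$voxels <= ptv$voxels))
  expect_error(expand_ptv(ctv, c(right = -1)), "non-negative")
})

test_that("gas insertion hits the requested volume and stays inside the rectum", {
  pair <- default_gas_pair(7, 15)
  ins <- pair$ins
  expect_lt(abs(ins$achieved_volume_cm3 - 15) / 15, 0.10)
  expect_true(all(ins$gas$voxels <= ins$rectum_gas$voxels))
  # displacement field is finite, bounded, and zero far from the pocket
  expect_true(all(is.finite(ins$dvf$field)))
  corner <- ins$dvf$field[1:3, 1:3, 1:3, ]
  expect_equal(max(abs(corner)), 0)
})

test_that("zero gas volume returns the planning CT unchanged with a zero field", {
  ph <- default_phantom(7)
  ins <- insert_gas(ph$ct, ph$structures, gas_spec(target_volume_cm3 = 0), seed = 1)
  expect_identical(ins$gasct$voxels, ph$ct$voxels)
  expect_equal(max(abs(ins$dvf$field)), 0)
  expect_equal(sum(ins$gas$voxels), 0)
})

test_that("ground-truth deformation is self-consistent and diffeomorphic", {
  pair <- default_gas_pair(7, 15)
  ph <- pair$ph; ins <- pair$ins
  warped <- gasfx:::warp_mask(ins$rectum_gas, ins$dvf)
  expect_gte(dice(warped, ph$structures$rectum), 0.95)
  diag_mm <- sqrt(sum(ph$ct$spacing^2))
  expect_lte(hausdorff(warped, ph$structures$rectum), 2 * diag_mm)
  # discrete Jacobian determinant of x + u positive everywhere
  u <- ins$dvf$field
  sp <- ins$dvf$spacing
  g <- function(comp, ax) {
    sh <- function(s) { dvec <- c(0, 0, 0); dvec[ax] <- s
      gasfx:::shift_array(u[, , , comp], dvec, 0) }
    (sh(-1) - sh(1)) / (2 * sp[ax])
  }
  J11 <- 1 + g(1, 1); J12 <- g(1, 2); J13 <- g(1, 3)
  J21 <- g(2, 1); J22 <- 1 + g(2, 2); J23 <- g(2, 3)
  J31 <- g(3, 1); J32 <- g(3, 2); J33 <- 1 + g(3, 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  interior <- array(TRUE, dim(det))
  interior[c(1, dim(det)[1]), , ] <- FALSE
  interior[, c(1, dim(det)[2]), ] <- FALSE
  interior[, , c(1, dim(det)[3])] <- FALSE
  expect_gt(min(det[interior]), 0)
})

test_that("gas volume by HU window has exact threshold semantics", {
  ph <- default_phantom(7)
  expect_equal(gas_volume(ph$ct, ph$structures$rectum), 0)
  pair <- default_gas_pair(7, 15)
  gv <- gas_volume(pair$ins$gasct, pair$ins$rectum_gas)
  expect_lt(abs(gv - pair$ins$achieved_volume_cm3), 1.0)
  # a window excluding soft tissue: rectum at HU 40 contributes nothing
  d <- c(8, 8, 8)
  ct <- ct_volume(array(40, d), spacing = c(2, 2, 2))
  m <- roi_mask(array(TRUE, d), "rectum", c(2, 2, 2))
  expect_equal(gas_volume(ct, m, c(-1200, -120)), 0)
  expect_error(gas_volume(ct, m, c(0, -10)), "low")
})

test_that("cohort gas volumes follow the configured distribution (LLN)", {
  set.seed(42)
  v <- sample_gas_volumes(500, gas_spec())
  se <- 11.10 / sqrt(500)
  expect_lt(abs(mean(v) - 17.54), 3 * se)
  expect_true(all(v >= 0))
})

test_that("per-fraction gas variability jitters volume and position within bounds", {
  g <- gas_spec(target_volume_cm3 = 15)
  j <- jitter_gas_spec(g, seed = 9)
  expect_gte(j$target_volume_cm3, 0)
  expect_lte(abs(j$z_offset_mm), g$fraction_shift_mm)
  expect_identical(jitter_gas_spec(g, 9)$target_volume_cm3, j$target_volume_cm3)
})
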