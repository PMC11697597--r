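test_that("DRR line integrals are correct for slabs and additive in attenuation", {
  # water slab 2 voxels (4 mm) thick in y, projected at 0 degrees (rays along y)
  d <- c(20, 20, 10)
  hu <- array(-1000, d)
  hu[, 10:11, ] <- 0          # water: mu = 1
  ct <- ct_volume(hu, spacing = c(2, 2, 2))
  geom <- drr_geometry(0, pixel_spacing_mm = 2, step_mm = 0.5)
  img <- project_drr(ct, geom)
  centre <- img$pixels[abs(img$u_mm) < 10, 3]
  expect_equal(mean(centre), 4, tolerance = 0.15)
  expect_lt(stats::sd(centre), 0.05)  # constant over the slab shadow
  # an air pocket lowers pixel values only inside its shadow
  hu2 <- hu; hu2[9:12, 10:11, 4:6] <- -1000
  img2 <- project_drr(ct_volume(hu2, spacing = c(2, 2, 2)), geom)
  expect_true(all(img2$pixels <= img$pixels + 1e-9))
  expect_lt(min(img2$pixels - img$pixels), -1)
  untouched <- img2$pixels[, 9:10] - img$pixels[, 9:10]
  expect_equal(max(abs(untouched)), 0, tolerance = 1e-9)
  # linearity: mu fields add (HU_c + 1000 = (HU_a + 1000) + (HU_b + 1000))
  hu_a <- array(200, d); hu_b <- array(-500, d)
  hu_c <- hu_a + hu_b + 1000
  pa <- project_drr(ct_volume(hu_a, spacing = c(2, 2, 2)), geom)$pixels
  pb <- project_drr(ct_volume(hu_b, spacing = c(2, 2, 2)), geom)$pixels
  pc <- project_drr(ct_volume(hu_c, spacing = c(2, 2, 2)), geom)$pixels
  expect_equal(pc, pa + pb, tolerance = 1e-9)
})

test_that("ROI projection produces the analytic silhouette", {
  d <- c(30, 30, 16)
  empty <- roi_mask(array(FALSE, d), spacing = c(2, 2, 2))
  geom0 <- drr_geometry(0, pixel_spacing_mm = 1, step_mm = 1)
  expect_false(any(project_roi(empty, geom0)$pixels))
  # axis-aligned box at 0 degrees: rectangle of its cross-section
  b <- array(FALSE, d); b[11:20, 14:17, 5:10] <- TRUE
  box <- roi_mask(b, spacing = c(2, 2, 2))
  pr <- project_roi(box, geom0)
  rows <- which(apply(pr$pixels, 2, any))
  expect_equal(range(pr$v_mm[rows]), c(8, 18))       # z extent of the box
  cols_width <- diff(range(pr$u_mm[apply(pr$pixels, 1, any)]))
  expect_lt(abs(cols_width - 18), 2.1)               # x extent 20-2 mm centre span
  # sphere projects to a disk of its radius at any angle
  vol <- ct_volume(array(0, d), spacing = c(2, 2, 2))
  cc <- gasfx:::coord_arrays(vol)
  sph <- (cc$x - 29)^2 + (cc$y - 29)^2 + (cc$z - 15)^2 <= 10^2
  sm <- roi_mask(sph, spacing = c(2, 2, 2))
  for (ang in c(0, 35, 325)) {
    g <- drr_geometry(ang, pixel_spacing_mm = 1, step_mm = 1)
    p <- project_roi(sm, g)
    width <- diff(range(p$u_mm[apply(p$pixels, 1, any)]))
    expect_lt(abs(width - 20), 2.1)
  }
})

test_that("gas-area extraction windows HU inside the rectum", {
  d <- c(24, 24, 20)
  hu <- array(40, d)
  m <- array(FALSE, d); m[10:15, 10:15, ] <- TRUE
  rectum <- roi_mask(m, "rectum", c(2, 2, 2))
  geom <- drr_geometry(0, pixel_spacing_mm = 1, step_mm = 1)
  # soft-tissue-only rectum: empty gas area
  ct <- ct_volume(hu, spacing = c(2, 2, 2))
  expect_false(any(extract_gas_area(ct, rectum, geom)$pixels))
  # gas cylinder of known SI length inside the rectum
  hu2 <- hu; hu2[11:14, 11:14, 6:13] <- -1000    # 8 slices = 16 mm
  ga <- extract_gas_area(ct_volume(hu2, spacing = c(2, 2, 2)), rectum, geom)
  rows <- which(apply(ga$pixels, 2, any))
  expect_lt(abs(diff(range(ga$v_mm[rows])) + 2 - 16), 2.1)
  expect_error(extract_gas_area(ct, rectum, geom, hu_window = c(0, -10)),
               "inverted")
})

test_that("indicators reproduce constructed geometry and the area identity", {
  # constructed pixel masks on a shared 1-mm DRR grid
  nu <- 60; nv <- 50
  u_mm <- seq(-29, 30, by = 1); v_mm <- seq(0, 98, by = 2)
  blank <- matrix(FALSE, nu, nv)
  mk <- function(px) structure(list(pixels = px, u_mm = u_mm, v_mm = v_mm,
                                    name = "m", source = "pCT",
                                    geom = drr_geometry(35)),
                               class = "projected_roi")
  # PTV shadow: u in [-15, 15], v rows 10..35
  ptv <- blank; ptv[u_mm >= -15 & u_mm <= 15, 10:35] <- TRUE
  # rectum shadow: u in [-5, 5], all rows
  rect <- blank; rect[u_mm >= -5 & u_mm <= 5, ] <- TRUE
  # gas: u in [-5, 11] (6 mm beyond the rectum edge), v rows 26..35
  # inside the PTV span; SI extent = 10 rows x 2 mm = 20 mm
  gas <- blank; gas[u_mm >= -5 & u_mm <= 11, 26:35] <- TRUE
  ind <- compute_indicators(mk(gas), mk(ptv), mk(rect))
  expect_equal(ind$drr_gas_si, 2.0)
  expect_equal(ind$drr_gas_side, 0.6)
  expect_equal(ind$drr_gas_area, 1.2)
  # empty gas -> all zeros
  z <- compute_indicators(mk(blank), mk(ptv), mk(rect))
  expect_equal(c(z$drr_gas_si, z$drr_gas_side, z$drr_gas_area), c(0, 0, 0))
  # area identity on arbitrary masks
  set.seed(3)
  for (i in 1:5) {
    g2 <- blank; g2[sample(nu * nv, 150)] <- TRUE
    ind2 <- compute_indicators(mk(g2), mk(ptv), mk(rect))
    expect_identical(ind2$drr_gas_area, ind2$drr_gas_si * ind2$drr_gas_side)
  }
})

test_that("enlarging the gas pocket never decreases the indicators", {
  ph <- default_phantom(7)
  small <- insert_gas(ph$ct, ph$structures, gas_spec(target_volume_cm3 = 8,
                                                     rescan_noise_sd = 0), seed = 5)
  large <- insert_gas(ph$ct, ph$structures, gas_spec(target_volume_cm3 = 22,
                                                     rescan_noise_sd = 0), seed = 5)
  geom <- drr_geometry(35)
  ptv_p <- project_roi(ph$structures$ptv, geom)
  rect_p <- project_roi(ph$structures$rectum, geom)
  ind_s <- compute_indicators(extract_gas_area(small$gasct, small$rectum_gas, geom),
                              ptv_p, rect_p)
  ind_l <- compute_indicators(extract_gas_area(large$gasct, large$rectum_gas, geom),
                              ptv_p, rect_p)
  expect_gte(ind_l$drr_gas_si, ind_s$drr_gas_si)
  expect_gte(ind_l$drr_gas_side, ind_s$drr_gas_side)
  expect_gte(ind_l$drr_gas_area, ind_s$drr_gas_area)
})
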