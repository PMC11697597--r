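test_that("HU to SPR conversion anchors at water and preserves order", {
  d <- c(4, 4, 2)
  ct <- ct_volume(array(c(0, -1000, 40, 700), d), spacing = c(2, 2, 2))
  spr <- hu_to_spr(ct)
  expect_equal(spr$spr[1, 1, 1], 1.0)
  expect_equal(spr$spr[2, 1, 1], 0.001)
  hu_sorted <- seq(-1000, 1500, length.out = 32)
  ct2 <- ct_volume(array(hu_sorted, c(32, 1, 1)), spacing = c(1, 1, 1))
  expect_false(is.unsorted(as.vector(hu_to_spr(ct2)$spr)))
  # HU beyond a (narrow) calibration domain are clamped with a warning
  narrow <- data.frame(hu = c(-1000, 0, 1000), spr = c(0.001, 1, 1.6))
  expect_warning(out <- hu_to_spr(ct_volume(array(1500, c(2, 2, 2))), narrow),
                 "clamped")
  expect_equal(out$spr[1, 1, 1], 1.6)
})

test_that("gas override sets SPR to water only inside the mask", {
  d <- c(4, 4, 4)
  ct <- ct_volume(array(-1000, d), spacing = c(2, 2, 2))
  spr <- hu_to_spr(ct)
  empty <- roi_mask(array(FALSE, d), "gas", c(2, 2, 2))
  expect_identical(override_gas_with_water(spr, empty)$spr, spr$spr)
  m <- array(FALSE, d); m[1, 1, 1] <- TRUE
  out <- override_gas_with_water(spr, roi_mask(m, "gas", c(2, 2, 2)))
  expect_equal(out$spr[1, 1, 1], 1.0)
  expect_equal(out$spr[2, 1, 1], spr$spr[2, 1, 1])
})

test_that("WEPL tracing matches hand-computed cumulative sums", {
  # uniform SPR 1.0: midpoint-convention depth at voxel i is (i - 0.5) * step
  d <- c(20, 4, 4)
  spr <- list(spr = array(1, d), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  class(spr) <- "spr_volume"
  w <- wepl_trace(spr, beam_spec(270))   # entering at x = 0, travelling +x
  expect_equal(w[1, 1, 1], 1)            # half of the first 2-mm step
  expect_equal(w[20, 2, 2], 39)          # 20 steps of 2 mm minus half a step
  expect_equal(w[20, 2, 2] + 1, 40)      # exit-face WEPL over 40 mm path
  # uniform SPR 0.5 halves every depth
  spr5 <- spr; spr5$spr <- array(0.5, d)
  expect_equal(wepl_trace(spr5, beam_spec(270))[20, 1, 1] + 0.5, 20)
  # alternating 2-mm voxels SPR {1.0, 0.5}: exit WEPL = 10*2*1 + 10*2*0.5 = 30
  alt <- spr; alt$spr <- array(rep(c(1, 0.5), 10), d)
  w_alt <- wepl_trace(alt, beam_spec(270))
  s <- rep(c(1, 0.5), 10)
  hand <- cumsum(s * 2) - s   # midpoint convention, 2-mm steps
  expect_equal(w_alt[, 1, 1], hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(w_alt[20, 1, 1] + 0.5 * 2 * 0.5, 30)
  # 90-degree beam enters from the opposite face
  w90 <- wepl_trace(spr, beam_spec(90))
  expect_equal(w90[20, 1, 1], 1)
  expect_error(wepl_trace(spr, beam_spec(35)), "cardinal")
})

test_that("depth-dose fixtures have a single Bragg peak and rising z1D*", {
  ddt <- depth_dose_table(80)
  expect_true(all(ddt$dose_per_fluence >= 0))
  pk <- which.max(ddt$dose_per_fluence)
  expect_lt(abs(ddt$depth_mm[pk] - 80), 3)
  # single maximum: rises before, falls after (smoothed shape)
  expect_true(all(diff(ddt$dose_per_fluence[ddt$depth_mm > 82]) <= 1e-9))
  expect_true(all(diff(ddt$z1dstar_gy) >= 0))
  expect_true(all(ddt$z1dstar_gy >= 0))
})

test_that("pencil-beam dose is linear in spot weights with peaks at the layer range", {
  d <- c(60, 20, 20)
  spr <- structure(list(spr = array(1, d), spacing = c(2, 2, 2),
                        origin = c(0, 0, 0)), class = "spr_volume")
  spec <- beam_spec(270)
  field <- list(spec = spec,
                spots = data.frame(layer = 1, u_mm = 19, v_mm = 19, range_mm = 60),
                layers = data.frame(layer = 1, range_mm = 60),
                ddt = list(depth_dose_table(60)), weights = 1)
  pd1 <- physical_dose(spr, field)
  expect_equal(max(pd1$dose), pd1$dose[which.max(pd1$dose)])
  # peak depth within one voxel of the layer range
  pk_idx <- which(pd1$dose == max(pd1$dose), arr.ind = TRUE)[1, ]
  wepl_at_peak <- (pk_idx[1] - 0.5) * 2
  expect_lte(abs(wepl_at_peak - 60), 2)
  # zero weights -> zero dose; doubling doubles
  expect_equal(max(physical_dose(spr, field, weights = 0)$dose), 0)
  pd2 <- physical_dose(spr, field, weights = 2)
  expect_equal(pd2$dose, 2 * pd1$dose)
  expect_error(physical_dose(spr, field, weights = -1), "non-negative")
})

test_that("MKM weighting matches the closed form and its limits", {
  p <- mkm_params()
  expect_equal(p$alpha0, 0.1720)
  expect_equal(p$beta, 0.0615)
  # alpha at z1D* = 1 Gy
  expect_equal(p$alpha0 + p$beta * 1, 0.2335)
  # zero dose maps to zero
  expect_equal(mkm_rbe_weight(array(0, c(2, 2, 2)), array(1, c(2, 2, 2)), p),
               array(0, c(2, 2, 2)))
  # self-reference limit: z1D* = 0 with reference = (alpha0, beta)
  D <- array(seq(0.5, 4, length.out = 8), c(2, 2, 2))
  expect_equal(mkm_rbe_weight(D, array(0, dim(D)), p), D, tolerance = 1e-12)
  # monotone in physical dose and in z1D*
  d1 <- mkm_rbe_weight(array(2, 1), array(1, 1), p)
  expect_gt(mkm_rbe_weight(array(2.5, 1), array(1, 1), p), d1)
  expect_gt(mkm_rbe_weight(array(2, 1), array(2, 1), p), d1)
  # round trip: reference survival recomputed from D_rbe equals ln S to 1e-9
  z1 <- array(1.7, 1); Dp <- array(2.3, 1)
  drbe <- mkm_rbe_weight(Dp, z1, p)
  lnS <- -((p$alpha0 + p$beta * 1.7) * 2.3 + p$beta * 2.3^2)
  lnS_ref <- -(p$alpha_ref * drbe + p$beta_ref * drbe^2)
  expect_equal(as.numeric(lnS_ref), lnS, tolerance = 1e-9)
})

test_that("a stopping-power deficit shifts the distal falloff by its WEPL", {
  # single spot in water vs the same geometry with a 20-mm slab of SPR 0.5
  # (10 mm WEPL deficit): the distal 80% falloff moves 10 mm downstream
  d <- c(80, 20, 20)
  mk_spr <- function(slab) {
    a <- array(1, d)
    if (slab) a[11:20, , ] <- 0.5
    structure(list(spr = a, spacing = c(2, 2, 2), origin = c(0, 0, 0)),
              class = "spr_volume")
  }
  field <- list(spec = beam_spec(270),
                spots = data.frame(layer = 1, u_mm = 19, v_mm = 19, range_mm = 80),
                layers = data.frame(layer = 1, range_mm = 80),
                ddt = list(depth_dose_table(80)), weights = 1)
  distal80 <- function(spr) {
    prof <- physical_dose(spr, field)$dose[, 10, 10]
    pk <- which.max(prof)
    i <- pk + which(prof[(pk + 1):length(prof)] < 0.8 * max(prof))[1]
    (i - 1) * 2
  }
  shift <- distal80(mk_spr(TRUE)) - distal80(mk_spr(FALSE))
  expect_lte(abs(shift - 10), 2)
})
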