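test_that("dose-at-volume handles uniform doses, Dmin, and the interpolation rule", {
  d <- c(10, 10, 10)
  uni <- dose_grid(array(51.6, d), spacing = c(2, 2, 2))
  mask <- roi_mask(array(TRUE, d), spacing = c(2, 2, 2))
  expect_equal(d_at_volume(uni, mask, 99.5), 51.6)
  expect_equal(d_at_volume(uni, mask, 100), 51.6)
  # 1000 voxels: 10 at 0 Gy, the rest at 50 Gy
  vals <- c(rep(0, 10), rep(50, 990))
  dg <- dose_grid(array(vals, d), spacing = c(2, 2, 2))
  expect_equal(d_at_volume(dg, mask, 100), 0)
  d995 <- d_at_volume(dg, mask, 99.5)
  expect_gte(d995, 0); expect_lte(d995, 50)
  expect_equal(d995, brute_d_at_volume(vals, 99.5))
  expect_error(d_at_volume(dg, roi_mask(array(FALSE, d), spacing = c(2, 2, 2)), 99.5),
               "empty")
})

test_that("volume-at-dose uses an inclusive threshold at 95% of 51.6 = 49.02 Gy", {
  d <- c(5, 5, 4)
  mask <- roi_mask(array(TRUE, d), spacing = c(2, 2, 2))
  lo <- dose_grid(array(10, d), spacing = c(2, 2, 2))
  expect_equal(v_at_dose_abs(lo, mask, 95, 51.6), 0)
  hi <- dose_grid(array(50, d), spacing = c(2, 2, 2))
  expect_equal(v_at_dose_abs(hi, mask, 95, 51.6), mask_volume_cm3(mask))
  # the cutoff is exactly 49.02 Gy and the comparison is inclusive
  at <- dose_grid(array(49.02, d), spacing = c(2, 2, 2))
  expect_equal(v_at_dose_abs(at, mask, 95, 51.6), mask_volume_cm3(mask))
  below <- dose_grid(array(49.02 - 1e-9, d), spacing = c(2, 2, 2))
  expect_equal(v_at_dose_abs(below, mask, 95, 51.6), 0)
  expect_error(v_at_dose_abs(at, mask, 95, 0), "positive")
})

test_that("DVH metrics equal a brute-force sort/count oracle on random masks", {
  for (s in 1:4) {
    dims <- c(10, 10, 10)
    dose <- rand_dose(dims, 100 + s, scale = 60)
    mask <- rand_mask(dims, 200 + s, p = 0.5)
    vals <- dose$dose[mask$voxels]
    vox <- prod(mask$spacing) / 1000
    expect_equal(d_at_volume(dose, mask, 99.5), brute_d_at_volume(vals, 99.5),
                 tolerance = 1e-12)
    expect_identical(d_at_volume(dose, mask, 100), min(vals))
    expect_equal(v_at_dose_abs(dose, mask, 95, 51.6),
                 brute_v_at_dose(vals, 0.95 * 51.6, vox), tolerance = 1e-12)
    expect_equal(v_at_dose_abs(dose, mask, 80, 51.6),
                 brute_v_at_dose(vals, 0.80 * 51.6, vox), tolerance = 1e-12)
  }
})

test_that("DVH metrics respect monotone dominance and V95 <= V80", {
  dims <- c(8, 8, 8)
  b <- rand_dose(dims, 11, scale = 55)
  a <- dose_grid(b$dose + 2, b$spacing)
  mask <- rand_mask(dims, 12, p = 0.6)
  expect_gte(d_at_volume(a, mask, 99.5), d_at_volume(b, mask, 99.5))
  expect_gte(d_at_volume(a, mask, 100), d_at_volume(b, mask, 100))
  expect_gte(v_at_dose_abs(a, mask, 95, 51.6), v_at_dose_abs(b, mask, 95, 51.6))
  for (dg in list(a, b))
    expect_lte(v_at_dose_abs(dg, mask, 95, 51.6), v_at_dose_abs(dg, mask, 80, 51.6))
})

test_that("delta tables are zero at baseline and match hand-computed differences", {
  # three-voxel structure with hand-checkable metrics
  d <- c(3, 1, 1)
  mask3 <- roi_mask(array(TRUE, d), spacing = c(2, 2, 2))
  st <- list(ctv = mask3, rectum = mask3, rectal_wall = mask3)
  mk <- function(v) dose_grid(array(v, d), spacing = c(2, 2, 2))
  p90 <- mk(c(4, 4.2, 4.3)); p270 <- mk(c(4.1, 4.2, 4.3))
  g90 <- mk(c(4.5, 4.2, 4.3)); g270 <- mk(c(4.1, 4.2, 4.3))
  scen <- compose_scenarios(p90, p270, g90, g270)
  deltas <- delta_metrics(scen, st, prescription_gy = 51.6, patient = "px")
  expect_true(all(deltas$delta[deltas$k == 0] == 0))
  # CTV Dmin at k: min over voxels of the summed dose, in % of baseline
  for (k in c(1, 6, 12)) {
    s <- build_schedule(k)
    tot <- s$n_p90 * p90$dose + s$n_p270 * p270$dose +
      s$n_gas90 * g90$dose + s$n_gas270 * g270$dose
    base <- 6 * p90$dose + 6 * p270$dose
    expected <- (min(tot) - min(base)) / min(base) * 100
    got <- deltas$delta[deltas$structure == "ctv" & deltas$metric == "dmin" &
                          deltas$k == k]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # identical gas and planning doses -> all deltas zero
  scen0 <- compose_scenarios(p90, p270, p90, p270)
  d0 <- delta_metrics(scen0, st, 51.6)
  expect_true(all(abs(d0$delta) < 1e-12))
})

test_that("cohort threshold crossing finds the smallest crossing k", {
  mk_cohort <- function(deltas_by_patient) {
    rows <- list()
    for (p in seq_along(deltas_by_patient)) {
      for (k in 0:12) {
        rows[[length(rows) + 1]] <- data.frame(
          patient = paste0("p", p), structure = "rectum", metric = "v95",
          k = k, value = NA_real_, delta = deltas_by_patient[[p]][k + 1],
          unit = "cm3")
      }
    }
    do.call(rbind, rows)
  }
  # all-zero cohort: never crosses
  z <- mk_cohort(list(rep(0, 13), rep(0, 13)))
  expect_true(is.na(cohort_threshold_crossing(z, 1)$k_crossing))
  # constructed cohort whose 75th percentile first exceeds 1 cm^3 at k = 8
  ramp <- function(amp) amp * (0:12) / 12
  amps <- c(0.4, 0.9, 1.5, 1.95)
  co <- mk_cohort(lapply(amps, ramp))
  q_at <- function(k) stats::quantile(vapply(amps, function(a) ramp(a)[k + 1], 0),
                                      0.75, type = 7)
  expect_true(q_at(8) > 1 && q_at(7) <= 1)
  expect_equal(cohort_threshold_crossing(co, 1)$k_crossing, 8)
  # threshold 0 with any positive delta at k = 1 returns 1
  pos <- mk_cohort(list(c(0, rep(0.2, 12)), c(0, rep(0.3, 12))))
  expect_equal(cohort_threshold_crossing(pos, 0)$k_crossing, 1)
  expect_error(cohort_threshold_crossing(z[z$patient == "p1", ], 1), ">= 2")
})
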