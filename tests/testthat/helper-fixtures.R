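# Shared fixtures, built in code. Heavy objects are memoised per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# default planning phantom (seeded)
default_phantom <- function(seed = 7) {
  memo(paste0("phantom_", seed), generate_phantom(phantom_spec(), seed = seed))
}

# phantom pair with an inserted mid-size gas pocket
default_gas_pair <- function(seed = 7, volume = 17.5) {
  memo(paste0("gaspair_", seed, "_", volume), {
    ph <- default_phantom(seed)
    ins <- insert_gas(ph$ct, ph$structures,
                      gas_spec(target_volume_cm3 = volume), seed = seed + 1)
    list(ph = ph, ins = ins)
  })
}

# small uniform-water box plan with fine spot settings (uniformity fixture)
box_plan <- function() {
  memo("box_plan", {
    wb <- water_box_phantom(shape = c(50, 50, 30), side_mm = 30)
    spr <- hu_to_spr(wb$ct)
    plan <- optimize_sfud(spr, wb$structures,
                          plan = plan_spec(spot_pitch_mm = 4, layer_step_mm = 3),
                          robust_mm = 0,
                          control = list(max_iter = 600, n_ptv = 2600,
                                        spot_margin_mm = 6, w_over = 30))
    list(wb = wb, spr = spr, plan = plan, doses = plan_field_doses(plan, spr))
  })
}

# optimised plan on the default pelvic phantom (constraint-set fixture)
phantom_plan <- function() {
  memo("phantom_plan", {
    ph <- default_phantom(7)
    spr <- hu_to_spr(ph$ct)
    plan <- optimize_sfud(spr, ph$structures)
    doses <- plan_field_doses(plan, spr)
    total <- dose_grid(6 * doses[["90"]]$rbe$dose + 6 * doses[["270"]]$rbe$dose,
                       spr$spacing, spr$origin, "rbe_weighted", "total")
    list(ph = ph, spr = spr, plan = plan, doses = doses, total = total)
  })
}

# full default cohort run (n = 18, ground-truth DVF mode); shared between the
# directional-replication checks
cohort_run <- function(seed = 1) {
  memo(paste0("cohort_", seed), run_cohort(run_config(seed = seed)))
}

# small dose grid filled with reproducible values
rand_dose <- function(dim3, seed, scale = 10) {
  set.seed(seed)
  dose_grid(array(stats::runif(prod(dim3), 0, scale), dim3), spacing = c(2, 2, 2))
}

rand_mask <- function(dim3, seed, p = 0.4) {
  set.seed(seed)
  roi_mask(array(stats::runif(prod(dim3)) < p, dim3), spacing = c(2, 2, 2))
}

# brute-force DVH oracles (independent of the implementation path)
brute_d_at_volume <- function(vals, y_percent) {
  s <- sort(vals)
  n <- length(s)
  p <- 1 - y_percent / 100
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

brute_v_at_dose <- function(vals, thr, vox_cm3) sum(vals >= thr) * vox_cm3

# brute-force Hausdorff over *all* mask voxel pairs is wrong (it must use
# surface voxels); for small masks compute over surface voxels found by
# 6-neighbour erosion, matching the definition independently
brute_hausdorff <- function(a, b) {
  surf <- function(m) {
    d <- dim(m$voxels)
    idx <- which(m$voxels, arr.ind = TRUE)
    keep <- apply(idx, 1, function(v) {
      for (ax in 1:3) for (s in c(-1, 1)) {
        w <- v; w[ax] <- w[ax] + s
        if (any(w < 1) || any(w > d)) return(TRUE)
        if (!m$voxels[w[1], w[2], w[3]]) return(TRUE)
      }
      FALSE
    })
    sweep(sweep(idx[keep, , drop = FALSE] - 1, 2, m$spacing, `*`), 2, m$origin, `+`)
  }
  pa <- surf(a); pb <- surf(b)
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                               nrow(pa) + seq_len(nrow(pb)),
                                               drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# exact Wilcoxon two-sided p by direct 2^n enumeration (independent oracle)
brute_wilcoxon_p <- function(a, b) {
  d <- (a - b); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ws <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    ws <- c(ws, sum(r[bits == 1]))
  }
  ws <- ws[-1]
  min(1, 2 * min(mean(ws <= V + 1e-9), mean(ws >= V - 1e-9)))
}
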