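#' Run configuration for the cohort pipeline
#'
#' Collects every tunable of the end-to-end simulation with defaults mirroring
#' the study conditions: 18 virtual patients, 51.6 Gy (RBE) in 12 fractions
#' from lateral opposed fields, 2-mm robust optimisation shifts, 2-mm dose
#' grid, gas HU window -1200..-120, oblique DRRs at 35/325 degrees, and
#' 1/2-cm^3 thresholds at the cohort 75th percentile.
#'
#' @param cohort_size number of virtual patients.
#' @param seed master RNG seed; per-patient seeds derive from it.
#' @param phantom a [phantom_spec()].
#' @param gas a [gas_spec()].
#' @param plan a [plan_spec()].
#' @param robust_mm robust-scenario shift (mm).
#' @param hu_window gas HU window.
#' @param drr_angles DRR projection angles (degrees).
#' @param thresholds_cm3 organ-delta thresholds (cm^3).
#' @param percentile cohort percentile for threshold crossings.
#' @param dir_mode `"ground_truth"` (use the generator's exact DVF) or
#'   `"estimate"` (deformable registration).
#' @param gas_cap_cm3 cap on drawn gas volumes (deformable capacity).
#' @param opt_control optimiser control list, see [optimize_sfud()].
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_size = 18, seed = 1,
                       phantom = phantom_spec(), gas = gas_spec(),
                       plan = plan_spec(), robust_mm = 2,
                       hu_window = c(-1200, -120), drr_angles = c(35, 325),
                       thresholds_cm3 = c(1, 2), percentile = 75,
                       dir_mode = c("ground_truth", "estimate"),
                       gas_cap_cm3 = 28, opt_control = list()) {
  dir_mode <- match.arg(dir_mode)
  if (cohort_size < 1) stop("cohort_size must be >= 1")
  if (hu_window[1] > hu_window[2]) stop("invalid HU window")
  structure(list(cohort_size = cohort_size, seed = as.integer(seed),
                 phantom = phantom, gas = gas, plan = plan,
                 robust_mm = robust_mm, hu_window = hu_window,
                 drr_angles = drr_angles, thresholds_cm3 = thresholds_cm3,
                 percentile = percentile, dir_mode = dir_mode,
                 gas_cap_cm3 = gas_cap_cm3, opt_control = opt_control),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Clinical planning dose constraints
#'
#' @return data.frame of the planning dose constraints: CTV Dmin > 47.90 Gy
#'   and D99.5% > 49.02 Gy; rectum and rectal-wall V95% < 0.80 cm^3 and
#'   V80% < 4.10 cm^3.
#' @export
plan_constraints <- function() {
  data.frame(
    structure = c("ctv", "ctv", "rectum", "rectum", "rectal_wall", "rectal_wall"),
    metric = c("dmin", "d99_5", "v95", "v80", "v95", "v80"),
    limit = c(47.90, 49.02, 0.80, 4.10, 0.80, 4.10),
    direction = c(">", ">", "<", "<", "<", "<"),
    stringsAsFactors = FALSE)
}

#' Check a total plan dose against the planning constraints
#'
#' @param plan_dose total RBE-weighted [dose_grid()] (baseline, k = 0).
#' @param structures `structure_set`.
#' @param constraints constraint table as [plan_constraints()].
#' @param prescription_gy prescription (Gy).
#' @return data.frame with measured values and a logical `pass` per
#'   constraint.
#' @export
validate_constraints <- function(plan_dose, structures,
                                 constraints = plan_constraints(),
                                 prescription_gy = 51.6) {
  res <- constraints
  res$measured <- NA_real_
  for (i in seq_len(nrow(res))) {
    mask <- structures[[res$structure[i]]]
    res$measured[i] <- metric_value(plan_dose, mask, res$metric[i],
                                    prescription_gy)
  }
  res$pass <- ifelse(res$direction == ">", res$measured > res$limit,
                     res$measured < res$limit)
  res
}

simulate_patient <- function(config, i, verbose = FALSE) {
  # derived seed kept inside the 32-bit integer range
  seed_i <- as.integer((as.numeric(config$seed) * 1000 + i) %% 2147483647)
  msg <- function(...) if (verbose) message(sprintf("[patient %02d] ", i), sprintf(...))
  ph <- generate_phantom(config$phantom, seed = seed_i)
  st <- ph$structures
  vol_draw <- with_seed(seed_i + 500L, sample_gas_volumes(1, config$gas))
  target <- min(vol_draw, config$gas_cap_cm3)
  gspec <- config$gas
  gspec$target_volume_cm3 <- target
  ins <- insert_gas(ph$ct, st, gspec, seed = seed_i + 600L)
  msg("gas target %.1f cm^3, achieved %.1f cm^3", target, ins$achieved_volume_cm3)

  spr_p <- hu_to_spr(ph$ct)
  plan <- optimize_sfud(spr_p, st, config$plan, robust_mm = config$robust_mm,
                        control = config$opt_control)
  doses_p <- plan_field_doses(plan, spr_p)
  spr_g <- hu_to_spr(ins$gasct)
  doses_g <- recalc_plan(plan, spr_g)

  dvf <- if (config$dir_mode == "ground_truth") ins$dvf
  else deformable_register(ph$ct, ins$gasct,
                           structures = list(list(fixed = st$rectum,
                                                  moving = ins$rectum_gas)))
  angs <- as.character(config$plan$beam_angles)
  gas_warp <- lapply(angs, function(a) warp_dose(doses_g[[a]]$rbe, dvf))
  names(gas_warp) <- angs
  scen <- compose_scenarios(doses_p[[angs[1]]]$rbe, doses_p[[angs[2]]]$rbe,
                            gas_warp[[angs[1]]], gas_warp[[angs[2]]])
  pid <- sprintf("p%02d", i)
  deltas <- delta_metrics(scen, st, config$plan$prescription_gy, patient = pid)
  constraints <- validate_constraints(scen[[1]], st,
                                      prescription_gy = config$plan$prescription_gy)

  # DRR indicators, averaged over the configured oblique angles
  per_angle <- lapply(config$drr_angles, function(a) {
    geom <- drr_geometry(a)
    gas_area <- extract_gas_area(ins$gasct, ins$rectum_gas, geom,
                                 hu_window = config$hu_window)
    compute_indicators(gas_area, project_roi(st$ptv, geom),
                       project_roi(st$rectum, geom))
  })
  ind <- data.frame(
    patient = pid,
    d_rectum_volume_cm3 = mask_volume_cm3(ins$rectum_gas) - mask_volume_cm3(st$rectum),
    d_gas_volume_cm3 = gas_volume(ins$gasct, ins$rectum_gas, config$hu_window) -
      gas_volume(ph$ct, st$rectum, config$hu_window),
    drr_gas_side_cm = mean(vapply(per_angle, `[[`, 0, "drr_gas_side")),
    drr_gas_si_cm = mean(vapply(per_angle, `[[`, 0, "drr_gas_si")),
    drr_gas_area_cm2 = mean(vapply(per_angle, `[[`, 0, "drr_gas_area")),
    stringsAsFactors = FALSE)

  dir_quality <- list(
    dice_rectum = dice(warp_mask(ins$rectum_gas, dvf), st$rectum),
    hausdorff_rectum = hausdorff(warp_mask(ins$rectum_gas, dvf), st$rectum))

  list(patient = pid, deltas = deltas, indicators = ind,
       constraints = constraints, dir_quality = dir_quality,
       gas_volume_cm3 = gas_volume(ins$gasct, ins$rectum_gas, config$hu_window),
       gas_volume_pct_cm3 = gas_volume(ph$ct, st$rectum, config$hu_window),
       per_angle = per_angle)
}

#' Run the full cohort pipeline
#'
#' For each virtual patient: generate the planning phantom, insert a
#' cohort-sampled gas pocket, optimise the robust SFUD plan, recalculate it
#' on the gas CT, warp the gas doses back through the displacement field,
#' compose the 13 fraction scenarios, evaluate DVH deltas, extract DRR gas
#' indicators, then assemble cohort statistics: threshold crossings at the
#' configured percentile, signed-rank tests per metric and k, and the
#' correlation table between k = 12 DVH changes and the five indicators.
#'
#' @param config a [run_config()].
#' @param verbose print per-patient progress.
#' @return object of class `gasfx_run`.
#' @export
run_cohort <- function(config = run_config(), verbose = FALSE) {
  t0 <- Sys.time()
  patients <- lapply(seq_len(config$cohort_size),
                     function(i) simulate_patient(config, i, verbose))
  deltas <- do.call(rbind, lapply(patients, `[[`, "deltas"))
  indicators <- do.call(rbind, lapply(patients, `[[`, "indicators"))

  crossings <- lapply(config$thresholds_cm3, function(th) {
    if (config$cohort_size >= 2)
      cohort_threshold_crossing(deltas, th, config$percentile)
    else NULL
  })
  names(crossings) <- paste0("cm3_", config$thresholds_cm3)

  # signed-rank tests of scenario values vs baseline per metric and k
  tests <- NULL
  if (config$cohort_size >= 2) {
    combos <- unique(deltas[, c("structure", "metric")])
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      sel <- deltas$structure == combos$structure[i] &
        deltas$metric == combos$metric[i]
      v0 <- deltas$value[sel & deltas$k == 0]
      for (k in 1:12) {
        vk <- deltas$value[sel & deltas$k == k]
        # sub-nanoGray differences are floating-point noise, treated as ties
        p <- tryCatch(wilcoxon_signed_rank(round(vk, 9), round(v0, 9))$p_value,
                      error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          structure = combos$structure[i], metric = combos$metric[i],
          k = k, p_value = p, stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
  }

  correlations <- NULL
  if (config$cohort_size >= 3) {
    d12 <- deltas[deltas$k == 12, ]
    d12$row <- paste(d12$structure, d12$metric, sep = "_")
    correlations <- tryCatch(
      build_correlation_table(d12[, c("patient", "row", "delta")], indicators),
      error = function(e) NULL)
  }

  prov <- list(seed = config$seed, config_hash = config_hash(config),
               r_version = as.character(getRversion()),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(config = config, patients = patients, deltas = deltas,
                 indicators = indicators, crossings = crossings,
                 tests = tests, correlations = correlations,
                 mkm_to_lem = mkm_to_lem_factor(config$plan$per_fx_gy),
                 provenance = prov),
            class = "gasfx_run")
}

#' @export
print.gasfx_run <- function(x, ...) {
  cat(sprintf("<gasfx_run> %d patients, %.1f Gy / %d fx, DIR mode '%s'\n",
              x$config$cohort_size, x$config$plan$prescription_gy,
              x$config$plan$n_fx, x$config$dir_mode))
  cat(sprintf("  gas volume (gas CT): mean %.1f cm^3\n",
              mean(vapply(x$patients, `[[`, 0, "gas_volume_cm3"))))
  cat(sprintf("  elapsed %.1f s, config %s\n", x$provenance$elapsed_s,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

#' @export
summary.gasfx_run <- function(object, ...) {
  x <- object
  cat("Cohort summary\n==============\n")
  print(x)
  cat("\nThreshold crossings (smallest k, cohort", x$config$percentile,
      "th percentile):\n")
  for (nm in names(x$crossings)) {
    cat(" ", nm, "\n")
    if (!is.null(x$crossings[[nm]])) {
      cr <- x$crossings[[nm]]
      for (i in seq_len(nrow(cr)))
        cat(sprintf("    %-12s %-6s k = %s\n", cr$structure[i], cr$metric[i],
                    ifelse(is.na(cr$k_crossing[i]), "never", cr$k_crossing[i])))
    }
  }
  if (!is.null(x$correlations)) {
    cat("\n"); print(x$correlations)
  }
  cat(sprintf("\nMKM->LEM conversion factor at %.2f Gy/fx: %.4f\n",
              x$config$plan$per_fx_gy, x$mkm_to_lem))
  invisible(x)
}
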