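#' Fraction schedule for k gas-affected fractions
#'
#' The 12-fraction course uses lateral opposed fields, 6 fractions each.
#' Gas-affected fractions are added starting from the 90-degree field, with
#' the extra 90-degree fraction on odd counts: `n_gas90 = ceiling(k/2)`,
#' `n_gas270 = floor(k/2)`; the remainder are planning-CT fractions.
#'
#' @param k_gas integer in `[0, 12]`.
#' @return list of class `fraction_schedule` with counts `n_gas90`,
#'   `n_gas270`, `n_p90`, `n_p270`.
#' @export
build_schedule <- function(k_gas) {
  if (length(k_gas) != 1 || is.na(k_gas) || k_gas < 0 || k_gas > 12 ||
      k_gas != round(k_gas))
    stop("k_gas must be an integer in [0, 12]")
  n_gas90 <- ceiling(k_gas / 2)
  n_gas270 <- floor(k_gas / 2)
  structure(list(n_gas90 = n_gas90, n_gas270 = n_gas270,
                 n_p90 = 6 - n_gas90, n_p270 = 6 - n_gas270, k = k_gas),
            class = "fraction_schedule")
}

#' Compose the 13 scenario dose distributions
#'
#' For every k in 0..12 the summed dose is the integer combination of the
#' four per-fraction dose grids given by [build_schedule()]. All grids must
#' be congruent and on the planning-CT frame (the gas doses already warped).
#'
#' @param p90,p270,gas90,gas270 per-fraction [dose_grid()]s.
#' @return list of class `scenario_set`: element `k0`..`k12`, each a
#'   [dose_grid()] with `per = "total"`; attribute `schedules`.
#' @export
compose_scenarios <- function(p90, p270, gas90, gas270) {
  grids <- list(p90, p270, gas90, gas270)
  for (g in grids[-1]) {
    if (!identical(dim(g$dose), dim(p90$dose)) ||
        max(abs(g$spacing - p90$spacing)) > 1e-9)
      stop("per-fraction grids are not congruent")
  }
  out <- vector("list", 13)
  schedules <- vector("list", 13)
  for (k in 0:12) {
    s <- build_schedule(k)
    total <- s$n_p90 * p90$dose + s$n_p270 * p270$dose +
      s$n_gas90 * gas90$dose + s$n_gas270 * gas270$dose
    out[[k + 1]] <- dose_grid(total, p90$spacing, p90$origin,
                              label = p90$label, per = "total")
    schedules[[k + 1]] <- s
  }
  names(out) <- paste0("k", 0:12)
  structure(out, class = "scenario_set", schedules = schedules)
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> %d summed dose distributions (k = 0..%d)\n",
              length(x), length(x) - 1))
  invisible(x)
}
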