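#' Dose at volume (Dy%)
#'
#' The dose received by at least `y_percent` of the structure volume: the
#' `(1 - y)` order-statistic quantile of the voxel doses, with linear
#' interpolation between order statistics (quantile type 7). `y = 100`
#' returns the minimum voxel dose (Dmin).
#'
#' @param dose a [dose_grid()].
#' @param mask nonempty congruent [roi_mask()].
#' @param y_percent volume percentage in `(0, 100]`.
#' @return dose in Gy.
#' @export
d_at_volume <- function(dose, mask, y_percent) {
  if (!any(mask$voxels)) stop("mask is empty")
  if (!identical(dim(dose$dose), dim(mask$voxels)))
    stop("grids are not congruent")
  if (y_percent <= 0 || y_percent > 100) stop("y_percent must be in (0, 100]")
  v <- dose$dose[mask$voxels]
  unname(stats::quantile(v, probs = 1 - y_percent / 100, type = 7))
}

#' Absolute volume at dose (Vx%)
#'
#' The absolute volume (cm^3) of mask voxels receiving at least `x_percent`
#' of the prescription. The threshold comparison is inclusive (>=).
#'
#' @param dose a [dose_grid()].
#' @param mask congruent [roi_mask()].
#' @param x_percent percentage of the prescription.
#' @param prescription_gy prescription dose (Gy), > 0.
#' @return volume in cm^3.
#' @export
v_at_dose_abs <- function(dose, mask, x_percent, prescription_gy) {
  if (prescription_gy <= 0) stop("prescription must be positive")
  if (!identical(dim(dose$dose), dim(mask$voxels)))
    stop("grids are not congruent")
  thr <- x_percent / 100 * prescription_gy
  sum(dose$dose[mask$voxels] >= thr) * prod(mask$spacing) / 1000
}

#' DVH metric set for one structure
#'
#' Dmin, D99.5%, V95% and V80% against a prescription.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [roi_mask()].
#' @param prescription_gy prescription (Gy).
#' @return list of class `dvh_metrics`.
#' @export
dvh_metrics <- function(dose, mask, prescription_gy = 51.6) {
  out <- list(structure = mask$name,
              dmin = d_at_volume(dose, mask, 100),
              d99_5 = d_at_volume(dose, mask, 99.5),
              v95 = v_at_dose_abs(dose, mask, 95, prescription_gy),
              v80 = v_at_dose_abs(dose, mask, 80, prescription_gy),
              prescription_gy = prescription_gy)
  class(out) <- "dvh_metrics"
  out
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> %s: Dmin %.2f Gy, D99.5%% %.2f Gy, V95%% %.2f cm^3, V80%% %.2f cm^3\n",
              x$structure, x$dmin, x$d99_5, x$v95, x$v80))
  invisible(x)
}

#' Cumulative DVH curve
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [roi_mask()].
#' @param n_bins number of dose bins.
#' @return data.frame `dose_gy`, `volume_cm3` (volume receiving >= dose).
#' @export
dvh_curve <- function(dose, mask, n_bins = 200) {
  v <- dose$dose[mask$voxels]
  vox <- prod(mask$spacing) / 1000
  grid <- seq(0, max(v) * 1.02 + 1e-9, length.out = n_bins)
  data.frame(dose_gy = grid,
             volume_cm3 = vapply(grid, function(t) sum(v >= t) * vox, 0))
}

#' DVH parameter deltas versus the initial plan
#'
#' CTV deltas (Dmin, D99.5%) are expressed in percent of the baseline value;
#' rectum and rectal-wall deltas (V95%, V80%) in absolute cm^3. The baseline
#' is the k = 0 scenario, so all deltas at k = 0 are exactly 0.
#'
#' @param scenarios a `scenario_set` from [compose_scenarios()].
#' @param structures `structure_set` (uses `ctv`, `rectum`, `rectal_wall`).
#' @param prescription_gy prescription (Gy).
#' @param patient optional patient label.
#' @return data.frame with columns `patient`, `structure`, `metric`, `k`,
#'   `value`, `delta`, `unit`.
#' @export
delta_metrics <- function(scenarios, structures, prescription_gy = 51.6,
                          patient = "p1") {
  specs <- list(
    list(structure = "ctv", mask = structures$ctv, metric = "dmin", unit = "%"),
    list(structure = "ctv", mask = structures$ctv, metric = "d99_5", unit = "%"),
    list(structure = "rectum", mask = structures$rectum, metric = "v95", unit = "cm3"),
    list(structure = "rectum", mask = structures$rectum, metric = "v80", unit = "cm3"),
    list(structure = "rectal_wall", mask = structures$rectal_wall, metric = "v95", unit = "cm3"),
    list(structure = "rectal_wall", mask = structures$rectal_wall, metric = "v80", unit = "cm3"))
  rows <- list()
  base <- lapply(specs, function(s)
    metric_value(scenarios[[1]], s$mask, s$metric, prescription_gy))
  for (k in 0:(length(scenarios) - 1)) {
    dg <- scenarios[[k + 1]]
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      val <- metric_value(dg, s$mask, s$metric, prescription_gy)
      delta <- if (s$unit == "%") {
        if (abs(base[[i]]) < 1e-12) NA_real_ else (val - base[[i]]) / base[[i]] * 100
      } else val - base[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        patient = patient, structure = s$structure, metric = s$metric,
        k = k, value = val, delta = delta, unit = s$unit,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

metric_value <- function(dose, mask, metric, prescription_gy) {
  switch(metric,
         dmin = d_at_volume(dose, mask, 100),
         d99_5 = d_at_volume(dose, mask, 99.5),
         v95 = v_at_dose_abs(dose, mask, 95, prescription_gy),
         v80 = v_at_dose_abs(dose, mask, 80, prescription_gy),
         stop("unknown metric: ", metric))
}

#' Smallest k whose cohort 75th-percentile delta exceeds a threshold
#'
#' For each (structure, metric) pair, computes the cohort percentile of the
#' delta at every k and returns the smallest k at which it exceeds
#' (strictly) the threshold, or `NA` if it never does. Percentiles use linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param deltas combined [delta_metrics()] data.frame over a cohort
#'   (>= 2 patients).
#' @param threshold_cm3 threshold on the delta (1 or 2 cm^3 for the organ
#'   metrics).
#' @param percentile cohort percentile (75 by default).
#' @param metrics which metrics to evaluate (organ volume metrics by default).
#' @return data.frame `structure`, `metric`, `k_crossing` (NA if never).
#' @export
cohort_threshold_crossing <- function(deltas, threshold_cm3 = 1, percentile = 75,
                                      metrics = c("v95", "v80")) {
  if (length(unique(deltas$patient)) < 2) stop("cohort must have >= 2 patients")
  combos <- unique(deltas[deltas$metric %in% metrics, c("structure", "metric")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- deltas$structure == combos$structure[i] & deltas$metric == combos$metric[i]
    ks <- sort(unique(deltas$k[sel]))
    k_cross <- NA_integer_
    for (k in ks) {
      q <- stats::quantile(deltas$delta[sel & deltas$k == k],
                           probs = percentile / 100, type = 7, na.rm = TRUE)
      if (is.finite(q) && q > threshold_cm3) { k_cross <- k; break }
    }
    data.frame(structure = combos$structure[i], metric = combos$metric[i],
               k_crossing = k_cross, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
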