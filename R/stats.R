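#' Pearson product-moment correlation
#'
#' Thin validated wrapper around the standard estimator. Errors on
#' constant input, where the coefficient is undefined.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classic signed-rank handling). For n <= 12 non-zero pairs the null
#' distribution is enumerated exactly over all 2^n sign patterns (valid under
#' ties, which keep their averaged ranks); for larger n a normal
#' approximation with tie correction is used.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list of class `signed_rank_test`: `statistic` (V, sum of positive
#'   ranks), `p_value`, `n` (pairs after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 12) {
    # exact: all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_le <- mean(w_all <= V + 1e-9)
    p_ge <- mean(w_all >= V - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = V, p_value = p, n = n, method = method),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): V = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n, x$p_value))
  invisible(x)
}

#' MKM to LEM dose-conversion factor
#'
#' Linear interpolation between the published scalar conversion anchors for
#' fraction doses of 4.20 Gy (factor 1.09) and 4.38 Gy (factor 1.07); no
#' extrapolation outside the anchor span.
#'
#' @param dose_per_fx_gy fraction dose (Gy), within the anchor span.
#' @param anchors 2-column matrix `(dose, factor)`.
#' @return conversion factor.
#' @export
mkm_to_lem_factor <- function(dose_per_fx_gy,
                              anchors = cbind(c(4.20, 4.38), c(1.09, 1.07))) {
  lo <- min(anchors[, 1]); hi <- max(anchors[, 1])
  if (any(dose_per_fx_gy < lo - 1e-12) || any(dose_per_fx_gy > hi + 1e-12))
    stop(sprintf("dose per fraction outside the anchor span [%.2f, %.2f]", lo, hi))
  stats::approx(anchors[, 1], anchors[, 2], xout = dose_per_fx_gy)$y
}

#' Correlation table between DVH deltas and gas indicators
#'
#' Pearson correlations between each DVH parameter change (at the
#' all-gas-fraction scenario, k = 12) and five indicators: rectal volume
#' change, rectal gas volume change, and the three DRR indicators. Each row
#' is flagged with the indicator achieving the highest coefficient.
#'
#' @param dvh_deltas data.frame with columns `patient`, `row` (metric label)
#'   and `delta`.
#' @param indicators data.frame with column `patient` plus one column per
#'   indicator.
#' @return object of class `correlation_table`: matrix `r` (rows = DVH
#'   metrics, columns = indicators), character vector `max_indicator`.
#' @export
build_correlation_table <- function(dvh_deltas, indicators) {
  stopifnot(all(c("patient", "row", "delta") %in% names(dvh_deltas)))
  ind_cols <- setdiff(names(indicators), "patient")
  rows <- unique(dvh_deltas$row)
  if (nrow(indicators) < 3) stop("cohort must have n >= 3")
  r <- matrix(NA_real_, length(rows), length(ind_cols),
              dimnames = list(rows, ind_cols))
  for (i in seq_along(rows)) {
    dd <- dvh_deltas[dvh_deltas$row == rows[i], c("patient", "delta")]
    m <- merge(dd, indicators, by = "patient")
    for (j in seq_along(ind_cols)) {
      x <- m$delta; y <- m[[ind_cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
        r[i, j] <- stats::cor(x[ok], y[ok])
    }
  }
  max_ind <- apply(r, 1, function(z)
    if (all(is.na(z))) NA_character_ else colnames(r)[which.max(z)])
  structure(list(r = r, max_indicator = max_ind), class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("Correlation coefficients (rows: DVH parameter changes at k = 12)\n")
  m <- formatC(x$r, format = "f", digits = 3)
  m[is.na(x$r)] <- "  --"
  for (i in seq_len(nrow(x$r))) {
    flag <- ifelse(colnames(x$r) == x$max_indicator[i] &
                     !is.na(x$max_indicator[i]), "*", " ")
    cat(sprintf("  %-22s %s\n", rownames(x$r)[i],
                paste(sprintf("%s%s", m[i, ], flag), collapse = "  ")))
  }
  cat("  columns:", paste(colnames(x$r), collapse = ", "), "\n")
  cat("  * highest coefficient in the row\n")
  invisible(x)
}
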