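#' Read and write volumes, masks and displacement fields as NIfTI
#'
#' Volumes and doses are stored as floating-point NIfTI with the grid spacing
#' in the header; masks as unsigned 8-bit 0/1; displacement fields as
#' 4-D NIfTI with three components (mm) in the fourth dimension.
#'
#' @param vol a [ct_volume()] or [dose_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "dose_grid")) vol$dose else vol$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing spacing override when the header is incomplete.
#' @export
read_volume <- function(path, spacing = NULL) {
  img <- RNifti::readNifti(path)
  sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
  ct_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp)
}

#' @rdname write_volume
#' @param mask an [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume
#' @param name mask name on reading.
#' @export
read_mask <- function(path, name = "roi", spacing = NULL) {
  img <- RNifti::readNifti(path)
  sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
  roi_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]), name = name, spacing = sp)
}

#' @rdname write_volume
#' @param dvf a `dvf` displacement field.
#' @export
write_dvf <- function(dvf, path) {
  img <- RNifti::asNifti(dvf$field)
  RNifti::pixdim(img) <- c(dvf$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_dvf <- function(path, spacing = NULL) {
  img <- RNifti::readNifti(path)
  sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
  structure(list(field = array(as.numeric(img), dim(img)),
                 spacing = sp, origin = c(0, 0, 0)), class = "dvf")
}

#' Serialise a rigid transform to JSON
#'
#' @param tr a [rigid_transform()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_rigid <- function(tr, path) {
  jsonlite::write_json(list(translation_mm = tr$translation_mm,
                            rotation_deg = tr$rotation_deg,
                            center_mm = tr$center_mm,
                            order = "Rz Ry Rx then translate"),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$translation_mm, j$rotation_deg, j$center_mm)
}

#' Write delta metrics and indicators of a cohort run to CSV
#'
#' @param run a `gasfx_run`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_tables <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$deltas, file.path(dir, "dvh_deltas.csv"), row.names = FALSE)
  utils::write.csv(run$indicators, file.path(dir, "gas_indicators.csv"),
                   row.names = FALSE)
  if (!is.null(run$tests))
    utils::write.csv(run$tests, file.path(dir, "signed_rank_tests.csv"),
                     row.names = FALSE)
  if (!is.null(run$correlations)) {
    r <- as.data.frame(run$correlations$r)
    r$max_indicator <- run$correlations$max_indicator
    utils::write.csv(r, file.path(dir, "correlation_table.csv"))
  }
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a DRR image as 16-bit-equivalent PNG
#'
#' Pixel values are rescaled to `[0, 1]` over the image range; the u axis maps
#' to image columns and the SI axis to rows (superior at the top).
#'
#' @param drr a `drr_image` from [project_drr()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_drr_png <- function(drr, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG images")
  px <- drr$pixels
  rng <- range(px)
  norm <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  # rows = SI (superior first), columns = u
  png::writePNG(t(norm)[rev(seq_len(ncol(norm))), , drop = FALSE], path)
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Reads a YAML file whose top-level keys override the [run_config()]
#' defaults (`cohort_size`, `seed`, `dir_mode`, `prescription_gy`, `n_fx`,
#' `drr_angles`, `hu_window`, `thresholds_cm3`, `percentile`, `robust_mm`).
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  plan <- plan_spec(prescription_gy = y$prescription_gy %||% 51.6,
                    n_fx = y$n_fx %||% 12)
  run_config(cohort_size = y$cohort_size %||% 18,
             seed = y$seed %||% 1,
             plan = plan,
             robust_mm = y$robust_mm %||% 2,
             hu_window = unlist(y$hu_window %||% c(-1200, -120)),
             drr_angles = unlist(y$drr_angles %||% c(35, 325)),
             thresholds_cm3 = unlist(y$thresholds_cm3 %||% c(1, 2)),
             percentile = y$percentile %||% 75,
             dir_mode = y$dir_mode %||% "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
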