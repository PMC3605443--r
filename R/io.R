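#' Read and write cohort CSV files
#'
#' The cohort schema is a UTF-8, comma-separated, header-first CSV with '.'
#' decimals. Fractions are stored as decimals and visual fat as percent; the
#' column suffixes `_pct` / `_frac` disambiguate the two conventions.
#' Mandatory columns: `id`, `group`, `his_vis_pct`, `his_morph_frac`,
#' `alpha_s1`, `alpha_s2`, `alpha_s3`, `alpha`, `lic_mg_g`, `metavir`,
#' `bmi`, `diagnosis`. Unknown columns are preserved. Histology and staging
#' columns may be `NA` for controls.
#'
#' Validation is strict: a malformed file fails with the offending row
#' numbers rather than propagating silently (`alpha` and `his_morph_frac`
#' must lie in `[0, 1]`, `his_vis_pct` in `[0, 100]`, `group` must be
#' `patient` or `control`, and `alpha` must equal the mean of the three
#' slice values to within 1e-6).
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "his_vis_pct", "his_morph_frac",
            "alpha_s1", "alpha_s2", "alpha_s3", "alpha",
            "lic_mg_g", "metavir", "bmi", "diagnosis")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort file is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num_cols <- c("his_vis_pct", "his_morph_frac", "alpha_s1", "alpha_s2",
                "alpha_s3", "alpha", "lic_mg_g", "bmi")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("column `%s` contains non-numeric values", cl), call. = FALSE)
    }
  }
  .bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop(sprintf("%s on row(s): %s", what,
                   paste(rows, collapse = ", ")), call. = FALSE)
    }
  }
  .bad_rows(!df$group %in% c("patient", "control"),
            "`group` must be 'patient' or 'control'")
  .bad_rows(!is.na(df$alpha) & (df$alpha < 0 | df$alpha > 1),
            "`alpha` outside [0, 1]")
  .bad_rows(!is.na(df$his_morph_frac) &
              (df$his_morph_frac < 0 | df$his_morph_frac > 1),
            "`his_morph_frac` outside [0, 1]")
  .bad_rows(!is.na(df$his_vis_pct) &
              (df$his_vis_pct < 0 | df$his_vis_pct > 100),
            "`his_vis_pct` outside [0, 100]")
  sl <- as.matrix(df[, c("alpha_s1", "alpha_s2", "alpha_s3")])
  ok <- is.na(df$alpha) | apply(is.na(sl), 1, any) |
    abs(rowMeans(sl) - df$alpha) <= 1e-6
  .bad_rows(!ok, "`alpha` is not the mean of the three slice values")
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @return `write_cohort()`: the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom and its ground truth to disk
#'
#' The colour image and the masks are written as TIFF (requires the `tiff`
#' package), together with a JSON sidecar carrying the generating spec and
#' the ground-truth fat fraction.
#'
#' @param phantom A `histology_phantom`.
#' @param prefix Output path prefix; files `<prefix>.tif`,
#'   `<prefix>_fat_mask.tif`, `<prefix>_tissue_mask.tif`,
#'   `<prefix>.json` are produced.
#' @return Character vector of the files written, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "histology_phantom"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing phantom images requires the `tiff` package", call. = FALSE)
  }
  img_path <- paste0(prefix, ".tif")
  fat_path <- paste0(prefix, "_fat_mask.tif")
  tis_path <- paste0(prefix, "_tissue_mask.tif")
  json_path <- paste0(prefix, ".json")
  tiff::writeTIFF(phantom$image / 255, img_path)
  tiff::writeTIFF(matrix(as.numeric(phantom$fat_mask), nrow(phantom$fat_mask)),
                  fat_path)
  tiff::writeTIFF(matrix(as.numeric(phantom$tissue_mask), nrow(phantom$tissue_mask)),
                  tis_path)
  jsonlite::write_json(
    list(spec = unclass(phantom$spec),
         true_areal_fat_fraction = phantom$true_areal_fat_fraction),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, fat_path, tis_path, json_path))
}

#' Read an RGB raster from a TIFF or PNG file
#'
#' Returns the 8-bit RGB array format the morphometry functions consume.
#'
#' @param path Image path (.tif/.tiff needs the `tiff` package, .png the
#'   `png` package).
#' @return Numeric array `c(rows, cols, 3)` with values in 0-255.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the `png` package", call. = FALSE)
    }
    png::readPNG(path)
  } else {
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  }
  if (length(dim(arr)) == 2) {
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  }
  round(arr[, , 1:3, drop = FALSE] * 255)
}

#' Serialize a calibration model or diagnostic report to JSON
#'
#' @param x A `calibration_model` or `diagnostic_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- if (inherits(x, "diagnostic_report")) {
    list(roc_vis = x$roc_vis, roc_morph = x$roc_morph,
         calibration = unclass(x$calibration),
         link = unclass(x$link),
         morph_cutoffs = as.list(x$morph_cutoffs),
         agreement = unclass(x$agreement),
         control_pi = if (is.null(x$control_pi)) NULL else unclass(x$control_pi),
         n_patients = x$n_patients, n_controls = x$n_controls)
  } else if (inherits(x, "calibration_model")) {
    unclass(x)
  } else {
    stop("unsupported object type", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
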