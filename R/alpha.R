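#' Triple-echo ROI intensities
#'
#' Container for the mean ROI intensity of one liver slice at the three
#' gradient-echo times of an opposed-phase / in-phase / opposed-phase
#' acquisition. At 1.5 T the water-fat chemical shift puts the two species in
#' opposed phase at 2.38 ms and 7.14 ms and in phase at 4.76 ms, which are the
#' default echo times.
#'
#' @param op1 Mean ROI intensity of the first opposed-phase echo (at `te1`).
#' @param ip Mean ROI intensity of the in-phase echo (at `te2`).
#' @param op2 Mean ROI intensity of the second opposed-phase echo (at `te3`).
#' @param te1,te2,te3 Echo times in ms; must be strictly increasing.
#' @return An object of class `echo_triple`.
#' @examples
#' echo_triple(op1 = 88.8, ip = 78.8, op2 = 70.0)
#' @export
echo_triple <- function(op1, ip, op2, te1 = 2.38, te2 = 4.76, te3 = 7.14) {
  .check_num(op1, "op1", lo = 0)
  .check_num(ip, "ip", lo = 0)
  .check_num(op2, "op2", lo = 0)
  .check_num(te1, "te1", lo = 0)
  .check_num(te2, "te2", lo = 0)
  .check_num(te3, "te3", lo = 0)
  if (!(te1 < te2 && te2 < te3)) {
    stop("echo times must satisfy te1 < te2 < te3", call. = FALSE)
  }
  structure(list(op1 = op1, ip = ip, op2 = op2,
                 te1 = te1, te2 = te2, te3 = te3),
            class = "echo_triple")
}

#' Estimate T2* from the two opposed-phase echoes
#'
#' The two opposed-phase echoes carry the same water-fat contrast and differ
#' only by T2* decay, so the mono-exponential decay constant follows from their
#' ratio: `T2* = (te3 - te1) / log(op1 / op2)`.
#'
#' When `op1 <= op2` the ratio implies zero or negative decay, which is
#' non-physical; near-equal echoes can be inverted by noise at low fat. In
#' that case `Inf` is returned as a no-correction sentinel (a decay factor of
#' exactly 1 in [compute_alpha()]) rather than failing the slice.
#'
#' @param triple An [echo_triple()].
#' @return T2* in ms, or `Inf` when no decay is measurable.
#' @examples
#' estimate_t2star(echo_triple(op1 = 17.756, ip = 78.821, op2 = 13.997))
#' @export
estimate_t2star <- function(triple) {
  stopifnot(inherits(triple, "echo_triple"))
  if (triple$op1 <= 0 || triple$op2 <= 0) {
    stop("opposed-phase intensities must be strictly positive to estimate T2*",
         call. = FALSE)
  }
  if (triple$op1 <= triple$op2) {
    return(Inf)
  }
  (triple$te3 - triple$te1) / log(triple$op1 / triple$op2)
}

#' Compute the fat-sensitive parameter alpha for one slice
#'
#' The first opposed-phase intensity is corrected for T2* decay to the
#' in-phase echo time and combined with the in-phase intensity in the
#' two-point Dixon fraction:
#'
#' `alpha = (IP - OP1 * exp(-(te2 - te1) / T2*)) / (2 * IP)`
#'
#' For a water-dominant voxel `IP ~ W + F` and the corrected `OP1 ~ W - F`, so
#' alpha estimates the (signal-weighted) fat fraction `F / (W + F)`. Raw
#' values outside `[0, 1]` — possible under noise — are clamped to the range.
#'
#' @param triple An [echo_triple()].
#' @param t2star T2* in ms, typically from [estimate_t2star()]; `Inf` applies
#'   no decay correction.
#' @return alpha, a dimensionless value in `[0, 1]`.
#' @examples
#' tr <- echo_triple(op1 = 17.756, ip = 78.821, op2 = 13.997)
#' compute_alpha(tr, estimate_t2star(tr))
#' @export
compute_alpha <- function(triple, t2star) {
  stopifnot(inherits(triple, "echo_triple"))
  .check_num(t2star, "t2star")
  if (t2star <= 0) stop("`t2star` must be positive (or Inf)", call. = FALSE)
  if (triple$ip <= 0) {
    stop("in-phase intensity must be strictly positive", call. = FALSE)
  }
  decay <- exp(-(triple$te2 - triple$te1) / t2star)
  a <- (triple$ip - triple$op1 * decay) / (2 * triple$ip)
  min(max(a, 0), 1)
}

#' Per-slice alpha with T2* correction, averaged across slices
#'
#' Computes T2* and alpha independently for each slice and reports their
#' arithmetic mean, the per-slice values, and whether the T2* correction was
#' applicable (slices whose opposed-phase echoes showed no decay fall back to
#' an uncorrected alpha and are flagged).
#'
#' @param triples A list of 1 to 3 [echo_triple()] objects, one per axial
#'   slice. Fewer than 3 slices triggers a warning but is accepted.
#' @return An object of class `alpha_result` with fields `alpha`
#'   (mean across slices), `alpha_per_slice`, `t2star_per_slice` and
#'   `correction_applied` (logical per slice).
#' @examples
#' tr <- echo_triple(op1 = 17.756, ip = 78.821, op2 = 13.997)
#' alpha_from_slices(list(tr, tr, tr))$alpha
#' @export
alpha_from_slices <- function(triples) {
  if (inherits(triples, "echo_triple")) triples <- list(triples)
  if (length(triples) == 0) stop("no slices supplied", call. = FALSE)
  if (length(triples) > 3) {
    stop("at most 3 slices are expected", call. = FALSE)
  }
  if (length(triples) < 3) {
    warning(sprintf("only %d slice(s) supplied; alpha averaged over fewer than 3 slices",
                    length(triples)), call. = FALSE)
  }
  t2 <- vapply(triples, estimate_t2star, numeric(1))
  a <- vapply(seq_along(triples),
              function(i) compute_alpha(triples[[i]], t2[i]), numeric(1))
  structure(list(alpha = mean(a),
                 alpha_per_slice = a,
                 t2star_per_slice = t2,
                 correction_applied = is.finite(t2)),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("alpha = %.4f (mean of %d slice(s): %s)\n",
              x$alpha, length(x$alpha_per_slice),
              paste(sprintf("%.4f", x$alpha_per_slice), collapse = ", ")))
  if (!all(x$correction_applied)) {
    cat(sprintf("  T2* correction not applicable on %d slice(s); decay factor 1 used\n",
                sum(!x$correction_applied)))
  }
  invisible(x)
}

#' Radius of a circular ROI of given area
#'
#' @param area_mm2 ROI area in mm^2 (the liver protocol uses about 580 mm^2).
#' @return Radius in mm.
#' @examples
#' roi_radius_mm(580)
#' @export
roi_radius_mm <- function(area_mm2) {
  .check_num(area_mm2, "area_mm2", lo = 0)
  sqrt(area_mm2 / pi)
}

#' Mean intensity over a circular region of interest
#'
#' Averages the intensity of every pixel whose centre falls inside a circle of
#' the given physical area, mirroring manual circular-ROI measurement on a
#' magnitude image.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param center Length-2 vector `(row, col)` of the ROI centre in pixel
#'   coordinates.
#' @param area_mm2 ROI area in mm^2.
#' @param pixel_spacing Pixel size in mm/pixel (isotropic).
#' @return Mean intensity over the ROI.
#' @export
roi_mean <- function(image, center, area_mm2 = 580, pixel_spacing = 300 / 256) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  .check_num(center, "center", len = 2L)
  .check_num(area_mm2, "area_mm2", lo = 0)
  .check_num(pixel_spacing, "pixel_spacing", lo = 1e-12)
  r_px <- roi_radius_mm(area_mm2) / pixel_spacing
  if (center[1] - r_px < 0.5 || center[1] + r_px > nrow(image) + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > ncol(image) + 0.5) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
  mean(image[inside])
}
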