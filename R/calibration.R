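#' Nonlinear calibration between fat volume fraction and alpha
#'
#' The MRI parameter alpha is deliberately T1-weighted, so it is not expected
#' to equal the fat volume fraction `f`. With fat and water signals weighted
#' by a lumped constant `k` (capturing proton-density and T1-weighting
#' differences), the signal fat fraction becomes
#'
#' `alpha = k * f / (k * f + (1 - f))`
#'
#' which is a strictly increasing bijection of `[0, 1]` onto itself with
#' `alpha(0) = 0`, `alpha(1) = 1`, the identity at `k = 1`, concave for
#' `k > 1`, and initial slope `d alpha / d f = k` at `f = 0` — so `k > 1`
#' amplifies contrast at low fat fractions.
#'
#' @param f Fat volume fraction(s) in `[0, 1]`; `alpha_model` is vectorised.
#' @param k Positive calibration constant.
#' @return alpha value(s) in `[0, 1]`.
#' @seealso [invert_alpha()], [fit_k()]
#' @examples
#' alpha_model(0.25, k = 2)   # 0.4
#' invert_alpha(0.4, k = 2)   # 0.25
#' @export
alpha_model <- function(f, k) {
  if (!is.numeric(f) || anyNA(f)) stop("`f` must be numeric", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("`f` must lie in [0, 1]", call. = FALSE)
  .check_num(k, "k", lo = 1e-12)
  k * f / (k * f + (1 - f))
}

#' @rdname alpha_model
#' @param alpha alpha value(s) in `[0, 1]`.
#' @export
invert_alpha <- function(alpha, k) {
  if (!is.numeric(alpha) || anyNA(alpha)) {
    stop("`alpha` must be numeric", call. = FALSE)
  }
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  .check_num(k, "k", lo = 1e-12)
  alpha / (k - alpha * (k - 1))
}

#' Fit the calibration constant k by least squares
#'
#' Minimises `sum((alpha_i - alpha_model(f_i, k))^2)` over `k` by
#' deterministic one-dimensional bounded optimisation (Brent search on
#' `(1e-3, 100]`, tolerance 1e-9; no random initialisation), and reports
#' `r^2 = 1 - SS_res / SS_tot`.
#'
#' @param alphas Observed alpha values in `[0, 1]`.
#' @param fractions Paired fat fractions in `[0, 1]` (e.g. morphometric areal
#'   fat fractions, equal to the volume fraction for thin sections).
#' @return An object of class `calibration_model` with fields `k`,
#'   `r_squared` and `n`.
#' @examples
#' f <- seq(0.01, 0.4, length.out = 20)
#' fit_k(alpha_model(f, 3), f)$k
#' @export
fit_k <- function(alphas, fractions) {
  if (length(alphas) != length(fractions)) {
    stop("`alphas` and `fractions` must have equal length", call. = FALSE)
  }
  keep <- !(is.na(alphas) | is.na(fractions))
  alphas <- alphas[keep]; fractions <- fractions[keep]
  if (length(alphas) < 3) stop("at least 3 paired observations required", call. = FALSE)
  if (any(alphas < 0 | alphas > 1)) stop("`alphas` must lie in [0, 1]", call. = FALSE)
  if (any(fractions < 0 | fractions > 1)) {
    stop("`fractions` must lie in [0, 1]", call. = FALSE)
  }
  if (all(fractions == 0)) {
    stop("all fat fractions are zero: k is unidentifiable", call. = FALSE)
  }
  if (length(unique(fractions)) < 2) {
    warning("all fat fractions identical: fit has no leverage along f",
            call. = FALSE)
  }
  sse <- function(k) sum((alphas - alpha_model(fractions, k))^2)
  opt <- optimise(sse, interval = c(1e-3, 100), tol = 1e-9)
  ss_tot <- sum((alphas - mean(alphas))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  structure(list(k = opt$minimum, r_squared = r2, n = length(alphas)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("alpha ~ k f / (k f + 1 - f): k = %.4f, r^2 = %.3f, n = %d\n",
              x$k, x$r_squared, x$n))
  invisible(x)
}

#' Linear link between morphometric and visual fat estimates
#'
#' Ordinary least-squares regression of the morphometric areal fat fraction
#' on the pathologist's visual fat percentage. Used to translate the clinical
#' visual steatosis grade boundaries into morphometric cutoffs.
#'
#' @param his_morph Morphometric areal fat fractions in `[0, 1]`.
#' @param his_vis Visual fat estimates in percent (0-100).
#' @param through_origin If `TRUE`, fit without an intercept.
#' @return An object of class `linear_link` with fields `slope` (fraction per
#'   percent), `intercept`, `r_squared` and `n`.
#' @export
fit_morph_vis_link <- function(his_morph, his_vis, through_origin = FALSE) {
  keep <- !(is.na(his_morph) | is.na(his_vis))
  his_morph <- his_morph[keep]; his_vis <- his_vis[keep]
  if (length(his_morph) < 3) stop("at least 3 paired observations required", call. = FALSE)
  fit <- if (through_origin) lm(his_morph ~ his_vis - 1) else lm(his_morph ~ his_vis)
  co <- coef(fit)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- if (through_origin) sum(his_morph^2) else
    sum((his_morph - mean(his_morph))^2)
  structure(list(slope = unname(co[["his_vis"]]),
                 intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(his_morph)),
            class = "linear_link")
}

#' Morphometric cutoffs equivalent to visual steatosis grade boundaries
#'
#' Evaluates the fitted morphometry-versus-visual regression line at the
#' clinical visual cutoffs (by default the steatosis grade boundaries 5, 33
#' and 66 percent of hepatocytes containing fat).
#'
#' @param link A `linear_link` from [fit_morph_vis_link()].
#' @param vis_cutoffs Visual cutoffs in percent.
#' @return Named numeric vector of morphometric fat-fraction cutoffs.
#' @export
derive_morph_cutoffs <- function(link, vis_cutoffs = c(5, 33, 66)) {
  stopifnot(inherits(link, "linear_link"))
  .check_num(vis_cutoffs, "vis_cutoffs", lo = 0, hi = 100,
             len = length(vis_cutoffs))
  setNames(link$intercept + link$slope * vis_cutoffs,
           paste0(vis_cutoffs, "%"))
}
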