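#' Area under the ROC curve
#'
#' Mann-Whitney pairwise formulation: the probability that a randomly chosen
#' positive scores higher than a randomly chosen negative, with ties counting
#' one half. Identical to trapezoidal integration of the empirical ROC
#' curve.
#'
#' @param scores Numeric diagnostic scores (higher = more positive).
#' @param labels Binary reference labels (logical, or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("`scores` and `labels` must be equal-length and NA-free", call. = FALSE)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal: two-sided normal-approximation p-value for AUC vs 0.5
.auc_p_value <- function(auc, n1, n0) {
  sd0 <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  2 * pnorm(-abs(auc - 0.5) / sd0)
}

# internal: sensitivity/specificity at `score > cutoff`
.sens_spec <- function(scores, labels, cutoff) {
  pos <- scores > cutoff
  c(sens = sum(pos & labels) / sum(labels),
    spec = sum(!pos & !labels) / sum(!labels))
}

#' Optimal diagnostic cutoff by the Youden criterion
#'
#' Scans every achievable cutoff (the midpoints between consecutive sorted
#' unique scores, plus one cutoff below the minimum and the maximum itself)
#' with positivity defined as `score > cutoff`, and returns the cutoff
#' maximising sensitivity + specificity. Ties are broken toward the lowest
#' qualifying cutoff, which favours sensitivity.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `sensitivity` and `specificity` (the latter
#'   two as proportions in `[0, 1]`).
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("both classes must be present to choose a cutoff", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)])
  ss <- vapply(cand, function(ct) .sens_spec(scores, labels, ct), numeric(2))
  youden <- ss[1, ] + ss[2, ]
  best <- which(youden >= max(youden) - 1e-12)[1]
  list(cutoff = cand[best],
       sensitivity = unname(ss[1, best]),
       specificity = unname(ss[2, best]))
}

#' Exact binomial (Clopper-Pearson) confidence interval, in percent
#'
#' @param successes Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Length-2 vector `c(lower, upper)` in percent.
#' @examples
#' proportion_ci(30, 30)  # lower bound ~88.4%
#' @export
proportion_ci <- function(successes, n, conf = 0.95) {
  .check_num(successes, "successes", lo = 0)
  .check_num(n, "n", lo = 1)
  if (successes > n) stop("`successes` cannot exceed `n`", call. = FALSE)
  a <- (1 - conf) / 2
  lo <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  c(lower = 100 * lo, upper = 100 * hi)
}

#' Limits of agreement from the moments of log differences
#'
#' Core Bland-Altman arithmetic on the natural-log scale: limits
#' `mean +/- 1.96 sd`, their confidence intervals via the standard error
#' `sd * sqrt(3/n)` with a `t(n-1)` quantile, and multiplicative ratio
#' bounds by exponentiation.
#'
#' @param mean_diff Mean of the log differences.
#' @param sd_diff Standard deviation of the log differences.
#' @param n Number of pairs.
#' @param conf Confidence level for the limit CIs (default 0.95).
#' @return An object of class `agreement_result` with fields
#'   `mean_diff_log`, `sd_diff_log`, `loa_low`, `loa_high`, `loa_low_ci`,
#'   `loa_high_ci` (each length-2), `ratio_low`, `ratio_high`, `n`.
#' @seealso [bland_altman_log()]
#' @export
loa_from_moments <- function(mean_diff, sd_diff, n, conf = 0.95) {
  .check_num(mean_diff, "mean_diff")
  .check_num(sd_diff, "sd_diff", lo = 0)
  .check_num(n, "n", lo = 3)
  half <- 1.96 * sd_diff
  lo <- mean_diff - half; hi <- mean_diff + half
  se <- sd_diff * sqrt(3 / n)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  structure(list(mean_diff_log = mean_diff, sd_diff_log = sd_diff,
                 loa_low = lo, loa_high = hi,
                 loa_low_ci = c(lo - tq * se, lo + tq * se),
                 loa_high_ci = c(hi - tq * se, hi + tq * se),
                 ratio_low = exp(lo), ratio_high = exp(hi),
                 n = as.integer(n)),
            class = "agreement_result")
}

#' Log-scale Bland-Altman limits of agreement
#'
#' For paired positive measurements whose disagreement grows with magnitude,
#' the differences of natural logarithms `d_i = ln x_i - ln y_i` are
#' analysed: limits of agreement `mean(d) +/- 1.96 sd(d)` with confidence
#' intervals, and back-transformation `exp(limit)` giving the bounds on the
#' ratio `x / y` within which 95 percent of measurement pairs are expected
#' to fall.
#'
#' @param x,y Paired strictly positive measurements (e.g. morphometric fat
#'   fraction and the MRI-derived equivalent).
#' @param conf Confidence level for the limit CIs.
#' @return An `agreement_result`; see [loa_from_moments()].
#' @export
bland_altman_log <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("`x` and `y` must be NA-free", call. = FALSE)
  if (length(x) < 3) stop("at least 3 pairs required", call. = FALSE)
  bad <- which(x <= 0 | y <= 0)
  if (length(bad) > 0) {
    stop(sprintf("log-scale agreement requires strictly positive values; offending pair(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- log(x) - log(y)
  loa_from_moments(mean(d), sd(d), length(d), conf)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("log-scale limits of agreement (n = %d):\n", x$n))
  cat(sprintf("  mean diff %.3f (sd %.3f)\n", x$mean_diff_log, x$sd_diff_log))
  cat(sprintf("  limits %.3f (95%% CI %.3f to %.3f) and %.3f (95%% CI %.3f to %.3f)\n",
              x$loa_low, x$loa_low_ci[1], x$loa_low_ci[2],
              x$loa_high, x$loa_high_ci[1], x$loa_high_ci[2]))
  cat(sprintf("  ratio bounds %.3f to %.3f\n", x$ratio_low, x$ratio_high))
  invisible(x)
}

#' Log-scale 95 percent prediction interval
#'
#' For positive, right-skewed measurements the prediction interval for a new
#' observation is computed on the natural-log scale,
#' `mean +/- t_{0.975}(n-1) * sd * sqrt(1 + 1/n)`, and both ends are
#' exponentiated. Used to state a reference range, e.g. of alpha in healthy
#' controls.
#'
#' @param values Strictly positive measurements, `n >= 3`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `prediction_interval` with fields `low`,
#'   `high`, `n`.
#' @export
prediction_interval_log <- function(values, conf = 0.95) {
  if (anyNA(values) || length(values) < 3) {
    stop("at least 3 NA-free values required", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("log-scale prediction interval requires strictly positive values",
         call. = FALSE)
  }
  lv <- log(values); n <- length(values)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(lv) * sqrt(1 + 1 / n)
  structure(list(low = exp(mean(lv) - half), high = exp(mean(lv) + half),
                 n = as.integer(n)),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("95%% prediction interval (log scale, n = %d): %.3f to %.3f\n",
              x$n, x$low, x$high))
  invisible(x)
}

# internal: one ROC table row for a given reference dichotomy
.roc_row <- function(scores, ref_positive, label) {
  n1 <- sum(ref_positive); n0 <- sum(!ref_positive)
  auc <- roc_auc(scores, ref_positive)
  oc <- optimal_cutoff(scores, ref_positive)
  ci_se <- proportion_ci(round(oc$sensitivity * n1), n1)
  ci_sp <- proportion_ci(round(oc$specificity * n0), n0)
  data.frame(threshold = label,
             cutoff = oc$cutoff,
             auc = auc,
             p_value = .auc_p_value(auc, n1, n0),
             sensitivity = 100 * oc$sensitivity,
             sens_ci_lower = ci_se[[1]], sens_ci_upper = ci_se[[2]],
             specificity = 100 * oc$specificity,
             spec_ci_lower = ci_sp[[1]], spec_ci_upper = ci_sp[[2]],
             n_positive = n1, n_negative = n0,
             stringsAsFactors = FALSE)
}

#' Full diagnostic-performance report for a cohort
#'
#' Assembles the statistical surface of the pipeline for a cohort carrying
#' alpha and both biopsy reference measurements:
#'
#' * ROC analyses of alpha against the visual steatosis grade boundaries
#'   (reference positive at `his_vis >= 5`, `> 33`, `> 66` percent), with the
#'   optimal cutoff (`alpha > cutoff`), AUC, normal-approximation p-value,
#'   and exact binomial CIs for sensitivity and specificity;
#' * the same against morphometric cutoffs derived from the regression of
#'   morphometry on the visual estimate ([derive_morph_cutoffs()]; reference
#'   positive at `>= c1`, `> c2`, `> c3`);
#' * log-scale Bland-Altman agreement between the morphometric fat fraction
#'   and the MRI-derived fat fraction `invert_alpha(alpha, k)`;
#' * the controls' 95 percent log-scale prediction interval of alpha, when
#'   controls are present.
#'
#' @param cohort Cohort data frame in the [generate_cohort()] /
#'   [read_cohort()] schema.
#' @param calibration Optional `calibration_model`; fitted from the cohort's
#'   patients when `NULL`.
#' @param vis_cutoffs Visual steatosis grade boundaries in percent.
#' @return An object of class `diagnostic_report` with fields `roc_vis`,
#'   `roc_morph` (data frames), `calibration`, `link`, `morph_cutoffs`,
#'   `agreement`, `control_pi` (or `NULL`), `n_patients`, `n_controls`.
#' @export
diagnostic_report <- function(cohort, calibration = NULL,
                              vis_cutoffs = c(5, 33, 66)) {
  need <- c("group", "his_vis_pct", "his_morph_frac", "alpha")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  pat <- cohort[cohort$group == "patient" &
                  !is.na(cohort$his_vis_pct) &
                  !is.na(cohort$his_morph_frac) &
                  !is.na(cohort$alpha), , drop = FALSE]
  if (nrow(pat) < 3) stop("fewer than 3 complete patient records", call. = FALSE)

  if (is.null(calibration)) {
    calibration <- fit_k(pat$alpha, pat$his_morph_frac)
  }
  stopifnot(inherits(calibration, "calibration_model"))
  link <- fit_morph_vis_link(pat$his_morph_frac, pat$his_vis_pct)
  mcut <- derive_morph_cutoffs(link, vis_cutoffs)

  ref_vis <- list(pat$his_vis_pct >= vis_cutoffs[1],
                  pat$his_vis_pct > vis_cutoffs[2],
                  pat$his_vis_pct > vis_cutoffs[3])
  lab_vis <- c(sprintf(">=%g%%", vis_cutoffs[1]),
               sprintf(">%g%%", vis_cutoffs[2]),
               sprintf(">%g%%", vis_cutoffs[3]))
  roc_vis <- do.call(rbind, lapply(seq_along(ref_vis), function(i) {
    .roc_row(pat$alpha, ref_vis[[i]], lab_vis[i])
  }))

  ref_mor <- list(pat$his_morph_frac >= mcut[1],
                  pat$his_morph_frac > mcut[2],
                  pat$his_morph_frac > mcut[3])
  lab_mor <- c(sprintf(">=%.3f", mcut[1]),
               sprintf(">%.3f", mcut[2]),
               sprintf(">%.3f", mcut[3]))
  roc_morph <- do.call(rbind, lapply(seq_along(ref_mor), function(i) {
    .roc_row(pat$alpha, ref_mor[[i]], lab_mor[i])
  }))

  mri_morph <- invert_alpha(pat$alpha, calibration$k)
  agreement <- bland_altman_log(pat$his_morph_frac, mri_morph)

  ctrl <- cohort$alpha[cohort$group == "control" & !is.na(cohort$alpha)]
  control_pi <- if (length(ctrl) >= 3) prediction_interval_log(ctrl) else NULL

  structure(list(roc_vis = roc_vis, roc_morph = roc_morph,
                 calibration = calibration, link = link,
                 morph_cutoffs = mcut, agreement = agreement,
                 control_pi = control_pi,
                 n_patients = nrow(pat), n_controls = length(ctrl)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic report: %d patients, %d controls\n",
              x$n_patients, x$n_controls))
  cat("\nROC vs visual fat estimate:\n")
  print(x$roc_vis, row.names = FALSE, digits = 4)
  cat("\nROC vs morphometric fat fraction:\n")
  print(x$roc_morph, row.names = FALSE, digits = 4)
  cat("\nCalibration: "); print(x$calibration)
  cat("\n"); print(x$agreement)
  if (!is.null(x$control_pi)) {
    cat("\nControls: "); print(x$control_pi)
  }
  invisible(x)
}

#' Routine group-comparison tests between controls and patients
#'
#' Thin wrappers over standard base-R tests for the descriptive comparison
#' of controls and patients: unpaired t test on BMI (parametric),
#' Mann-Whitney tests on liver iron and alpha (non-parametric). Provided for
#' report completeness only.
#'
#' @param cohort Cohort data frame.
#' @return Data frame with columns `variable`, `test`, `p_value`.
#' @export
compare_groups <- function(cohort) {
  pat <- cohort[cohort$group == "patient", ]
  ctl <- cohort[cohort$group == "control", ]
  if (nrow(ctl) < 2 || nrow(pat) < 2) {
    stop("both groups must have at least 2 subjects", call. = FALSE)
  }
  data.frame(
    variable = c("bmi", "lic_mg_g", "alpha"),
    test = c("t", "mann-whitney", "mann-whitney"),
    p_value = c(stats::t.test(pat$bmi, ctl$bmi)$p.value,
                stats::wilcox.test(pat$lic_mg_g, ctl$lic_mg_g, exact = FALSE)$p.value,
                stats::wilcox.test(pat$alpha, ctl$alpha, exact = FALSE)$p.value),
    stringsAsFactors = FALSE
  )
}
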