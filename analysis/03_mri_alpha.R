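#!/usr/bin/env Rscript
# Stage 3: alpha estimation from simulated triple-echo signals.
#
# For every subject in the simulated cohort, per-slice triple-echo ROI
# signals are synthesised from the subject's slice alpha values (as signal
# fat fractions, without T1 weighting so the mapping is exact) across a
# range of T2* values, then re-estimated with the T2*-corrected two-point
# Dixon estimator. This closes the loop between the signal simulator and
# the estimator on every record.

library(hepafat)

coh <- read_cohort("results/cohort.csv")
t2_grid <- c(15, 25, 35)  # ms, per slice

alpha_mri <- vapply(seq_len(nrow(coh)), function(i) {
  triples <- lapply(1:3, function(s) {
    simulate_roi_signals(
      min(coh[[paste0("alpha_s", s)]][i], 0.5),
      mri_signal_params(flip_angle = 90, tr = 1e9, t2star = t2_grid[s],
                        noise_sd = 0))
  })
  alpha_from_slices(triples)$alpha
}, numeric(1))

coh$alpha_mri <- alpha_mri
write_cohort(coh, "results/cohort_alpha.csv")

err <- abs(coh$alpha_mri - coh$alpha)
cat(sprintf("Re-estimated alpha for %d subjects -> results/cohort_alpha.csv\n",
            nrow(coh)))
cat(sprintf("Max |alpha_mri - alpha| = %.2e (T2* values %s ms, corrected per slice)\n",
            max(err), paste(t2_grid, collapse = "/")))
stopifnot(max(err) < 1e-6)
cat("The estimator inverts the signal model exactly on noiseless data.\n")
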