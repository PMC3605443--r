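#!/usr/bin/env Rscript
# Stage 4: calibration between alpha and the morphometric fat fraction.
#
# Fits the one-parameter rational model alpha = k f / (k f + 1 - f) to the
# patients' (morphometry, alpha) pairs, and derives morphometric cutoffs
# equivalent to the 5/33/66 percent visual steatosis grade boundaries from
# the morphometry-versus-visual regression line.

library(hepafat)

coh <- read_cohort("results/cohort.csv")
pat <- coh[coh$group == "patient", ]

calib <- fit_k(pat$alpha, pat$his_morph_frac)
write_report_json(calib, "results/calibration.json")
cat("Nonlinear calibration fit -> results/calibration.json\n")
print(calib)
cat(sprintf("Low-fat contrast gain d(alpha)/df at f=0 equals k = %.2f\n",
            calib$k))

link <- fit_morph_vis_link(pat$his_morph_frac, pat$his_vis_pct)
cuts <- derive_morph_cutoffs(link, c(5, 33, 66))
cat(sprintf("\nMorphometry ~ visual link: slope %.5f per %%, intercept %.4f, r^2 = %.2f\n",
            link$slope, link$intercept, link$r_squared))
cat("Morphometric cutoffs at visual 5/33/66%:\n")
print(round(cuts, 4))
write.csv(data.frame(vis_cutoff_pct = c(5, 33, 66), morph_cutoff_frac = cuts),
          "results/morph_cutoffs.csv", row.names = FALSE)
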