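#!/usr/bin/env Rscript
# Stage 5: diagnostic performance of alpha against both biopsy references.
#
# ROC analyses of alpha against the visual steatosis grade boundaries and
# against the derived morphometric cutoffs; log-scale Bland-Altman limits of
# agreement between the morphometric fraction and the MRI-derived fraction;
# and the controls' 95% prediction interval (the healthy reference range of
# alpha).

library(hepafat)

coh <- read_cohort("results/cohort.csv")
rep_ <- diagnostic_report(coh)

write_report_json(rep_, "results/report.json")
write.csv(rep_$roc_vis, "results/roc_vis.csv", row.names = FALSE)
write.csv(rep_$roc_morph, "results/roc_morph.csv", row.names = FALSE)

print(rep_)
cat("\nTables -> results/roc_vis.csv, results/roc_morph.csv; full report -> results/report.json\n")
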