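#!/usr/bin/env Rscript
# Stage 2: morphometric fat measurement on a synthetic histology section.
#
# Generates a trichrome-like phantom with known ground-truth fat, runs the
# threshold / particle / shape-filter / fill-holes pipeline, and reports how
# well the measured areal fat fraction recovers the truth while rejecting
# vessel- and tear-like structures.

library(hepafat)

dir.create("results", showWarnings = FALSE)
spec <- histology_phantom_spec(width = 768, height = 768,
                               target_fat_fraction = 0.10,
                               n_vessels = 2, n_tears = 1, seed = 20260302)
ph <- generate_histology_phantom(spec)
res <- areal_fat_fraction(ph$image)

write.csv(res$particles, "results/particles.csv", row.names = FALSE)
jsonlite::write_json(
  list(true_areal_fat_fraction = ph$true_areal_fat_fraction,
       measured_areal_fat_fraction = res$areal_fat_fraction,
       fat_area_px = res$fat_area, tissue_area_px = res$tissue_area,
       n_particles = nrow(res$particles),
       n_accepted = sum(res$particles$accepted)),
  "results/morphometry.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("Phantom truth: %.4f  |  measured: %.4f  (relative error %+.2f%%)\n",
            ph$true_areal_fat_fraction, res$areal_fat_fraction,
            100 * (res$areal_fat_fraction / ph$true_areal_fat_fraction - 1)))
cat(sprintf("%d of %d particles accepted as fat vacuoles\n",
            sum(res$particles$accepted), nrow(res$particles)))
rej <- res$particles[!res$particles$accepted & !res$particles$touches_border, ]
cat("Rejected interior structures (area px / circularity):\n")
for (i in seq_len(nrow(rej))) {
  why <- if (rej$area[i] > 10000) "oversize (vessel-like)"
         else if (rej$circularity[i] < 0.5) "elongated (tear-like)"
         else "out of bounds"
  cat(sprintf("  %6d px  circ %.2f  -> %s\n",
              rej$area[i], rej$circularity[i], why))
}
cat("Particle table -> results/particles.csv; summary -> results/morphometry.json\n")
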