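#!/usr/bin/env Rscript
# Generate example synthetic specimens and record their realized phase
# fractions. Writes volumes (TIFF + JSON sidecar) and a summary table under
# results/phantoms/.

library(secmorph)

out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (s in 1:4) {
  sp <- phantom_spec(shape = c(64L, 64L, 64L), seed = s)
  pv <- generate_phase_volume(sp)
  gv <- render_grayscale(pv, sp)
  write_volume_tiff(pv, file.path(out_dir, sprintf("specimen%02d_phase.tiff", s)),
                    spec = sp)
  write_volume_tiff(gv, file.path(out_dir, sprintf("specimen%02d_gray.tiff", s)))
  rf <- attr(pv, "realized_fractions")
  rows[[s]] <- data.frame(specimen = s, seed = s,
                          bone_target = sp$bone_fraction_target,
                          graft_target = sp$graft_fraction_target,
                          bone_realized = rf["bone"],
                          graft_realized = rf["graft"],
                          noncalcified_realized = rf["noncalcified"])
}
summary_tab <- do.call(rbind, rows)
rownames(summary_tab) <- NULL
write.csv(summary_tab, file.path(out_dir, "realized_fractions.csv"),
          row.names = FALSE)

cat("Realized vs target phase fractions (4 specimens, 64^3 voxels):\n")
print(summary_tab, digits = 4, row.names = FALSE)
cat(sprintf("\nLargest |bone - target| deviation: %.4f\n",
            max(abs(summary_tab$bone_realized - summary_tab$bone_target))))
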