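#!/usr/bin/env Rscript
# The full in-silico study: 16 synthetic specimens, a histology-proxy
# reference per specimen, the original virtual section plus +/-4 pixel
# (79 um) parallel offsets and +/-10 degree rotations, percent-area
# morphometry, and the two per-phase agreement tables. Writes everything
# under results/study/.

library(secmorph)

report <- run_study(study_config(seed = 42L))
write_study_report(report, "results/study")

cat("Agreement of percent BONE area (CCC with 95% CI, mean diff +/- SD):\n")
print(report$table_bone[, c("reference", "comparator", "ccc", "ci_lower",
                            "ci_upper", "mean_diff", "sd_diff")],
      digits = 3, row.names = FALSE)
cat("\nAgreement of percent GRAFT area:\n")
print(report$table_graft[, c("reference", "comparator", "ccc", "ci_lower",
                             "ci_upper", "mean_diff", "sd_diff")],
      digits = 3, row.names = FALSE)

hm_bone <- report$table_bone[report$table_bone$reference == "HM", ]
cat(sprintf(
  "\nMatched-plane agreement tops its block: CCC(original) = %.3f vs best perturbed %.3f (bone).\n",
  hm_bone$ccc[hm_bone$comparator == "original"],
  max(hm_bone$ccc[hm_bone$comparator != "original"])))
cat("Perturbing the section plane by one pixel-group offset or a 10-degree\n")
cat("rotation visibly degrades between-image concordance, the study's headline effect.\n")
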