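#!/usr/bin/env Rscript
# Stage 1: simulate the two-scan cohort.
#
# Generates the study-condition synthetic cohort (9 control vs 15
# long-sepsis subjects; planted regional uptake increments appear only in
# the recall scan, at the group means of the real study; nested
# subject/hemisphere/slice/voxel noise; freezing traces with group-dependent
# bout structure) and writes it to results/cohort as NIfTI volumes, CSV
# traces/labels, and JSON ground truth + manifest. Later stages read these
# fixtures back, so the whole workflow runs off on-disk standard formats.

suppressPackageStartupMessages(library(betapet))

seed <- 20240730L
out <- "results/cohort"

cohort <- generate_cohort(synth_config(seed = seed))
manifest <- write_fixtures(cohort, out)
validate_manifest(out)

cat(sprintf("cohort: %d CON + %d LS subjects on a %s grid (seed %d)\n",
            cohort$config$n_con, cohort$config$n_ls,
            paste(cohort$config$grid_shape, collapse = "x"), seed))
cat(sprintf("wrote %d files under %s (volumes, masks, traces, labels, ground truth)\n",
            length(manifest$files) + 4, out))
gt <- cohort$subjects[[1]]$ground_truth$planted_increment
cat("planted CON increments:",
    paste(sprintf("%s=%.3g", names(gt), gt), collapse = ", "), "\n")
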