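#!/usr/bin/env Rscript
# Stage 3: the beta-PET core.
#
# Normalizes every scan to its whole-brain mean, extracts regional SUVs per
# coronal slice and hemisphere (prefrontal regions as single midline
# objects), subtracts baseline from recall (delta-SUV), and summarizes each
# subject's regional response. Writes the record-level and subject-level
# tables plus the group-mean network map.

suppressPackageStartupMessages(library(betapet))

fx <- read_fixtures("results/cohort")
delta <- do.call(rbind, c(lapply(fx$subjects, function(su) {
  f1 <- region_suv_table(normalize_scan(su$scans$F1, fx$brain_mask), fx$masks)
  f3 <- region_suv_table(normalize_scan(su$scans$F3, fx$brain_mask), fx$masks)
  delta_suv(f1, f3)
}), make.row.names = FALSE))
write.csv(delta, "results/delta_suv.csv", row.names = FALSE)

means <- subject_region_mean(delta)
write.csv(means, "results/subject_region_means.csv", row.names = FALSE)

grp_means <- lapply(setNames(c("CON", "LS"), c("CON", "LS")), function(g) {
  sm <- means[fx$labels[means$subject] == g, ]
  tapply(sm$mean_delta, sm$region, mean)
})
nm <- network_map(grp_means, "mean_delta")
write_network_map(nm, "results/network_map.json")

cat(sprintf("delta-SUV records: %d (%d per subject)\n", nrow(delta),
            nrow(delta) / length(fx$subjects)))
cat("group-mean delta-SUV per region:\n")
for (rg in nm$regions)
  cat(sprintf("  %-4s CON %+.3f   LS %+.3f\n", rg,
              nm$values$CON[[rg]], nm$values$LS[[rg]]))
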