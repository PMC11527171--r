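#!/usr/bin/env Rscript
# Stage 4: group inference.
#
# For each region, tests the group difference in delta-SUV with the nested
# linear mixed model (fixed group effect, random subject intercept,
# F against between-subject df), then correlates each subject's regional
# mean delta-SUV with recall freezing within each group.

suppressPackageStartupMessages(library(betapet))

fx <- read_fixtures("results/cohort")
delta <- read.csv("results/delta_suv.csv")
means <- read.csv("results/subject_region_means.csv")
freezing <- read.csv("results/freezing.csv")
f3 <- freezing[freezing$session == "F3", ]

regions <- c("BA", "PLC", "ILC", "DH", "VH", "SB", "LEC", "MEC")
lmm_tab <- do.call(rbind, lapply(regions, function(rg) {
  r <- suppressWarnings(lmm_group_test(delta[delta$region == rg, ], fx$labels))
  data.frame(region = rg, mean_CON = r$group_means[["CON"]],
             mean_LS = r$group_means[["LS"]], F_stat = r$F_stat,
             p_value = r$p_value)
}))
write.csv(lmm_tab, "results/lmm_group_tests.csv", row.names = FALSE)
cat("mixed-model group tests (delta-SUV ~ group + (1 | subject)):\n")
for (i in seq_len(nrow(lmm_tab)))
  cat(sprintf("  %-4s CON %+.3f LS %+.3f  F = %6.2f  p = %.3g%s\n",
              lmm_tab$region[i], lmm_tab$mean_CON[i], lmm_tab$mean_LS[i],
              lmm_tab$F_stat[i], lmm_tab$p_value[i],
              if (lmm_tab$p_value[i] < 0.05) "  *" else ""))

cors <- do.call(rbind, lapply(c("CON", "LS"), function(grp) {
  subj <- f3$subject[f3$group == grp]
  do.call(rbind, lapply(regions, function(rg) {
    mrg <- means[means$region == rg, ]
    r <- region_behavior_correlation(mrg$mean_delta[match(subj, mrg$subject)],
                                     f3$pct_freezing[f3$group == grp])
    data.frame(group = grp, region = rg, r = r$pearson_r,
               slope = r$slope, intercept = r$intercept)
  }))
}))
write.csv(cors, "results/behavior_correlations.csv", row.names = FALSE)
grp_r <- lapply(setNames(c("CON", "LS"), c("CON", "LS")), function(g)
  setNames(cors$r[cors$group == g], cors$region[cors$group == g]))
write_network_map(network_map(grp_r, "pearson_r"),
                  "results/correlation_map.json")
cat("strongest delta-SUV/freezing correlations (CON):\n")
cc <- cors[cors$group == "CON", ]
cc <- cc[order(-abs(cc$r)), ][1:3, ]
for (i in 1:3) cat(sprintf("  %-4s r = %+.2f\n", cc$region[i], cc$r[i]))
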