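#!/usr/bin/env Rscript
# Stage 2: score freezing behavior.
#
# Reads the activity traces written by 01_simulate.R, thresholds them into
# immobility flags, computes 10-s-bin percent freezing over each session's
# analysis window (conditioning: tone + trace intervals; recall: last 4
# minutes), detects freezing bouts (>= 2 s), and compares the groups:
# a pooled t test on recall freezing and a two-sample KS test on the bout
# duration distributions.

suppressPackageStartupMessages(library(betapet))

fx <- read_fixtures("results/cohort")
rows <- list(); bouts <- list()
for (su in fx$subjects) for (ss in c("F2", "F3")) {
  sf <- session_freezing(su$traces[[ss]], ss)
  rows[[length(rows) + 1]] <- data.frame(subject = su$id, group = su$group,
                                         session = ss,
                                         pct_freezing = sf$session_pct)
  if (nrow(sf$bouts))
    bouts[[length(bouts) + 1]] <- cbind(subject = su$id, group = su$group,
                                        session = ss, sf$bouts)
}
freezing <- do.call(rbind, rows)
bout_tab <- do.call(rbind, bouts)
write.csv(freezing, "results/freezing.csv", row.names = FALSE)
write.csv(bout_tab, "results/bouts.csv", row.names = FALSE)

for (ss in c("F2", "F3")) {
  m <- tapply(freezing$pct_freezing[freezing$session == ss],
              freezing$group[freezing$session == ss], mean)
  cat(sprintf("%s freezing: CON %.1f%%, LS %.1f%%\n", ss, m["CON"], m["LS"]))
}
f3 <- freezing[freezing$session == "F3", ]
tt <- t_test_groups(f3$pct_freezing[f3$group == "CON"],
                    f3$pct_freezing[f3$group == "LS"])
cat(sprintf("recall (F3) group difference: T = %.2f, p = %.3g (pooled t, df = %d)\n",
            tt$T_stat, tt$p_value, tt$df))
ks <- ks_two_sample(bout_tab$duration_s[bout_tab$group == "CON"],
                    bout_tab$duration_s[bout_tab$group == "LS"])
cat(sprintf("bout durations (CON vs LS, %d bouts): KS D = %.3f, p = %.3g\n",
            nrow(bout_tab), ks$D, ks$p_value))
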