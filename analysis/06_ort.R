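#!/usr/bin/env Rscript
# Stage 6: ordinal-trends canonical variates analysis.
#
# On the control group's baseline/recall pairs: PCA of the scan matrix, AIC
# selection of the trend pattern, label-flip permutation test of the ordinal
# trend, and bootstrap reliability of the voxel weights. The selected
# pattern is then expressed in both groups to compare their recall-related
# expression changes.

suppressPackageStartupMessages(library(betapet))

fx <- read_fixtures("results/cohort")
pairs_of <- function(grp) lapply(
  Filter(function(su) su$group == grp, fx$subjects),
  function(su) list(F1 = normalize_scan(su$scans$F1, fx$brain_mask),
                    F3 = normalize_scan(su$scans$F3, fx$brain_mask)))
con <- pairs_of("CON"); ls <- pairs_of("LS")

res <- ort_analysis(con, fx$brain_mask, n_perm = 500, n_boot = 500,
                    seed = 20240730L)
cat(sprintf("selected PCs {%s}; %d/%d CON subjects increasing; permutation p = %.4g\n",
            paste(res$pattern$selected, collapse = ","), res$n_increasing,
            length(con), res$perm_p))
cat(sprintf("bootstrap-reliable voxels: %d increasing, %d decreasing (one-tailed p < 0.05)\n",
            sum(res$sig_pos), sum(res$sig_neg)))

grid <- fx$masks$grid_shape
zvol <- array(0, grid); zvol[fx$brain_mask] <- res$boot_z
write_volume(zvol, "results/ort_boot_z.nii",
             unlist(fx$manifest$voxel_size_mm))
svol <- array(0, grid); svol[fx$brain_mask] <- as.numeric(res$sig_mask)
write_volume(svol, "results/ort_sig_mask.nii",
             unlist(fx$manifest$voxel_size_mm))

om_all <- build_ort_matrix(c(con, ls), fx$brain_mask)
ec <- expression_change(res$pattern, om_all, groups = fx$labels)
write.csv(ec$expressions, "results/ort_expressions.csv", row.names = FALSE)
g <- fx$labels[names(ec$delta)]
cat(sprintf("nodal expression increasing: CON %.1f%%, LS %.1f%%\n",
            100 * ec$fraction_increasing[["CON"]],
            100 * ec$fraction_increasing[["LS"]]))
cat(sprintf("expression change (z units): CON %.2f, LS %.2f; T = %.2f, p = %.3g\n",
            mean(ec$delta[g == "CON"]), mean(ec$delta[g == "LS"]),
            ec$t_test$T_stat, ec$t_test$p_value))
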