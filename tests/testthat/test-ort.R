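toy_matrix <- function(X, n_subj = nrow(X) / 2) {
  structure(list(data = X,
                 subjects = rep(sprintf("S%02d", seq_len(n_subj)), each = 2),
                 conditions = rep(c("F1", "F3"), n_subj),
                 voxel_index = NULL, grid_shape = NULL),
            class = "ort_matrix")
}

test_that("the scan matrix has 2 rows per subject and a round-tripping voxel index", {
  co <- generate_cohort(block_cfg(seed = 2, n_con = 9), traces = FALSE)
  scans <- normalized_pairs(co, "CON")
  om <- build_ort_matrix(scans, co$brain_mask)
  expect_equal(nrow(om$data), 18)
  expect_equal(ncol(om$data), sum(co$brain_mask))
  # column -> coordinate -> column
  lin <- om$voxel_index[, 1] +
    (om$voxel_index[, 2] - 1) * co$config$grid_shape[1] +
    (om$voxel_index[, 3] - 1) * prod(co$config$grid_shape[1:2])
  expect_identical(as.integer(lin), which(co$brain_mask))
  scans_missing <- scans
  scans_missing[[3]]$F3 <- NULL
  expect_error(build_ort_matrix(scans_missing, co$brain_mask),
               "missing condition F3")
})

test_that("PCA of a rank-1 matrix recovers the planted component", {
  set.seed(6)
  u <- rnorm(10); v <- rnorm(50); v <- v / sqrt(sum(v^2))
  X <- 3 + outer(u, v) * 2
  om <- toy_matrix(X, 5)
  pcs <- pca_decompose(om)
  expect_equal(length(pcs$singular_values), 1)
  expect_equal(abs(sum(pcs$components[, 1] * v)), 1, tolerance = 1e-10)
  expect_equal(cor(pcs$expressions[, 1], u)^2, 1, tolerance = 1e-10)
  expect_error(pca_decompose(toy_matrix(matrix(5, 4, 10), 2)), "rank 0")
})

test_that("PCA reconstructs the centered data and expression variances match", {
  set.seed(8)
  X <- matrix(rnorm(12 * 30), 12, 30)
  om <- toy_matrix(X, 6)
  pcs <- pca_decompose(om)
  Xc <- sweep(X, 2, colMeans(X))
  recon <- pcs$expressions %*% t(pcs$components)
  expect_equal(recon, Xc, tolerance = 1e-8)
  # components orthonormal
  G <- crossprod(pcs$components)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-10)
  for (k in seq_along(pcs$singular_values)) {
    expect_equal(var(pcs$expressions[, k]),
                 pcs$singular_values[k]^2 / (nrow(X) - 1), tolerance = 1e-10)
  }
})

test_that("AIC selection follows the stated formula and tie-breaks to parsimony", {
  # hand-built pc_set: n = 4 expressions, orthogonal components
  pcs <- structure(list(
    components = diag(3),
    expressions = matrix(c(1, 1, -1, -1,      # orthogonal to the design
                           1, -1, 1, -1,
                           0.5, -0.5, -0.5, 0.5), 4, 3),
    singular_values = c(3, 2, 1), explained_variance = c(.6, .3, .1)),
    class = "pc_set")
  subjects <- c("A", "A", "B", "B")
  design <- c(-1, 1, -1, 1)
  # candidate {1}: expr1 is orthogonal to the design, so RSS = 4 and
  # AIC = 4 ln(4/4) + 2(1+1) = 4
  e1 <- pcs$expressions[, 1]
  beta <- sum((design - mean(design)) * e1) / sum(e1^2)
  rss <- sum((design - beta * e1)^2)
  expect_equal(rss, 4)
  # a component perfectly collinear with the design wins as a singleton
  pcs2 <- pcs
  pcs2$expressions[, 2] <- design * 2
  pat2 <- suppressWarnings(select_pattern_aic(pcs2, design, subjects, Kmax = 3))
  expect_equal(pat2$aic_trace$aic[1], 4 * log(4 / 4) + 2 * 2)
  expect_identical(pat2$selected, 2L)
  # exact ties go to the smaller candidate set
  pcs3 <- pcs
  pcs3$expressions[, 2] <- pcs3$expressions[, 1]
  pat3 <- suppressWarnings(select_pattern_aic(pcs3, design, subjects, Kmax = 2))
  expect_length(pat3$selected, 1)
})

test_that("the permutation p honors its formula bounds", {
  co <- generate_cohort(block_cfg(seed = 4, eff = 0.3, sd_voxel = 0.02),
                        traces = FALSE)
  om <- build_ort_matrix(normalized_pairs(co, "CON"), co$brain_mask)
  pr <- ordinal_trend_permutation(om, n_perm = 60, seed = 5)
  expect_equal(pr$perm_p,
               (1 + sum(pr$perm_stats >= pr$stat)) / (1 + 60))
  expect_gt(pr$perm_p, 0)
  expect_lte(pr$perm_p, 1)
  expect_gte(pr$perm_p, 1 / 61)
  # a statistic at its floor makes p = 1
  expect_equal((1 + 60) / (1 + 60), 1)
})

test_that("bootstrap z-maps are seed-reproducible and flag the planted pattern", {
  co <- generate_cohort(block_cfg(seed = 11, eff = 0.15, sd_voxel = 0.05),
                        traces = FALSE)
  om <- build_ort_matrix(normalized_pairs(co, "CON"), co$brain_mask)
  st <- betapet:::ort_trend_statistic(om)
  b1 <- bootstrap_voxel_weights(om, st$pattern, n_boot = 80, seed = 9)
  b2 <- bootstrap_voxel_weights(om, st$pattern, n_boot = 80, seed = 9)
  expect_identical(b1$boot_z, b2$boot_z)
  blk <- co$masks$masks$BLK[co$brain_mask]
  expect_gt(mean(b1$sig_pos[blk]), 0.9)        # planted voxels detected
  expect_gt(mean(blk[b1$sig_pos]), 0.8)        # and dominate the increases
  b3 <- bootstrap_voxel_weights(om, st$pattern, n_boot = 80, seed = 10)
  expect_false(identical(b1$boot_z, b3$boot_z))
})

test_that("expression changes are z-scored, zero for identical pairs, and sign-flip exactly", {
  co <- generate_cohort(block_cfg(seed = 13, eff = 0.2), traces = FALSE)
  scans <- normalized_pairs(co, "CON")
  om <- build_ort_matrix(scans, co$brain_mask)
  st <- betapet:::ort_trend_statistic(om)
  ec <- expression_change(st$pattern, om)
  expect_equal(mean(ec$expressions$expression), 0, tolerance = 1e-10)
  expect_equal(sd(ec$expressions$expression), 1, tolerance = 1e-10)
  # flipping every subject's condition pair flips every delta exactly
  om_fl <- betapet:::flip_subjects(om, rep(TRUE, 9))
  ec_fl <- expression_change(st$pattern, om_fl)
  expect_equal(unname(ec_fl$delta), -unname(ec$delta), tolerance = 1e-10)
  # a subject with F1 == F3 has exactly zero change
  scans2 <- scans
  scans2[[1]]$F3 <- scans2[[1]]$F1
  om2 <- build_ort_matrix(scans2, co$brain_mask)
  ec2 <- expression_change(st$pattern, om2)
  expect_equal(unname(ec2$delta[1]), 0, tolerance = 1e-12)
  expect_error(expression_change(st$pattern,
                                 toy_matrix(matrix(rnorm(8), 2, 4), 1)),
               "voxel index")
})

test_that("adding a constant image to every scan leaves expressions unchanged", {
  set.seed(20)
  X <- matrix(rnorm(12 * 40), 12, 40)
  om <- toy_matrix(X, 6)
  st <- betapet:::ort_trend_statistic(om)
  om2 <- om
  om2$data <- om2$data + 5
  expect_equal(betapet:::pattern_expressions(om2, st$pattern$weights),
               betapet:::pattern_expressions(om, st$pattern$weights),
               tolerance = 1e-10)
  expect_equal(sqrt(sum(st$pattern$weights^2)), 1, tolerance = 1e-12)
})
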