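sep_features <- function(n_neg = 6, n_pos = 8, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_neg * 3), n_neg),
             matrix(rnorm(n_pos * 3, mean = gap), n_pos))
  rownames(X) <- c(sprintf("c%d", 1:n_neg), sprintf("l%d", 1:n_pos))
  colnames(X) <- c("BA", "PLC", "ILC")
  structure(list(X = X,
                 y = factor(rep(c("CON", "LS"), c(n_neg, n_pos)),
                            levels = c("CON", "LS")),
                 regions = colnames(X)),
            class = "feature_matrix")
}

test_that("GentleBoost separates 1-D sign-labelled data in one round", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- sign(x[, 1])
  m <- train_gentleboost(x, y, n_rounds = 1)
  s <- predict_gentleboost(m, x)
  expect_true(all(sign(s) == y))
  expect_lt(m$rounds[[1]]$threshold, 1)
  expect_gt(m$rounds[[1]]$threshold, -1)
})

test_that("GentleBoost with single-class labels scores everything positive", {
  set.seed(5)
  x <- matrix(rnorm(12), ncol = 2)
  m <- suppressWarnings(train_gentleboost(x, rep(1, 6), n_rounds = 3))
  expect_true(all(predict_gentleboost(m, x) > 0))
})

test_that("GentleBoost training exponential loss is nonincreasing every round", {
  set.seed(14)
  for (i in 1:5) {
    x <- matrix(rnorm(40), ncol = 4)
    y <- ifelse(x[, 1] + rnorm(10, sd = 0.5) > 0, 1, -1)
    m <- train_gentleboost(x, y, n_rounds = 50)
    expect_true(all(diff(m$loss_trace) <= 1e-12))
  }
})

test_that("GentleBoost tolerates all-constant features", {
  x <- matrix(1, 8, 2)
  y <- rep(c(-1, 1), 4)
  m <- train_gentleboost(x, y, n_rounds = 5)
  expect_true(all(is.finite(predict_gentleboost(m, x))))
})

test_that("LOOCV yields one prediction per subject and perfect rates on separated data", {
  fm <- sep_features()
  for (mk in c("logistic", "svm", "gentleboost")) {
    r <- loocv(fm, mk, seed = 2)
    expect_equal(nrow(r$per_subject), nrow(fm$X))
    expect_equal(r$confusion$TPR, 100)
    expect_equal(r$confusion$TNR, 100)
    expect_equal(r$auc, 1)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0))
  }
})

test_that("the held-out row never influences its own training fold (leakage)", {
  fm <- sep_features(gap = 2, seed = 3)
  probe <- matrix(rnorm(5 * 3, sd = 2), 5, 3,
                  dimnames = list(NULL, fm$regions))
  for (mk in c("logistic", "svm", "gentleboost")) {
    for (i in c(1, nrow(fm$X))) {
      m0 <- loocv_fold(fm, i, mk, seed = 7)
      fm2 <- fm
      fm2$X[i, ] <- fm2$X[i, ] + 100
      m1 <- loocv_fold(fm2, i, mk, seed = 7)
      expect_equal(fold_model_score(m1, probe), fold_model_score(m0, probe),
                   tolerance = 1e-12)
    }
  }
})

test_that("all-constant features classify at the majority rate with chance AUC", {
  fm <- sep_features()
  fm$X[] <- 1
  r <- loocv(fm, "gentleboost", seed = 4)
  # no information: every prediction is the training majority class (LS)
  expect_true(all(r$per_subject$predicted == "LS"))
  expect_equal(r$confusion$TPR, 100)
  expect_equal(r$confusion$TNR, 0)
  # fold-calibrated scores of an uninformative model are all zero: chance AUC
  expect_equal(r$auc, 0.5)
})

test_that("confusion rates reproduce count arithmetic and ROC endpoints", {
  labels <- factor(rep(c("CON", "LS"), c(9, 15)), levels = c("CON", "LS"))
  pred <- labels
  pred[1:2] <- "LS"  # 7 of 9 true negatives kept
  scores <- ifelse(pred == "LS", 1, -1) + seq_along(pred) * 1e-3
  cr <- confusion_and_roc(scores, labels, predictions = pred)
  expect_equal(round(cr$confusion$TNR, 1), 77.8)
  expect_equal(cr$confusion$FPR, 100 * 2 / 9)
  expect_equal(cr$confusion$TPR, 100)
  perfect <- confusion_and_roc(ifelse(labels == "LS", 1, -1), labels)
  expect_equal(perfect$confusion$TNR, 100)
  expect_equal(perfect$confusion$TPR, 100)
  expect_equal(perfect$auc, 1)
  expect_error(confusion_and_roc(1:3, factor(rep("LS", 3), levels = c("CON", "LS"))),
               "both classes")
})

test_that("AUC is invariant to strictly monotone score transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:20) {
    labels <- factor(sample(rep(c("CON", "LS"), c(7, 9))), levels = c("CON", "LS"))
    scores <- rnorm(16)
    a1 <- confusion_and_roc(scores, labels)$auc
    a2 <- confusion_and_roc(exp(2 * scores), labels)$auc
    expect_equal(a1, a2, tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                levels = c("CON", "LS"),
                                                direction = "<")))
    expect_equal(a1, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("label-independent scores give chance-level AUC on average", {
  set.seed(42)
  labels <- factor(rep(c("CON", "LS"), c(9, 15)), levels = c("CON", "LS"))
  aucs <- vapply(1:1000, function(i)
    confusion_and_roc(rnorm(24), labels)$auc, 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("scrambled controls are seeded, count-preserving permutations", {
  fm <- sep_features()
  r1 <- scrambled_control(fm, "logistic", seed = 11)
  r2 <- scrambled_control(fm, "logistic", seed = 11)
  expect_identical(r1$per_subject$score, r2$per_subject$score)
  expect_equal(table(r1$per_subject$true), table(fm$y))
  r3 <- scrambled_control(fm, "logistic", seed = 12)
  expect_false(identical(r1$per_subject$true, r3$per_subject$true))
})
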