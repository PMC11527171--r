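#' Build a classifier feature matrix from per-subject regional delta-SUVs
#'
#' Rows are subjects, columns the eight regional mean delta-SUVs in a fixed
#' recorded order; CON is the negative class and LS the positive class.
#'
#' @param subject_means output of [subject_region_mean()] over the cohort
#' @param labels named character vector subject -> group
#' @param regions column order (defaults to the regions present, sorted)
#' @return object of class \code{feature_matrix}: list(X, y, regions)
#' @export
feature_matrix <- function(subject_means, labels,
                           regions = sort(unique(subject_means$region))) {
  subjects <- sort(unique(subject_means$subject))
  X <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  for (k in seq_len(nrow(subject_means)))
    X[subject_means$subject[k], subject_means$region[k]] <- subject_means$mean_delta[k]
  if (anyNA(X)) stopf("feature_matrix: missing region values for some subjects")
  y <- factor(labels[subjects], levels = c("CON", "LS"))
  if (anyNA(y)) stopf("feature_matrix: labels missing for some subjects")
  structure(list(X = X, y = y, regions = regions), class = "feature_matrix")
}

# stratified fold assignment depending only on (seed, y), never on X
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Train a GentleBoost stump ensemble
#'
#' Gentle AdaBoost with weighted-least-squares regression stumps: weights
#' start at 1/n; each round the stump (feature, threshold, left value,
#' right value) minimizing weighted squared error against y in {-1, +1} is
#' added to the score F, and weights are updated w <- w * exp(-y * f(x)) and
#' renormalized. Region outputs are weighted means of y so lie in [-1, 1],
#' which keeps the training exponential loss nonincreasing. With all-equal
#' feature values the stump degenerates to the class-weighted mean on both
#' sides and the model remains valid.
#'
#' @param X numeric matrix (n x p)
#' @param y numeric vector in {-1, +1}
#' @param n_rounds boosting rounds
#' @return object of class \code{boost_model}: list(rounds, n_rounds,
#'   loss_trace) where each round is (feature, threshold, left, right)
#' @export
train_gentleboost <- function(X, y, n_rounds = 100) {
  n <- nrow(X)
  if (n < 2) stopf("need >= 2 samples")
  if (!all(y %in% c(-1, 1))) stopf("y must be in {-1, +1}")
  if (length(unique(y)) < 2) warnf("single-class training data")
  w <- rep(1 / n, n)
  Fscore <- numeric(n)
  rounds <- vector("list", n_rounds)
  loss <- numeric(n_rounds)
  for (t in seq_len(n_rounds)) {
    best <- NULL; best_err <- Inf
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      ux <- sort(unique(xj))
      thr <- if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2
             else ux[1]  # degenerate: all rows on one side
      for (th in thr) {
        left <- xj < th
        wl <- sum(w[left]); wr <- sum(w[!left])
        a <- if (wl > 0) sum(w[left] * y[left]) / wl else sum(w * y)
        b <- if (wr > 0) sum(w[!left] * y[!left]) / wr else sum(w * y)
        f <- ifelse(left, a, b)
        err <- sum(w * (y - f)^2)
        if (err < best_err - 1e-15) {
          best_err <- err
          best <- list(feature = j, threshold = th, left = a, right = b)
        }
      }
    }
    f <- ifelse(X[, best$feature] < best$threshold, best$left, best$right)
    Fscore <- Fscore + f
    w <- w * exp(-y * f)
    w <- w / sum(w)
    rounds[[t]] <- best
    loss[t] <- mean(exp(-y * Fscore))
  }
  structure(list(rounds = rounds, n_rounds = n_rounds, loss_trace = loss),
            class = "boost_model")
}

#' Predict GentleBoost decision scores
#'
#' @param model a \code{boost_model}
#' @param X matrix of feature rows
#' @param n_rounds evaluate only the first n_rounds stumps (defaults to all)
#' @return numeric decision scores (sign is the predicted class)
#' @export
predict_gentleboost <- function(model, X, n_rounds = model$n_rounds) {
  s <- numeric(nrow(X))
  for (t in seq_len(min(n_rounds, model$n_rounds))) {
    r <- model$rounds[[t]]
    s <- s + ifelse(X[, r$feature] < r$threshold, r$left, r$right)
  }
  s
}

# Train one classifier on (X, y) with hyperparameters tuned by stratified
# inner k-fold CV; fold assignment and tuning depend only on (seed, y).
# Returns a self-contained model with a score() closure (positive = LS).
train_fold <- function(X, y, model_kind, seed, inner_k = 5) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  # inner CV needs every training split to keep both classes with >= 2
  # members; with very small classes, tuning is skipped in favor of
  # mid-grid defaults
  tune <- min(table(y)) >= 4
  k <- max(2, min(inner_k, min(table(y)) %/% 2))
  fold <- stratified_folds(y, k, seed)
  if (model_kind == "logistic") {
    # glmnet needs >= 2 columns; pad single-feature data with a zero column
    # (its ridge coefficient is identically 0)
    pad <- ncol(Xs) == 1
    pad_x <- function(M) if (pad) cbind(M, 0) else M
    Xs <- pad_x(Xs)
    lambdas <- 10^seq(1, -4, length.out = 12)
    if (tune) {
      dev <- numeric(length(lambdas))
      for (fk in seq_len(k)) {
        tr <- fold != fk; va <- !tr
        fit <- suppressWarnings(
          glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], family = "binomial",
                         alpha = 0, lambda = lambdas, standardize = FALSE))
        lp <- predict(fit, Xs[va, , drop = FALSE], s = lambdas, type = "link")
        yv <- as.numeric(y[va] == "LS")
        for (li in seq_along(lambdas)) {
          p <- 1 / (1 + exp(-lp[, li]))
          p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
          dev[li] <- dev[li] - 2 * sum(yv * log(p) + (1 - yv) * log(1 - p))
        }
      }
      lam <- lambdas[which.min(dev)]  # which.min ties -> first (largest lambda)
    } else lam <- 0.1
    fit <- suppressWarnings(
      glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                     lambda = lambdas, standardize = FALSE))
    model <- list(fit = fit, lambda = lam)
    score <- function(m, Xnew) {
      Xn <- pad_x(scale(Xnew, center = mu, scale = sdv))
      as.numeric(predict(m$fit, Xn, s = m$lambda, type = "link"))
    }
  } else if (model_kind == "svm") {
    costs <- 2^seq(-5, 5, by = 2)
    if (tune) {
      errs <- numeric(length(costs))
      for (fk in seq_len(k)) {
        tr <- fold != fk; va <- !tr
        for (ci in seq_along(costs)) {
          m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                          cost = costs[ci], scale = FALSE)
          errs[ci] <- errs[ci] + sum(predict(m, Xs[va, , drop = FALSE]) != y[va])
        }
      }
      cost <- costs[which.min(errs)]
    } else cost <- 1
    fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
    model <- list(fit = fit, cost = cost)
    score <- function(m, Xnew) {
      Xn <- scale(Xnew, center = mu, scale = sdv)
      pr <- predict(m$fit, Xn, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients decision values toward the first label in its header
      if (grepl("^LS/", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
    }
  } else if (model_kind == "gentleboost") {
    ynum <- ifelse(y == "LS", 1, -1)
    rounds_grid <- c(10, 30, 100)
    if (tune) {
      errs <- numeric(length(rounds_grid))
      for (fk in seq_len(k)) {
        tr <- fold != fk; va <- !tr
        m <- train_gentleboost(Xs[tr, , drop = FALSE], ynum[tr],
                               n_rounds = max(rounds_grid))
        for (ri in seq_along(rounds_grid)) {
          s <- predict_gentleboost(m, Xs[va, , drop = FALSE], rounds_grid[ri])
          errs[ri] <- errs[ri] + sum(sign(s) != ynum[va] & s != 0) + sum(s == 0 & ynum[va] != 1)
        }
      }
      nr <- rounds_grid[which.min(errs)]
    } else nr <- 100
    fit <- train_gentleboost(Xs, ynum, n_rounds = nr)
    model <- list(fit = fit, n_rounds = nr)
    score <- function(m, Xnew) {
      Xn <- scale(Xnew, center = mu, scale = sdv)
      predict_gentleboost(m$fit, Xn)
    }
  } else stopf("unknown model_kind %s", model_kind)
  structure(list(model_kind = model_kind, model = model, center = mu,
                 scale = sdv, score = score),
            class = "fold_model")
}

#' Train the model of one leave-one-out iteration
#'
#' Exposes the per-iteration training step of [loocv()]: the model is fit on
#' all rows except \code{i} (the held-out subject never influences it), with
#' hyperparameters tuned by stratified inner cross-validation on the
#' remaining rows only.
#'
#' @param features a \code{feature_matrix}
#' @param i index of the held-out subject
#' @param model_kind "logistic", "svm" or "gentleboost"
#' @param seed integer seed (inner folds derived per iteration)
#' @return a \code{fold_model}; call \code{fold_model_score(m, X)} on new rows
#' @export
loocv_fold <- function(features, i, model_kind, seed = 1L) {
  X <- features$X[-i, , drop = FALSE]
  y <- droplevels(features$y[-i])
  if (nlevels(y) < 2) stopf("a class is absent from the training fold")
  train_fold(X, y, model_kind, derive_seed(seed, "fold", i))
}

#' Decision scores of a fold model on new feature rows
#' @param m a \code{fold_model}
#' @param X matrix of feature rows (original, unstandardized scale)
#' @return numeric scores, positive = LS
#' @export
fold_model_score <- function(m, X) m$score(m$model, X)

#' Leave-one-out cross-validated classification
#'
#' For each subject, a model is trained on all other subjects (features
#' standardized and hyperparameters tuned by stratified inner CV inside the
#' iteration, so the held-out row never leaks into training) and the
#' held-out subject's decision score and hard prediction are recorded. A
#' raw score of exactly 0 predicts the positive class (LS).
#'
#' The ROC pools the held-out scores across iterations, after calibrating
#' each score by the mean decision score of its own training fold. Raw
#' scores from different folds are not comparable: each fold's score offset
#' reflects its training class mix, which depends on the held-out subject's
#' class and would deterministically anti-order the classes whenever the
#' features carry no signal. Per-fold centering removes exactly that offset
#' (an uninformative model then scores every subject 0, giving the chance
#' AUC of 0.5) and leaves within-fold orderings, hence informative
#' classifiers, unchanged.
#'
#' @param features a \code{feature_matrix}
#' @param model_kind "logistic", "svm" or "gentleboost"
#' @param seed integer seed for the inner-CV folds
#' @return object of class \code{loocv_result}: list(per_subject (with raw
#'   and fold-calibrated scores), confusion, roc, auc, model_kind, seed)
#' @export
loocv <- function(features, model_kind = c("logistic", "svm", "gentleboost"),
                  seed = 1L) {
  model_kind <- match.arg(model_kind)
  y <- features$y
  if (any(table(y) < 2)) stopf("need >= 2 subjects per class")
  n <- nrow(features$X)
  scores <- numeric(n)
  cal_scores <- numeric(n)
  for (i in seq_len(n)) {
    m <- loocv_fold(features, i, model_kind, seed)
    scores[i] <- fold_model_score(m, features$X[i, , drop = FALSE])
    cal_scores[i] <- scores[i] -
      mean(fold_model_score(m, features$X[-i, , drop = FALSE]))
  }
  pred <- factor(ifelse(scores >= 0, "LS", "CON"), levels = levels(y))
  cr <- confusion_and_roc(cal_scores, y, predictions = pred)
  structure(list(per_subject = data.frame(subject = rownames(features$X),
                                          true = y, predicted = pred,
                                          score = cal_scores,
                                          score_raw = scores,
                                          stringsAsFactors = FALSE),
                 confusion = cr$confusion, roc = cr$roc, auc = cr$auc,
                 model_kind = model_kind, seed = seed),
            class = "loocv_result")
}

#' Confusion rates, ROC curve and AUC
#'
#' CON is the negative class and LS the positive class. Hard predictions
#' give the confusion counts and percentage rates (TNR/FPR among true
#' negatives, FNR/TPR among true positives). The ROC sweeps all decision
#' thresholds (predict positive when score >= t), runs from (0,0) to (1,1)
#' with nondecreasing FPR, and AUC is the trapezoid-rule area.
#'
#' @param scores numeric decision scores, larger = more LS-like
#' @param labels factor with levels c("CON", "LS")
#' @param predictions optional hard predictions; default sign(score)
#' @return list(confusion = counts + rates (percent), roc = data.frame(fpr,
#'   tpr), auc)
#' @export
confusion_and_roc <- function(scores, labels, predictions = NULL) {
  labels <- factor(labels, levels = c("CON", "LS"))
  if (nlevels(droplevels(labels)) < 2) stopf("both classes must be present")
  if (is.null(predictions))
    predictions <- factor(ifelse(scores >= 0, "LS", "CON"), levels = levels(labels))
  pos <- labels == "LS"
  TP <- sum(pos & predictions == "LS"); FN <- sum(pos & predictions == "CON")
  TN <- sum(!pos & predictions == "CON"); FP <- sum(!pos & predictions == "LS")
  confusion <- list(counts = c(TN = TN, FP = FP, FN = FN, TP = TP),
                    TNR = 100 * TN / (TN + FP), FPR = 100 * FP / (TN + FP),
                    FNR = 100 * FN / (TP + FN), TPR = 100 * TP / (TP + FN))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # step only at distinct score values so ties move diagonally
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[keep] / sum(pos))
  fpr <- c(0, cumsum(!p)[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(confusion = confusion, roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Scrambled-label control for LOOCV
#'
#' Permutes the class labels uniformly at random (seeded) and reruns the
#' identical LOOCV pipeline; class counts are preserved by construction.
#'
#' @inheritParams loocv
#' @return a \code{loocv_result} (with \code{scrambled = TRUE})
#' @export
scrambled_control <- function(features, model_kind = c("logistic", "svm", "gentleboost"),
                              seed = 1L) {
  model_kind <- match.arg(model_kind)
  perm <- with_seed(derive_seed(seed, "scramble"), sample(seq_along(features$y)))
  f2 <- features
  f2$y <- features$y[perm]
  res <- loocv(f2, model_kind, seed = seed)
  res$scrambled <- TRUE
  res
}
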