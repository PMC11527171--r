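#' Nested mixed-model group test for one region's delta-SUVs
#'
#' Fits delta_suv ~ group + (1 | subject) by REML: a fixed two-level group
#' effect with a random intercept per subject absorbs the correlation among
#' the multiple slice/hemisphere records of each mouse. The group effect is
#' tested with an F statistic (squared Wald t) against the conservative
#' between-subject denominator df, n_subjects - 2.
#'
#' When every subject contributes exactly one record the random intercept is
#' unidentifiable; the model then reduces exactly to ordinary least squares
#' and the function takes that path, reproducing the pooled two-sample t
#' test (F = t^2). A between-subject variance estimated at the boundary
#' (zero) is reported via \code{singular = TRUE} with a warning; F and p are
#' still returned.
#'
#' @param delta delta-SUV table restricted to one region
#' @param labels named character vector subject -> group (two groups)
#' @return object of class \code{lmm_result}: list(group_effect_estimate,
#'   se, F_stat, p_value, df_num, df_den, group_means, n_obs, n_subjects,
#'   groups, singular)
#' @export
lmm_group_test <- function(delta, labels) {
  if (length(unique(delta$region)) > 1)
    stopf("lmm_group_test expects records from a single region")
  subj <- as.character(delta$subject)
  grp <- labels[subj]
  if (any(is.na(grp))) stopf("labels missing for subject(s): %s",
                             paste(unique(subj[is.na(grp)]), collapse = ", "))
  glev <- sort(unique(labels))
  if (length(glev) != 2) stopf("need exactly two groups")
  n_subjects <- length(unique(subj))
  per_group <- table(labels[unique(subj)])
  if (any(per_group < 2)) stopf("need >= 2 subjects per group")
  d <- data.frame(y = delta$delta_suv,
                  group = factor(grp, levels = glev),
                  subject = factor(subj))
  one_per_subject <- max(table(d$subject)) == 1
  singular <- FALSE
  if (one_per_subject) {
    fit <- lm(y ~ group, data = d)
    est <- coef(fit)[["group" %+% glev[2]]]
    se <- summary(fit)$coefficients[2, 2]
    intercept <- coef(fit)[[1]]
    singular <- TRUE
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ group + (1 | subject), data = d, REML = TRUE)))
    singular <- lme4::isSingular(fit)
    if (singular)
      warnf("between-subject variance estimated at boundary zero; F/p still reported")
    cf <- lme4::fixef(fit)
    est <- cf[[2]]
    se <- sqrt(diag(as.matrix(vcov(fit))))[2]
    intercept <- cf[[1]]
  }
  df_den <- n_subjects - 2
  F_stat <- (est / se)^2
  p <- pf(F_stat, 1, df_den, lower.tail = FALSE)
  gm <- c(intercept, intercept + est)
  names(gm) <- glev
  structure(list(group_effect_estimate = est, se = se, F_stat = F_stat,
                 p_value = p, df_num = 1, df_den = df_den, group_means = gm,
                 n_obs = nrow(d), n_subjects = n_subjects, groups = glev,
                 singular = singular),
            class = "lmm_result")
}

`%+%` <- function(a, b) paste0(a, b)

#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance, df = n_a + n_b - 2, two-sided p. With
#' zero pooled variance the limit behavior is documented: equal means give
#' T = 0, p = 1; unequal means give T = +/-Inf, p = 0.
#'
#' @param a,b numeric vectors of per-subject values (each length >= 2)
#' @return object of class \code{t_test_result}: list(means, T_stat,
#'   p_value, df)
#' @export
t_test_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs >= 2 values")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      T_stat <- 0; p <- 1
    } else {
      T_stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    ht <- t.test(a, b, var.equal = TRUE)
    T_stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(means = c(a = mean(a), b = mean(b)), T_stat = T_stat,
                 p_value = p, df = df),
            class = "t_test_result")
}

#' Regional delta-SUV vs freezing correlation
#'
#' Least-squares line and Pearson product-moment r for per-subject points
#' (mean regional delta-SUV, percent freezing). A constant x or y makes r
#' undefined; the result then carries \code{defined = FALSE} with NA
#' statistics rather than reporting 0.
#'
#' @param x per-subject mean delta-SUV (length >= 3)
#' @param y per-subject percent freezing, same length
#' @return object of class \code{correlation_result}: list(slope, intercept,
#'   pearson_r, n, defined)
#' @export
region_behavior_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3) stopf("need n >= 3 points")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          pearson_r = NA_real_, n = length(x),
                          defined = FALSE),
                     class = "correlation_result"))
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = cor(x, y), n = length(x), defined = TRUE),
            class = "correlation_result")
}

#' Mann-Whitney U test (utility)
#'
#' Thin wrapper over \code{stats::wilcox.test} for the nonparametric
#' two-sample comparisons occasionally used alongside the t test.
#'
#' @param a,b numeric vectors
#' @return htest object
#' @export
mann_whitney <- function(a, b) wilcox.test(a, b, exact = FALSE)
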