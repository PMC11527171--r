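make_trace <- function(scores, rate = 10) {
  structure(list(times_s = (seq_along(scores) - 1) / rate, scores = scores,
                 frame_rate_hz = rate), class = "activity_trace")
}

test_that("binarization uses a strict threshold and records it", {
  s <- binarize_activity(make_trace(rep(0, 10)), threshold = 1)
  expect_true(all(s$inactive))
  expect_identical(s$threshold_used, 1)
  s <- binarize_activity(make_trace(rep(5, 10)), threshold = 5)
  expect_false(any(s$inactive))  # scores equal to threshold count as active
  s <- binarize_activity(make_trace(c(0, 5, 0)), threshold = 1)
  expect_identical(s$inactive, c(TRUE, FALSE, TRUE))
  expect_error(binarize_activity(make_trace(numeric(0))), "empty")
})

test_that("percent freezing follows the per-bin definition", {
  # 100 frames in one 10-s bin at 10 Hz, 30 inactive
  s <- binarize_activity(make_trace(c(rep(0, 30), rep(50, 70))), threshold = 1)
  pf <- percent_freezing(s, bin_s = 10)
  expect_equal(pf$binned$pct, 30)
  expect_equal(pf$session_pct, 30)
  # all inactive: every bin and the session at 100
  s <- binarize_activity(make_trace(rep(0, 300)), threshold = 1)
  pf <- percent_freezing(s, bin_s = 10)
  expect_true(all(pf$binned$pct == 100))
  expect_equal(pf$session_pct, 100)
  # two complete bins at 20% and 40% average to 30
  sc <- c(rep(0, 20), rep(50, 80), rep(0, 40), rep(50, 60))
  pf <- percent_freezing(binarize_activity(make_trace(sc), threshold = 1),
                         bin_s = 10)
  expect_equal(pf$binned$pct, c(20, 40))
  expect_equal(pf$session_pct, 30)
  expect_error(percent_freezing(binarize_activity(make_trace(rep(0, 10))),
                                window = c(0, 100)), "outside trace")
})

test_that("a trailing partial bin is reported but excluded from the session mean", {
  sc <- c(rep(0, 100), rep(0, 50))  # 15 s at 10 Hz: one full bin + 5-s tail
  pf <- percent_freezing(binarize_activity(make_trace(sc), threshold = 1),
                         bin_s = 10)
  expect_identical(pf$binned$complete, c(TRUE, FALSE))
  expect_equal(pf$session_pct, 100)
})

test_that("bout detection keeps runs at or above the minimum duration", {
  tr <- trace_with_runs(run_starts_s = c(10, 50, 100),
                        run_durations_s = c(1.5, 2.0, 5.0))
  b <- detect_bouts(binarize_activity(tr))
  expect_equal(nrow(b), 2)  # the 2.0 s boundary run is included
  expect_equal(b$duration_s, c(2.0, 5.0))
  expect_equal(b$start_s, c(50, 100))
  # fully active trace
  expect_equal(nrow(detect_bouts(binarize_activity(make_trace(rep(50, 100))))), 0)
  # fully inactive 8-min trace: one 480-s bout from time 0
  b <- detect_bouts(binarize_activity(make_trace(rep(0, 4800))))
  expect_equal(nrow(b), 1)
  expect_equal(b$start_s, 0)
  expect_equal(b$duration_s, 480)
})

test_that("bout totals are bounded by the session and raising the threshold is monotone", {
  set.seed(31)
  for (rep in 1:20) {
    tr <- generate_activity_trace(list(freezing_frac = runif(1, 0.2, 0.8),
                                       mean_bout_s = runif(1, 2, 8),
                                       bout_cv = 1), 10, 120, seed = rep)
    s <- binarize_activity(tr)
    b <- detect_bouts(s)
    expect_lte(sum(b$duration_s), 120 + 1e-9)
    expect_lte(nrow(b), length(rle(s$inactive)$lengths))
    lo <- percent_freezing(binarize_activity(tr, threshold = 15))$binned$pct
    hi <- percent_freezing(binarize_activity(tr, threshold = 30))$binned$pct
    expect_true(all(hi >= lo - 1e-12))
  }
})

test_that("session percent equals the overall inactive fraction for complete equal bins", {
  tr <- generate_activity_trace(list(freezing_frac = 0.5, mean_bout_s = 4,
                                     bout_cv = 1), 10, 200, seed = 8)
  s <- binarize_activity(tr)
  pf <- percent_freezing(s, bin_s = 10)
  expect_true(all(pf$binned$complete))
  expect_equal(pf$session_pct, 100 * mean(s$inactive), tolerance = 1e-12)
})

test_that("two-sample KS matches simple closed-form cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "nonempty")
})

test_that("KS statistic agrees exactly with a brute-force ECDF oracle", {
  set.seed(77)
  for (i in 1:1000) {
    n_a <- sample(2:12, 1); n_b <- sample(2:12, 1)
    a <- round(rnorm(n_a), 1)  # rounding forces ties across samples
    b <- round(rnorm(n_b, sd = runif(1, 0.5, 2)), 1)
    r <- ks_two_sample(a, b)
    expect_identical(r$D, ks_oracle_D(a, b))
  }
  # asymptotic p matches the reference implementation
  set.seed(3)
  a <- rnorm(80); b <- rnorm(90, 0.3)
  r <- ks_two_sample(a, b)
  ref <- suppressWarnings(ks.test(a, b, exact = FALSE))
  expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})
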