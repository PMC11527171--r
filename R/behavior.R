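#' Binarize an activity trace into mobility/immobility flags
#'
#' A frame is inactive iff its activity score is strictly below the
#' threshold; with a zero threshold nothing is scored as freezing, the safe
#' degenerate case. The threshold used is recorded in the output.
#'
#' @param trace an \code{activity_trace} (list with times_s, scores,
#'   frame_rate_hz)
#' @param threshold activity threshold (>= 0)
#' @return object of class \code{freezing_series}: list(times_s, inactive,
#'   frame_rate_hz, threshold_used)
#' @export
binarize_activity <- function(trace, threshold = activity_threshold_default()) {
  if (!length(trace$scores)) stopf("empty trace")
  if (length(trace$times_s) != length(trace$scores))
    stopf("times and scores lengths differ")
  if (is.unsorted(trace$times_s, strictly = TRUE))
    stopf("times must be strictly increasing")
  if (threshold < 0) stopf("threshold must be >= 0")
  structure(list(times_s = trace$times_s,
                 inactive = trace$scores < threshold,
                 frame_rate_hz = trace$frame_rate_hz,
                 threshold_used = threshold),
            class = "freezing_series")
}

#' Percent freezing in fixed bins and over a session window
#'
#' Per-bin value is 100 x (inactive frames) / (frames in bin), on 10-s bins
#' by default. The session value is the unweighted mean over complete bins
#' inside the analysis window; a trailing partial bin is reported
#' (\code{complete = FALSE}) but excluded from the session mean. The window
#' may be a single c(start, end) range or a list of ranges (e.g. the
#' tone + trace intervals of the conditioning session), in which case bins
#' are laid out within each range and the session mean pools complete bins
#' across ranges.
#'
#' @param series a \code{freezing_series}
#' @param bin_s bin width in seconds (> 0)
#' @param window NULL (whole trace), c(start, end), or list of ranges
#' @return the series with added \code{binned} data.frame (window_id,
#'   bin_start, bin_end, n_frames, pct, complete) and \code{session_pct}
#' @export
percent_freezing <- function(series, bin_s = 10, window = NULL) {
  if (bin_s <= 0) stopf("bin_s must be > 0")
  t0 <- series$times_s[1]
  t_end <- series$times_s[length(series$times_s)] + 1 / series$frame_rate_hz
  windows <- if (is.null(window)) list(c(t0, t_end))
             else if (is.numeric(window)) list(window) else window
  rows <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    if (length(w) != 2 || w[1] >= w[2]) stopf("window must be c(start, end) with start < end")
    if (w[1] < t0 - 1e-9 || w[2] > t_end + 1e-9)
      stopf("window [%g, %g] outside trace [%g, %g]", w[1], w[2], t0, t_end)
    starts <- seq(w[1], w[2] - 1e-12, by = bin_s)
    for (bs in starts) {
      be <- min(bs + bin_s, w[2])
      sel <- series$times_s >= bs - 1e-9 & series$times_s < be - 1e-9
      nfr <- sum(sel)
      if (nfr == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        window_id = wi, bin_start = bs, bin_end = be, n_frames = nfr,
        pct = 100 * sum(series$inactive[sel]) / nfr,
        complete = (be - bs) >= bin_s - 1e-9)
    }
  }
  binned <- do.call(rbind, rows)
  series$binned <- binned
  series$bin_s <- bin_s
  series$session_pct <- if (any(binned$complete)) mean(binned$pct[binned$complete]) else NA_real_
  series
}

#' Detect freezing bouts
#'
#' Maximal runs of consecutive inactive frames in the unbinned flags are
#' converted to (start time, duration = run length / frame rate); runs at
#' least \code{min_duration_s} long are kept (a run of exactly the minimum
#' counts). Runs are not merged across single-frame activity blips and no
#' smoothing is applied.
#'
#' @param series a \code{freezing_series}
#' @param min_duration_s minimum bout duration in seconds
#' @return data.frame with columns start_s, duration_s (possibly 0 rows)
#' @export
detect_bouts <- function(series, min_duration_s = 2) {
  if (is.null(series$frame_rate_hz)) stopf("series lacks frame_rate_hz")
  fl <- series$inactive
  if (!length(fl) || !any(fl))
    return(data.frame(start_s = numeric(0), duration_s = numeric(0)))
  r <- rle(fl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / series$frame_rate_hz >= min_duration_s)
  data.frame(start_s = series$times_s[starts[keep]],
             duration_s = r$lengths[keep] / series$frame_rate_hz)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the exact supremum gap between the two empirical CDFs, evaluated at
#' the pooled sample points; the p-value uses the asymptotic two-sample
#' Smirnov distribution (appropriate for the hundreds of bout durations this
#' is applied to, not for tiny samples).
#'
#' @param sample_a,sample_b numeric vectors (nonempty)
#' @return object of class \code{ks_result}: list(D, p_value, n_a, n_b)
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stopf("both samples must be nonempty")
  a <- sort(sample_a); b <- sort(sample_b)
  pooled <- sort(unique(c(a, b)))
  ecdf_at <- function(s, x) findInterval(x, s) / length(s)
  D <- max(abs(ecdf_at(a, pooled) - ecdf_at(b, pooled)))
  n_a <- length(a); n_b <- length(b)
  ne <- n_a * n_b / (n_a + n_b)
  lambda <- sqrt(ne) * D
  # asymptotic Smirnov tail: 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
  if (lambda == 0) {
    p <- 1
  } else {
    k <- seq_len(100)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  structure(list(D = D, p_value = p, n_a = n_a, n_b = n_b),
            class = "ks_result")
}

#' Session freezing summary for one subject
#'
#' Convenience wrapper: binarize, bin, and average a trace over the default
#' analysis window of each session (F2: the tone + trace intervals; F3: the
#' last 4 minutes; F1: the whole session).
#'
#' @param trace an \code{activity_trace}
#' @param session "F1", "F2" or "F3"
#' @param threshold activity threshold
#' @param bin_s bin width (s)
#' @param f2_windows tone + trace ranges for F2 (see [default_f2_windows()])
#' @param f3_last_s length of the terminal F3 window (s)
#' @return list(session_pct, bouts, series)
#' @export
session_freezing <- function(trace, session,
                             threshold = activity_threshold_default(),
                             bin_s = 10,
                             f2_windows = default_f2_windows(),
                             f3_last_s = 240) {
  series <- binarize_activity(trace, threshold)
  t_end <- trace$times_s[length(trace$times_s)] + 1 / trace$frame_rate_hz
  window <- switch(session,
                   F1 = NULL,
                   F2 = f2_windows,
                   F3 = c(max(0, t_end - f3_last_s), t_end),
                   stopf("unknown session %s", session))
  series <- percent_freezing(series, bin_s = bin_s, window = window)
  list(session_pct = series$session_pct,
       bouts = detect_bouts(series),
       series = series)
}
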