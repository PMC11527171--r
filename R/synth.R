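#' Default activity threshold separating mobility from immobility
#'
#' The real activity threshold is user-set per experiment and no canonical
#' value exists; this default (20 pixel-change units) is arbitrary but
#' consistent between the trace generator and the scoring defaults, and is
#' configurable everywhere it is used.
#' @return numeric scalar
#' @export
activity_threshold_default <- function() 20

#' Generate one frame-wise activity trace with known freezing structure
#'
#' Simulates an alternating renewal process of immobility and mobility
#' runs: immobility-run (bout) durations are gamma with the requested mean
#' and coefficient of variation, mobility runs are exponential with mean
#' chosen so the long-run freezing fraction equals the target. The initial
#' state and residual run length are drawn from the equilibrium
#' distribution, so the expected freezing fraction over any window equals
#' the target without edge bias. Immobile frames receive activity scores
#' strictly below the threshold, mobile frames strictly above.
#'
#' @param params list(freezing_frac, mean_bout_s, bout_cv)
#' @param frame_rate_hz frames per second (> 0)
#' @param session_length_s session length in seconds (> 0)
#' @param seed integer seed
#' @param threshold activity threshold the scores are generated around
#' @return object of class \code{activity_trace}: list(times_s, scores,
#'   frame_rate_hz) with the generating threshold in attribute
#'   \code{"gen_threshold"}
#' @export
generate_activity_trace <- function(params, frame_rate_hz, session_length_s,
                                    seed = 1L,
                                    threshold = activity_threshold_default()) {
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be > 0")
  if (session_length_s <= 0) stopf("session_length_s must be > 0")
  f <- params$freezing_frac
  if (is.null(f) || f < 0 || f > 1) stopf("freezing_frac must be in [0, 1]")
  mean_imm <- params$mean_bout_s %||% 5
  cv <- params$bout_cv %||% 1
  if (mean_imm <= 0 || cv <= 0) stopf("mean_bout_s and bout_cv must be > 0")
  n <- round(frame_rate_hz * session_length_s)
  times <- (seq_len(n) - 1) / frame_rate_hz
  with_seed(seed, {
    if (f <= 0) {
      imm <- rep(FALSE, n)
    } else if (f >= 1) {
      imm <- rep(TRUE, n)
    } else {
      shape <- 1 / cv^2
      scale <- mean_imm * cv^2
      mean_mob <- mean_imm * (1 - f) / f
      draw_imm <- function() rgamma(1, shape = shape, scale = scale)
      draw_mob <- function() rexp(1, rate = 1 / mean_mob)
      # equilibrium start: state ~ Bernoulli(f); residual of the run in
      # progress is U * (length-biased duration); exponential runs are
      # memoryless so a fresh draw suffices
      state <- runif(1) < f
      first <- if (state) {
        runif(1) * rgamma(1, shape = shape + 1, scale = scale)
      } else draw_mob()
      bounds <- first
      states <- state
      while (sum(bounds) < session_length_s) {
        state <- !state
        states <- c(states, state)
        bounds <- c(bounds, if (state) draw_imm() else draw_mob())
      }
      edges <- cumsum(bounds)
      run_of_frame <- findInterval(times, edges, left.open = FALSE) + 1
      imm <- states[pmin(run_of_frame, length(states))]
    }
    scores <- numeric(n)
    scores[imm] <- runif(sum(imm), 0, 0.5) * threshold
    scores[!imm] <- runif(sum(!imm), 1.2, 4) * threshold
  })
  structure(list(times_s = times, scores = scores,
                 frame_rate_hz = frame_rate_hz),
            class = "activity_trace", gen_threshold = threshold)
}

# Structured offsets for one region in one scan: planted increment (F3 only)
# plus subject/hemisphere/slice noise, written into `vol`; returns the total
# added over region voxels so the background can be compensated.
add_region_offsets <- function(vol, sp, midline_x, inc, u, sd_hemisphere, sd_slice) {
  total <- 0
  hemis <- if (isTRUE(sp$bilateral)) c("L", "R") else "BOTH"
  for (h in hemis) {
    xs <- switch(h,
                 L = seq(sp$x_left[1], sp$x_left[2]),
                 R = seq(sp$x_right[1], sp$x_right[2]),
                 BOTH = seq(sp$x[1], sp$x[2]))
    ys <- seq(sp$y[1], sp$y[2])
    h_off <- rnorm(1, 0, sd_hemisphere)
    for (z in sp$slices) {
      s_off <- rnorm(1, 0, sd_slice)
      off <- inc + u + h_off + s_off
      vol[xs, ys, z] <- vol[xs, ys, z] + off
      total <- total + off * length(xs) * length(ys)
    }
  }
  list(vol = vol, total = total)
}

# One raw (unnormalized) scan volume for a subject/session. Built on the
# normalized scale (whole-brain mean 1 before voxel noise, with the
# structured regional offsets compensated in the background so planted
# increments survive whole-brain-mean normalization exactly at zero noise),
# then multiplied by an arbitrary positive global scale.
generate_scan <- function(cfg, masks, brain, subject_id, group, session, seed) {
  with_seed(seed, {
    g <- cfg$grid_shape
    vol <- array(0, g)
    vol[brain] <- 1
    u <- rnorm(1, 0, cfg$sd_subject)
    total <- 0
    region_any <- array(FALSE, g)
    for (sp in cfg$region_specs) {
      inc <- if (session == "F3") cfg$effect_map[[group]][[sp$region]] else 0
      res <- add_region_offsets(vol, sp, masks$midline_x, inc, u,
                                cfg$sd_hemisphere, cfg$sd_slice)
      vol <- res$vol
      total <- total + res$total
      region_any <- region_any | masks$masks[[sp$region]]
    }
    bg <- brain & !region_any
    vol[bg] <- vol[bg] - total / sum(bg)
    if (cfg$sd_voxel > 0)
      vol[brain] <- vol[brain] + rnorm(sum(brain), 0, cfg$sd_voxel)
    scale <- exp(rnorm(1, 0, 0.2)) * 100  # arbitrary raw-uptake scale
    scan_volume(vol * scale, subject_id, session,
                voxel_size_mm = cfg$voxel_size_mm, normalized = FALSE)
  })
}

#' Generate a synthetic two-scan cohort with known ground truth
#'
#' Emulates the two-scan contextual-threat design: each subject gets a
#' baseline (F1) and recall (F3) registered volume on a common grid, with
#' group-specific planted regional uptake increments appearing only in F3,
#' nested Gaussian noise (subject > hemisphere > slice > voxel), and
#' frame-wise activity traces for the three behavioral sessions with
#' group-dependent freezing structure. Deterministic given the config seed;
#' per-subject random streams are derived by stable hashing of
#' (seed, subject id, session) so results do not depend on generation order.
#'
#' @param cfg a validated \code{synth_config}
#' @param traces generate behavioral activity traces (disable for
#'   imaging-only simulation studies)
#' @return object of class \code{synthetic_cohort}: list(config, masks,
#'   brain_mask, subjects); each subject is list(id, group, scans =
#'   list(F1, F3), traces = list(F1, F2, F3), ground_truth)
#' @export
generate_cohort <- function(cfg, traces = TRUE) {
  validate_synth_config(cfg)
  masks <- region_mask_set(cfg$region_specs, cfg$grid_shape)
  brain <- brain_mask_box(cfg$grid_shape, cfg$brain_margin_frac)
  for (rg in names(masks$masks))
    if (any(masks$masks[[rg]] & !brain))
      stopf("region_specs: %s footprint extends outside the brain mask", rg)
  ids <- c(sprintf("CON%02d", seq_len(cfg$n_con)),
           sprintf("LS%02d", seq_len(cfg$n_ls)))
  groups <- c(rep("CON", cfg$n_con), rep("LS", cfg$n_ls))
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]; grp <- groups[i]
    scans <- list(
      F1 = generate_scan(cfg, masks, brain, id, grp, "F1",
                         derive_seed(cfg$seed, id, "scan", "F1")),
      F3 = generate_scan(cfg, masks, brain, id, grp, "F3",
                         derive_seed(cfg$seed, id, "scan", "F3")))
    trc <- list()
    if (traces) {
      for (ss in c("F1", "F2", "F3")) {
        trc[[ss]] <- generate_activity_trace(
          cfg$behavior_params[[grp]][[ss]], cfg$frame_rate_hz,
          cfg$session_length_s[[ss]],
          seed = derive_seed(cfg$seed, id, "trace", ss))
      }
    }
    gt <- list(
      planted_increment = cfg$effect_map[[grp]],
      planted_freezing = vapply(cfg$behavior_params[[grp]],
                                function(p) p$freezing_frac, 0))
    subjects[[i]] <- list(id = id, group = grp, scans = scans,
                          traces = trc, ground_truth = gt)
  }
  names(subjects) <- ids
  structure(list(config = cfg, masks = masks, brain_mask = brain,
                 subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d CON + %d LS subjects, grid %s, seed %d\n",
              x$config$n_con, x$config$n_ls,
              paste(x$config$grid_shape, collapse = "x"), x$config$seed))
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort a \code{synthetic_cohort}
#' @return named character vector subject -> group
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "group")
}

#' Full delta-SUV table for a cohort
#'
#' Runs the differential pipeline (whole-brain-mean normalization, regional
#' SUV extraction, F3 - F1 subtraction) for every subject and row-binds the
#' per-record results.
#'
#' @param cohort a \code{synthetic_cohort}
#' @return data.frame: subject, region, slice_index, hemisphere, delta_suv,
#'   n_voxels
#' @export
cohort_delta_table <- function(cohort) {
  out <- lapply(cohort$subjects, function(su) {
    f1 <- region_suv_table(normalize_scan(su$scans$F1, cohort$brain_mask),
                           cohort$masks)
    f3 <- region_suv_table(normalize_scan(su$scans$F3, cohort$brain_mask),
                           cohort$masks)
    delta_suv(f1, f3)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
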