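# Small cohort configurations reused across tests. Noise SDs default to the
# package's study conditions; grids and region sets are scaled down so tests
# run at desk scale while preserving the record structure (BA keeps its
# 12 coronal slices x 2 hemispheres).

# single bilateral BA-like region on a 16^3 grid
ba_only_cfg <- function(seed, n_con = 9, n_ls = 15,
                        eff_con = 0.15, eff_ls = 0.049,
                        sd_subject = 0.03, sd_hemisphere = 0.015,
                        sd_slice = 0.04, sd_voxel = 0.10) {
  synth_config(
    grid_shape = c(16, 16, 16), n_con = n_con, n_ls = n_ls,
    region_specs = list(list(region = "BA", slices = 3:14, bilateral = TRUE,
                             x_left = c(3, 5), x_right = c(11, 13), y = c(6, 10))),
    effect_map = list(CON = c(BA = eff_con), LS = c(BA = eff_ls)),
    sd_subject = sd_subject, sd_hemisphere = sd_hemisphere,
    sd_slice = sd_slice, sd_voxel = sd_voxel, seed = seed)
}

# zero-noise full-region config (default grid, default planted effects)
zero_noise_cfg <- function(seed, n_con = 2, n_ls = 2) {
  synth_config(n_con = n_con, n_ls = n_ls,
               sd_subject = 0, sd_hemisphere = 0, sd_slice = 0, sd_voxel = 0,
               seed = seed)
}

# single midline block covering ~30% of a small brain mask, voxel noise only
block_cfg <- function(seed, eff = 0.1, sd_voxel = 0.05, n_con = 9) {
  synth_config(
    grid_shape = c(16, 16, 12), n_con = n_con, n_ls = 2,
    region_specs = list(list(region = "BLK", slices = 4:9, bilateral = FALSE,
                             x = c(4, 13), y = c(4, 13))),
    effect_map = list(CON = c(BLK = eff), LS = c(BLK = 0)),
    sd_subject = 0, sd_hemisphere = 0, sd_slice = 0, sd_voxel = sd_voxel,
    seed = seed)
}

# null config for ORT calibration runs: the detection scenario's geometry
# and noise with no planted effect
ort_null_cfg <- function(seed) block_cfg(seed, eff = 0, n_con = 9)

# normalized F1/F3 scan pairs for one group of a cohort
normalized_pairs <- function(cohort, group = "CON") {
  subs <- Filter(function(su) su$group == group, cohort$subjects)
  lapply(subs, function(su)
    list(F1 = normalize_scan(su$scans$F1, cohort$brain_mask),
         F3 = normalize_scan(su$scans$F3, cohort$brain_mask)))
}

# hand-built activity trace with specified inactivity runs (seconds);
# active frames score above the default threshold, inactive below
trace_with_runs <- function(run_starts_s, run_durations_s, length_s = 480,
                            rate_hz = 10) {
  n <- round(length_s * rate_hz)
  times <- (seq_len(n) - 1) / rate_hz
  thr <- activity_threshold_default()
  scores <- rep(2 * thr, n)
  for (k in seq_along(run_starts_s)) {
    i0 <- round(run_starts_s[k] * rate_hz) + 1
    len <- round(run_durations_s[k] * rate_hz)
    scores[i0:(i0 + len - 1)] <- 0.2 * thr
  }
  structure(list(times_s = times, scores = scores, frame_rate_hz = rate_hz),
            class = "activity_trace")
}

# brute-force two-sample KS oracle: evaluate both ECDFs on a dense
# comparison at every pooled sample point
ks_oracle_D <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), 0))
}
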