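#' Read a NIfTI-1 volume as a scan volume
#'
#' @param path path to a .nii or .nii.gz file
#' @param subject_id,session metadata to attach (parsed from the filename
#'   \code{<subject>_<session>.nii} if omitted)
#' @param normalized whether the stored volume is already normalized
#' @return a \code{scan_volume}
#' @export
read_volume <- function(path, subject_id = NULL, session = NULL,
                        normalized = FALSE) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("expected a NIfTI-1 file (.nii/.nii.gz), got: %s", basename(path))
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stopf("%s: expected a 3D volume", basename(path))
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3 || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0))
    stopf("%s: malformed header field pixdim", basename(path))
  if (is.null(subject_id)) {
    stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
    parts <- strsplit(stem, "_")[[1]]
    subject_id <- paste(parts[-length(parts)], collapse = "_")
    session <- parts[length(parts)]
  }
  scan_volume(array(as.numeric(img), dim = dim(img)), subject_id, session,
              voxel_size_mm = pix[1:3], normalized = normalized)
}

#' Write a scan volume (or plain array) as float32 NIfTI-1
#'
#' RAS+ orientation is recorded in the header via the default identity
#' orientation with the voxel spacings on the diagonal.
#'
#' @param vol a \code{scan_volume} or 3D array
#' @param path output path (.nii or .nii.gz)
#' @param voxel_size_mm voxel spacing when \code{vol} is a bare array
#' @return path, invisibly
#' @export
write_volume <- function(vol, path, voxel_size_mm = c(1, 1, 1)) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("output must be a .nii/.nii.gz path: %s", basename(path))
  arr <- if (inherits(vol, "scan_volume")) vol$voxels else vol
  sp <- if (inherits(vol, "scan_volume")) vol$voxel_size_mm else voxel_size_mm
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write an activity trace as CSV
#' @param trace an \code{activity_trace}
#' @param path output CSV path
#' @return path, invisibly
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times_s,
                              activity_score = trace$scores),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an activity trace from CSV
#' @param path CSV with columns time_s, activity_score
#' @param frame_rate_hz frame rate (inferred from timestamps if omitted)
#' @return an \code{activity_trace}
#' @export
read_trace <- function(path, frame_rate_hz = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "activity_score") %in% names(d)))
    stopf("%s: expected columns time_s, activity_score", basename(path))
  if (is.null(frame_rate_hz))
    frame_rate_hz <- 1 / stats::median(diff(d$time_s))
  structure(list(times_s = d$time_s, scores = d$activity_score,
                 frame_rate_hz = frame_rate_hz),
            class = "activity_trace")
}

#' Write a synthetic cohort to disk as standard formats
#'
#' Volumes as float32 NIfTI-1 (one file per subject and session), region
#' masks as a NIfTI-1 label volume plus a brain-mask volume, activity traces
#' as CSV, group labels as CSV, and ground truth plus a file manifest as
#' JSON. A round-trip read reproduces the in-memory cohort within float32
#' storage precision.
#'
#' @param cohort a \code{synthetic_cohort}
#' @param out_dir output directory (created if needed)
#' @return the manifest (list), invisibly
#' @export
write_fixtures <- function(cohort, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) stopf("cannot write to %s", out_dir)
  for (d in c("volumes", "masks", "traces"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  vox <- cohort$config$voxel_size_mm
  files <- list()
  for (su in cohort$subjects) {
    for (ss in c("F1", "F3")) {
      f <- file.path("volumes", sprintf("%s_%s.nii", su$id, ss))
      write_volume(su$scans[[ss]], file.path(out_dir, f))
      files[[length(files) + 1]] <- list(subject = su$id, session = ss,
                                         kind = "volume", path = f)
    }
    for (ss in c("F1", "F2", "F3")) {
      f <- file.path("traces", sprintf("%s_%s.csv", su$id, ss))
      write_trace(su$traces[[ss]], file.path(out_dir, f))
      files[[length(files) + 1]] <- list(subject = su$id, session = ss,
                                         kind = "trace", path = f)
    }
  }
  regions <- names(cohort$masks$masks)
  label <- array(0L, cohort$config$grid_shape)
  for (k in seq_along(regions)) label[cohort$masks$masks[[regions[k]]]] <- k
  write_volume(label, file.path(out_dir, "masks", "regions.nii"), vox)
  write_volume(cohort$brain_mask * 1, file.path(out_dir, "masks", "brain.nii"), vox)
  labels <- data.frame(subject = names(cohort$subjects),
                       group = cohort_labels(cohort))
  utils::write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  gt <- lapply(cohort$subjects, function(su)
    list(group = su$group,
         planted_increment = as.list(su$ground_truth$planted_increment),
         planted_freezing = as.list(su$ground_truth$planted_freezing)))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    grid_shape = cohort$config$grid_shape, voxel_size_mm = vox,
    seed = cohort$config$seed, frame_rate_hz = cohort$config$frame_rate_hz,
    midline_x = cohort$masks$midline_x,
    region_legend = as.list(setNames(seq_along(regions), regions)),
    bilateral = as.list(cohort$masks$bilateral),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate an on-disk fixture manifest
#'
#' Checks that every file the manifest lists exists and that every subject
#' has exactly one F1 and one F3 volume; errors name the missing
#' subject/session.
#'
#' @param dir fixture directory containing manifest.json
#' @return the manifest, invisibly
#' @export
validate_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("manifest.json not found in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  vols <- list()
  for (f in manifest$files) {
    p <- file.path(dir, f$path)
    if (!file.exists(p))
      stopf("missing %s file for subject %s session %s: %s",
            f$kind, f$subject, f$session, f$path)
    if (f$kind == "volume")
      vols[[f$subject]] <- c(vols[[f$subject]], f$session)
  }
  for (s in names(vols))
    if (!setequal(vols[[s]], c("F1", "F3")) || length(vols[[s]]) != 2)
      stopf("subject %s: expected exactly one F1 and one F3 volume", s)
  invisible(manifest)
}

#' Read a fixture directory back into a cohort-like object
#'
#' @param dir fixture directory written by [write_fixtures()]
#' @return list(subjects, masks, brain_mask, labels, manifest); volumes are
#'   raw (unnormalized) scan volumes at float32 precision
#' @export
read_fixtures <- function(dir) {
  manifest <- validate_manifest(dir)
  grid <- unlist(manifest$grid_shape)
  brain_img <- RNifti::readNifti(file.path(dir, "masks", "brain.nii"))
  brain <- array(as.numeric(brain_img) > 0.5, dim = grid)
  label_img <- RNifti::readNifti(file.path(dir, "masks", "regions.nii"))
  label <- array(as.integer(round(as.numeric(label_img))), dim = grid)
  legend <- manifest$region_legend
  masks <- lapply(legend, function(v) array(label == v, dim = grid))
  bil <- unlist(manifest$bilateral)[names(legend)]
  slices <- lapply(masks, function(m)
    which(apply(m, 3, any)))
  mask_set <- structure(list(masks = masks, bilateral = bil,
                             midline_x = manifest$midline_x,
                             grid_shape = as.integer(grid),
                             slices = slices),
                        class = "region_mask_set")
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  subjects <- list()
  for (f in manifest$files) {
    s <- f$subject
    if (is.null(subjects[[s]]))
      subjects[[s]] <- list(id = s,
                            group = labels$group[labels$subject == s],
                            scans = list(), traces = list())
    if (f$kind == "volume") {
      subjects[[s]]$scans[[f$session]] <- read_volume(file.path(dir, f$path),
                                                      subject_id = s,
                                                      session = f$session)
    } else {
      subjects[[s]]$traces[[f$session]] <- read_trace(
        file.path(dir, f$path), frame_rate_hz = manifest$frame_rate_hz)
    }
  }
  list(subjects = subjects, masks = mask_set, brain_mask = brain,
       labels = setNames(as.character(labels$group), labels$subject),
       manifest = manifest)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order -- behavior scoring, normalization + SUV
#' extraction + delta-SUV, mixed-model group tests and behavior
#' correlations, leave-one-out classification, and ordinal-trends analysis
#' on the control group -- writing each stage's tables under
#' \code{out_dir} before the next stage begins. A stage failure is recorded
#' in the report and dependent stages are skipped.
#'
#' @param cohort a \code{synthetic_cohort}
#' @param out_dir output directory (NULL to skip writing)
#' @param model_kinds classifier kinds to run
#' @param n_perm,n_boot ORT resampling sizes
#' @param seed integer seed for the stochastic stages
#' @return object of class \code{run_report}: list(stages, results, seeds,
#'   warnings, manifest)
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         model_kinds = c("logistic", "svm", "gentleboost"),
                         n_perm = 500, n_boot = 500, seed = 1L) {
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  warns <- character(0)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  run_stage <- function(name, deps, fun) {
    for (d in deps) if (!isTRUE(stages[[d]] == "ok")) {
      stages[[name]] <<- sprintf("skipped (dependency %s failed)", d)
      return(invisible(NULL))
    }
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stages[[name]] <<- paste("failed:", conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (is.null(stages[[name]])) stages[[name]] <<- "ok"
    if (!is.null(res)) results[[name]] <<- res
    invisible(NULL)
  }
  labels <- cohort_labels(cohort)

  run_stage("behavior", character(0), function() {
    rows <- list(); bouts <- list()
    for (su in cohort$subjects) for (ss in c("F2", "F3")) {
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
    emit(freezing, "freezing"); emit(bout_tab, "bouts")
    f3 <- freezing[freezing$session == "F3", ]
    tt <- t_test_groups(f3$pct_freezing[f3$group == "CON"],
                        f3$pct_freezing[f3$group == "LS"])
    ks <- ks_two_sample(bout_tab$duration_s[bout_tab$group == "CON"],
                        bout_tab$duration_s[bout_tab$group == "LS"])
    list(freezing = freezing, bouts = bout_tab, f3_t_test = tt, bout_ks = ks)
  })

  run_stage("delta_suv", character(0), function() {
    delta <- cohort_delta_table(cohort)
    emit(delta, "delta_suv")
    means <- subject_region_mean(delta)
    emit(means, "subject_region_means")
    list(delta = delta, subject_means = means)
  })

  run_stage("group_stats", c("delta_suv", "behavior"), function() {
    delta <- results$delta_suv$delta
    means <- results$delta_suv$subject_means
    f3 <- results$behavior$freezing
    f3 <- f3[f3$session == "F3", ]
    regions <- unique(delta$region)
    lmm <- lapply(setNames(regions, regions), function(rg)
      lmm_group_test(delta[delta$region == rg, ], labels))
    lmm_tab <- do.call(rbind, lapply(regions, function(rg) {
      r <- lmm[[rg]]
      data.frame(region = rg, estimate = r$group_effect_estimate, se = r$se,
                 F_stat = r$F_stat, p_value = r$p_value,
                 mean_CON = r$group_means[["CON"]], mean_LS = r$group_means[["LS"]])
    }))
    emit(lmm_tab, "lmm_group_tests")
    cors <- list()
    for (grp in c("CON", "LS")) for (rg in regions) {
      subj <- f3$subject[f3$group == grp]
      x <- means$mean_delta[means$region == rg][match(subj, means$subject[means$region == rg])]
      y <- f3$pct_freezing[f3$group == grp]
      cr <- region_behavior_correlation(x, y)
      cors[[length(cors) + 1]] <- data.frame(group = grp, region = rg,
                                             r = cr$pearson_r, slope = cr$slope,
                                             intercept = cr$intercept, n = cr$n)
    }
    cor_tab <- do.call(rbind, cors)
    emit(cor_tab, "behavior_correlations")
    grp_means <- lapply(setNames(c("CON", "LS"), c("CON", "LS")), function(g) {
      sm <- means[means$subject %in% names(labels)[labels == g], ]
      tapply(sm$mean_delta, sm$region, mean)
    })
    nm <- network_map(grp_means, "mean_delta", regions = sort(regions))
    if (!is.null(out_dir)) write_network_map(nm, file.path(out_dir, "network_map.json"))
    list(lmm = lmm, lmm_table = lmm_tab, correlations = cor_tab, network = nm)
  })

  run_stage("classify", "delta_suv", function() {
    fm <- feature_matrix(results$delta_suv$subject_means, labels)
    out <- lapply(setNames(model_kinds, model_kinds), function(mk) {
      real <- loocv(fm, mk, seed = derive_seed(seed, "loocv", mk))
      scr <- scrambled_control(fm, mk, seed = derive_seed(seed, "loocv", mk))
      list(real = real, scrambled = scr)
    })
    tab <- do.call(rbind, lapply(names(out), function(mk)
      data.frame(model = mk, TNR = out[[mk]]$real$confusion$TNR,
                 TPR = out[[mk]]$real$confusion$TPR, AUC = out[[mk]]$real$auc,
                 AUC_scrambled = out[[mk]]$scrambled$auc)))
    emit(tab, "classification")
    c(out, list(table = tab))
  })

  run_stage("ort", character(0), function() {
    norm_scans <- function(grp) {
      subs <- Filter(function(su) su$group == grp, cohort$subjects)
      lapply(subs, function(su)
        list(F1 = normalize_scan(su$scans$F1, cohort$brain_mask),
             F3 = normalize_scan(su$scans$F3, cohort$brain_mask)))
    }
    con <- norm_scans("CON")
    res <- ort_analysis(con, cohort$brain_mask, n_perm = n_perm,
                        n_boot = n_boot, seed = derive_seed(seed, "ort"))
    all_scans <- c(con, norm_scans("LS"))
    om_all <- build_ort_matrix(all_scans, cohort$brain_mask)
    ec <- expression_change(res$pattern, om_all, groups = labels)
    if (!is.null(out_dir)) {
      utils::write.csv(ec$expressions, file.path(out_dir, "ort_expressions.csv"),
                       row.names = FALSE)
      zvol <- array(0, cohort$config$grid_shape)
      zvol[cohort$brain_mask] <- res$boot_z
      write_volume(zvol, file.path(out_dir, "ort_boot_z.nii"),
                   cohort$config$voxel_size_mm)
      svol <- array(0, cohort$config$grid_shape)
      svol[cohort$brain_mask] <- as.numeric(res$sig_mask)
      write_volume(svol, file.path(out_dir, "ort_sig_mask.nii"),
                   cohort$config$voxel_size_mm)
    }
    list(con = res, all_groups = ec)
  })

  manifest <- NULL
  if (!is.null(out_dir)) {
    out_files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
    manifest <- data.frame(path = out_files,
                           md5 = unname(tools::md5sum(file.path(out_dir, out_files))))
  }
  structure(list(stages = stages, results = results, seed = seed,
                 warnings = warns, manifest = manifest,
                 version = as.character(utils::packageVersion("betapet"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages)) cat(sprintf("  %-12s %s\n", s, x$stages[[s]]))
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
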