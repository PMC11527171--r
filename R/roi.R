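#' Construct a scan volume
#'
#' A registered 3D uptake volume with subject/session metadata. Voxel
#' indices are 1-based; the third array index is the coronal slice.
#'
#' @param voxels 3D numeric array of uptake values
#' @param subject_id subject identifier
#' @param session "F1" (baseline) or "F3" (recall)
#' @param voxel_size_mm numeric 3-vector
#' @param normalized has the volume been normalized to its whole-brain mean?
#' @return object of class \code{scan_volume}
#' @export
scan_volume <- function(voxels, subject_id, session,
                        voxel_size_mm = c(1, 1, 1), normalized = FALSE) {
  if (length(dim(voxels)) != 3) stopf("voxels: need a 3D array")
  if (!all(is.finite(voxels))) stopf("voxels: non-finite values")
  if (!session %in% c("F1", "F3")) stopf("session: must be F1 or F3")
  structure(list(subject_id = subject_id, session = session,
                 voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
                 normalized = isTRUE(normalized)),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  cat(sprintf("<scan_volume> subject %s, session %s, %s grid, %s\n",
              x$subject_id, x$session, paste(dim(x$voxels), collapse = "x"),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Build a region mask set from footprint specs
#'
#' Converts per-slice box footprints into 3D logical masks, recording the
#' hemisphere-splitting midline and which regions are bilateral. The
#' midline defaults to half the x extent plus 0.5 (so a voxel with 1-based
#' x index \code{<=} grid/2 is left). Voxels with x >= midline are assigned
#' to the right hemisphere (midline ties go right).
#'
#' @param specs list of region specs (see [default_region_specs()])
#' @param grid_shape integer 3-vector
#' @param midline_x hemisphere split coordinate (1-based, may be fractional)
#' @return object of class \code{region_mask_set} with fields \code{masks}
#'   (region -> 3D logical), \code{bilateral}, \code{midline_x},
#'   \code{grid_shape}, \code{slices} (region -> slice indices)
#' @export
region_mask_set <- function(specs, grid_shape,
                            midline_x = grid_shape[1] / 2 + 0.5) {
  masks <- list(); bilateral <- logical(0); slices <- list()
  for (sp in specs) {
    m <- array(FALSE, grid_shape)
    xr <- if (isTRUE(sp$bilateral)) {
      list(seq(sp$x_left[1], sp$x_left[2]), seq(sp$x_right[1], sp$x_right[2]))
    } else list(seq(sp$x[1], sp$x[2]))
    for (xs in xr) m[xs, seq(sp$y[1], sp$y[2]), sp$slices] <- TRUE
    if (isTRUE(sp$bilateral)) {
      for (z in sp$slices) {
        sl <- m[, , z]
        has_l <- any(sl[seq_len(grid_shape[1]) < midline_x, ])
        has_r <- any(sl[seq_len(grid_shape[1]) >= midline_x, ])
        if (!has_l || !has_r)
          stopf("region %s: bilateral but slice %d lacks voxels on both sides of midline",
                sp$region, z)
      }
    }
    masks[[sp$region]] <- m
    bilateral[sp$region] <- isTRUE(sp$bilateral)
    slices[[sp$region]] <- as.integer(sp$slices)
  }
  structure(list(masks = masks, bilateral = bilateral, midline_x = midline_x,
                 grid_shape = as.integer(grid_shape), slices = slices),
            class = "region_mask_set")
}

#' Brain mask for a grid
#'
#' Centered box leaving a margin fraction of each axis outside the brain;
#' stands in for the skull-stripped brain support of registered scans.
#'
#' @param grid_shape integer 3-vector
#' @param margin_frac fraction of each axis excluded on each side
#' @return 3D logical array
#' @export
brain_mask_box <- function(grid_shape, margin_frac = 0.1) {
  m <- array(FALSE, grid_shape)
  lo <- pmax(1, floor(grid_shape * margin_frac) + 1)
  hi <- pmin(grid_shape, grid_shape - floor(grid_shape * margin_frac))
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Normalize a scan to its whole-brain mean
#'
#' Divides every voxel by the mean over in-mask voxels, the standard
#' per-mouse normalization for this pipeline; afterwards the in-mask mean is
#' 1 and out-of-mask voxels are zeroed. All downstream SUVs are therefore
#' dimensionless and invariant to global scale.
#'
#' @param volume a \code{scan_volume} (not already normalized)
#' @param brain_mask 3D logical array, same grid
#' @return normalized \code{scan_volume}
#' @export
normalize_scan <- function(volume, brain_mask) {
  if (volume$normalized) stopf("volume already normalized")
  if (!identical(dim(volume$voxels), dim(brain_mask)))
    stopf("brain_mask grid does not match volume")
  if (!any(brain_mask)) stopf("brain_mask is empty")
  m <- mean(volume$voxels[brain_mask])
  if (!is.finite(m) || m <= 0) stopf("in-mask mean is not positive; cannot normalize")
  v <- volume$voxels / m
  v[!brain_mask] <- 0
  out <- volume
  out$voxels <- v
  out$normalized <- TRUE
  out
}

#' Regional SUV table for one normalized scan
#'
#' For every region, slice, and hemisphere, the mean normalized uptake over
#' mask voxels. Bilateral regions are split at the mask set's midline
#' (x < midline is left, x >= midline is right); midline objects (PLC, ILC)
#' yield one BOTH record per slice. Slices whose mask intersection is empty
#' are dropped with a warning rather than zero-filled.
#'
#' @param volume normalized \code{scan_volume}
#' @param masks a \code{region_mask_set}
#' @return data.frame with columns subject, session, region, slice_index,
#'   hemisphere, suv, n_voxels
#' @export
region_suv_table <- function(volume, masks) {
  if (!volume$normalized) stopf("volume must be normalized first")
  if (!identical(dim(volume$voxels), as.integer(masks$grid_shape)))
    stopf("mask grid does not match volume")
  nx <- masks$grid_shape[1]
  left_cols <- seq_len(nx) < masks$midline_x
  recs <- list()
  for (rg in names(masks$masks)) {
    m3 <- masks$masks[[rg]]
    for (z in masks$slices[[rg]]) {
      sl_mask <- m3[, , z]
      sl_vox <- volume$voxels[, , z]
      if (masks$bilateral[[rg]]) {
        for (h in c("L", "R")) {
          sel <- sl_mask & (if (h == "L") left_cols else !left_cols)
          n <- sum(sel)
          if (n == 0) { warnf("empty mask: %s slice %d hemisphere %s dropped", rg, z, h); next }
          recs[[length(recs) + 1]] <- data.frame(
            subject = volume$subject_id, session = volume$session, region = rg,
            slice_index = z, hemisphere = h, suv = mean(sl_vox[sel]),
            n_voxels = n, stringsAsFactors = FALSE)
        }
      } else {
        n <- sum(sl_mask)
        if (n == 0) { warnf("empty mask: %s slice %d dropped", rg, z); next }
        recs[[length(recs) + 1]] <- data.frame(
          subject = volume$subject_id, session = volume$session, region = rg,
          slice_index = z, hemisphere = "BOTH", suv = mean(sl_vox[sl_mask]),
          n_voxels = n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) stopf("no mask voxels found in any region")
  do.call(rbind, recs)
}

#' Differential SUV table (recall minus baseline)
#'
#' Matches F1 and F3 SUV records of the same subject on (region, slice,
#' hemisphere) and returns their difference, the per-record delta-SUV.
#'
#' @param f1,f3 SUV tables from [region_suv_table()] for the same subject
#' @return data.frame with columns subject, region, slice_index, hemisphere,
#'   delta_suv, n_voxels
#' @export
delta_suv <- function(f1, f3) {
  if (!identical(unique(f1$subject), unique(f3$subject)) ||
      length(unique(f1$subject)) != 1)
    stopf("delta_suv: tables must be from one common subject")
  key <- function(d) paste(d$region, d$slice_index, d$hemisphere, sep = "|")
  k1 <- key(f1); k3 <- key(f3)
  orphans <- c(setdiff(k1, k3), setdiff(k3, k1))
  if (length(orphans))
    stopf("delta_suv: unmatched (region|slice|hemisphere) keys: %s",
          paste(unique(orphans), collapse = ", "))
  f1 <- f1[order(k1), ]; f3 <- f3[order(k3), ]
  data.frame(subject = f1$subject, region = f1$region,
             slice_index = f1$slice_index, hemisphere = f1$hemisphere,
             delta_suv = f3$suv - f1$suv, n_voxels = f1$n_voxels,
             stringsAsFactors = FALSE)
}

#' Per-subject regional mean delta-SUV
#'
#' Unweighted mean over all (slice, hemisphere) records of each region,
#' giving one value per subject per region -- the per-mouse summary used for
#' correlation with behavior and as classifier features.
#'
#' @param delta a delta-SUV table (possibly row-bound over subjects)
#' @return data.frame with columns subject, region, mean_delta, n_records
#' @export
subject_region_mean <- function(delta) {
  if (!nrow(delta)) stopf("empty delta table")
  agg <- aggregate(delta$delta_suv,
                   by = list(subject = delta$subject, region = delta$region),
                   FUN = mean)
  cnt <- aggregate(delta$delta_suv,
                   by = list(subject = delta$subject, region = delta$region),
                   FUN = length)
  out <- data.frame(subject = agg$subject, region = agg$region,
                    mean_delta = agg$x, n_records = cnt$x,
                    stringsAsFactors = FALSE)
  out[order(out$subject, out$region), ]
}

#' Region-level network map
#'
#' One scalar per region per group (group-mean delta-SUV or a Pearson r),
#' JSON-serializable, with the aggregation kind stamped.
#'
#' @param values named list group -> named numeric vector over all 8 regions
#' @param kind "mean_delta" or "pearson_r"
#' @param regions required region codes
#' @return object of class \code{network_map}
#' @export
network_map <- function(values, kind = c("mean_delta", "pearson_r"),
                        regions = c("BA", "PLC", "ILC", "DH", "VH", "SB", "LEC", "MEC")) {
  kind <- match.arg(kind)
  for (grp in names(values)) {
    missing <- setdiff(regions, names(values[[grp]]))
    if (length(missing))
      stopf("network_map: group %s missing region(s) %s", grp,
            paste(missing, collapse = ", "))
    values[[grp]] <- values[[grp]][regions]
  }
  structure(list(kind = kind, regions = regions, values = values),
            class = "network_map")
}

#' Write / read a network map as JSON
#' @param map a \code{network_map}
#' @param path output file
#' @return path (write) or \code{network_map} (read)
#' @export
write_network_map <- function(map, path) {
  jsonlite::write_json(list(kind = map$kind, regions = map$regions,
                            values = lapply(map$values, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_map
#' @export
read_network_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- lapply(j$values, function(v) unlist(v))
  network_map(vals, kind = j$kind, regions = j$regions)
}
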