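#' Configuration for the dual-station abdominal phantom
#'
#' Defines the acquisition geometry and appearance of a synthetic subject:
#' a whole-trunk volume split into two overlapping axial imaging stations,
#' with two bright parenchymal kidney bodies in the water channel, a dark
#' medial hilum (renal pelvis/calyces/vessels), a generic background tissue
#' blob with a subcutaneous fat rim in the fat channel, additive Gaussian
#' noise, and a rigid breath-hold misalignment applied to the content of the
#' second station.
#'
#' The default geometry follows the dual-echo neck-to-knee protocol in which
#' the kidneys are covered by two stations of 224 x 174 x 44 voxels at
#' (2.232, 2.232, 4.5) mm; the trunk grid of 64 slices with a 24-slice
#' overlap satisfies `2 * station_slices - overlap_slices = z extent`.
#'
#' @param grid_shape voxels per axis of the whole-trunk volume (AP, LR, SI).
#' @param voxel_spacing_mm voxel spacing in mm.
#' @param station_slices axial slices per station.
#' @param overlap_slices slices shared by the two stations.
#' @param kidney_size_range list of length-2 ranges (mm) for the kidney
#'   semi-axes along AP (`ap`), LR (`lr`) and SI (`si`).
#' @param hilum_fraction size of the excluded medial concavity relative to
#'   the kidney semi-axes.
#' @param intensity_params named list of mean intensities (arbitrary units,
#'   order of magnitude 1) for the tissue classes in the water and fat
#'   channels.
#' @param noise_sd additive Gaussian noise SD (intensities clipped at 0).
#' @param motion_offset_mm rigid (AP, LR, SI) shift in mm applied to the
#'   source content of station 2 before extraction, emulating breath-hold
#'   misalignment.
#' @param anomaly one of `"none"`, `"missing_left"`, `"missing_right"`,
#'   `"cysts"`, `"fused"`, `"border_truncation"`.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(224, 174, 64),
                           voxel_spacing_mm = c(2.232, 2.232, 4.5),
                           station_slices = 44,
                           overlap_slices = 24,
                           kidney_size_range = list(ap = c(22, 30),
                                                    lr = c(16, 24),
                                                    si = c(42, 58)),
                           hilum_fraction = 0.45,
                           intensity_params = list(parenchyma = 0.85,
                                                   background = 0.35,
                                                   dark = 0.06,
                                                   air = 0.02,
                                                   fat_rim = 0.8,
                                                   fat_background = 0.25,
                                                   fat_parenchyma = 0.08),
                           noise_sd = 0.02,
                           motion_offset_mm = c(1.5, 0, 2),
                           anomaly = c("none", "missing_left", "missing_right",
                                       "cysts", "fused", "border_truncation"),
                           seed = 1L) {
  anomaly <- match.arg(anomaly)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              station_slices = as.integer(station_slices),
              overlap_slices = as.integer(overlap_slices),
              kidney_size_range = kidney_size_range,
              hilum_fraction = hilum_fraction,
              intensity_params = intensity_params,
              noise_sd = noise_sd,
              motion_offset_mm = as.numeric(motion_offset_mm),
              anomaly = anomaly,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    stop("grid_shape must be three integers >= 4")
  if (any(cfg$voxel_spacing_mm <= 0))
    stop("voxel spacing entries must be positive")
  if (cfg$station_slices > cfg$grid_shape[3])
    stop("station_slices exceeds the z extent of the grid")
  if (cfg$overlap_slices <= 0L || cfg$overlap_slices >= cfg$station_slices)
    stop("overlap_slices must satisfy 0 < overlap < station_slices")
  if (2L * cfg$station_slices - cfg$overlap_slices != cfg$grid_shape[3])
    stop("station geometry inconsistent: 2 * station_slices - overlap_slices ",
         "(= ", 2L * cfg$station_slices - cfg$overlap_slices,
         ") must equal the grid z extent (", cfg$grid_shape[3], ")")
  invisible(cfg)
}

# Shift array content by a (possibly fractional) voxel offset along each
# axis, sampling outside the grid by border clamping. Linear interpolation
# for intensities, nearest-neighbour for labels.
shift_volume_array <- function(arr, offset_vox,
                               method = c("linear", "nearest")) {
  method <- match.arg(method)
  take <- function(a, ax, idx) {
    switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  out <- arr
  for (ax in 1:3) {
    off <- offset_vox[ax]
    if (off == 0) next
    n <- dim(out)[ax]
    src <- seq_len(n) - off
    if (method == "nearest") {
      idx <- pmin(pmax(floor(src + 0.5), 1), n)
      out <- take(out, ax, idx)
    } else {
      i0 <- floor(src)
      f <- src - i0
      i0c <- pmin(pmax(i0, 1), n)
      i1c <- pmin(pmax(i0 + 1, 1), n)
      out <- sweep(take(out, ax, i0c), ax, 1 - f, "*") +
        sweep(take(out, ax, i1c), ax, f, "*")
    }
  }
  out
}

# Solid superellipsoid |x/a|^p + |y/b|^p + |z/c|^p <= 1 on the voxel grid.
superellipsoid_mask <- function(coords, centre, semi, p = 2.5) {
  nr <- length(coords$r); nc <- length(coords$c); nz <- length(coords$z)
  out <- array(FALSE, c(nr, nc, nz))
  in_plane <- outer(abs((coords$r - centre[1]) / semi[1])^p,
                    abs((coords$c - centre[2]) / semi[2])^p, "+")
  zterm <- abs((coords$z - centre[3]) / semi[3])^p
  for (k in seq_len(nz)) {
    if (zterm[k] >= 1) next
    out[, , k] <- in_plane <= 1 - zterm[k]
  }
  out
}

ellipsoid_mask <- function(coords, centre, semi) {
  superellipsoid_mask(coords, centre, semi, p = 2)
}

#' Generate one synthetic dual-station subject
#'
#' Builds the whole-trunk water and fat volumes with voxel-level ground
#' truth, then extracts the two overlapping stations. Station 2 content is
#' rigidly shifted by `motion_offset_mm` before extraction, so the shared
#' slices of the two stations disagree in proportion to the injected motion;
#' with zero offset (and since noise is drawn once on the trunk volume) the
#' overlap agrees voxel for voxel. Ground truth marks parenchymal kidney
#' tissue only: the dark hilum and any cysts are excluded, exactly as the
#' bright/dark rendering of the water channel.
#'
#' @param config a [phantom_config()].
#' @return An object of class `subject_phantom` with fields `station_a`,
#'   `station_b` (each water + fat [volume_image]), per-station truth masks
#'   `truth_a`, `truth_b`, the whole-trunk `truth_fused`,
#'   `true_left_volume_cm3` / `true_right_volume_cm3` (0 for a missing
#'   kidney, `NA` where left/right is undefined for fused kidneys), and
#'   generation `metadata`.
#' @export
generate_subject <- function(config) {
  validate_phantom_config(config)
  set.seed(config$seed)
  d <- config$grid_shape
  sp <- config$voxel_spacing_mm
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  coords <- list(r = (seq_len(nr) - 1) * sp[1],
                 c = (seq_len(nc) - 1) * sp[2],
                 z = (seq_len(nz) - 1) * sp[3])
  extent <- (d - 1) * sp

  ksr <- config$kidney_size_range
  semi_l <- c(stats::runif(1, ksr$ap[1], ksr$ap[2]),
              stats::runif(1, ksr$lr[1], ksr$lr[2]),
              stats::runif(1, ksr$si[1], ksr$si[2]))
  semi_r <- c(stats::runif(1, ksr$ap[1], ksr$ap[2]),
              stats::runif(1, ksr$lr[1], ksr$lr[2]),
              stats::runif(1, ksr$si[1], ksr$si[2]))
  centre_row <- 0.60 * extent[1] + stats::runif(2, -5, 5)
  lat <- 0.15 * extent[2] + stats::runif(2, -8, 8)
  centre_z <- 0.5 * extent[3] + stats::runif(2, -8, 8)
  if (config$anomaly == "border_truncation")
    centre_z <- rep(extent[3] - 0.35 * semi_l[3], 2)
  # subject's left = increasing column index
  centre_l <- c(centre_row[1], extent[2] / 2 + lat[1], centre_z[1])
  centre_r <- c(centre_row[2], extent[2] / 2 - lat[2], centre_z[2])

  solid_l <- superellipsoid_mask(coords, centre_l, semi_l)
  solid_r <- superellipsoid_mask(coords, centre_r, semi_r)
  if (config$anomaly == "missing_left") solid_l[] <- FALSE
  if (config$anomaly == "missing_right") solid_r[] <- FALSE

  # medial hilum concavity, rendered dark and excluded from truth
  hf <- config$hilum_fraction
  hilum_l <- ellipsoid_mask(coords,
                            centre_l - c(0, 0.8 * semi_l[2], 0),
                            hf * semi_l)
  hilum_r <- ellipsoid_mask(coords,
                            centre_r + c(0, 0.8 * semi_r[2], 0),
                            hf * semi_r)
  dark <- (solid_l & hilum_l) | (solid_r & hilum_r)
  truth_l <- solid_l & !hilum_l
  truth_r <- solid_r & !hilum_r

  if (config$anomaly == "cysts") {
    for (side in list(list(m = centre_l, s = semi_l),
                      list(m = centre_r, s = semi_r))) {
      for (i in 1:2) {
        cc <- side$m + stats::runif(3, -0.35, 0.35) * side$s
        cyst <- ellipsoid_mask(coords, cc, rep(stats::runif(1, 6, 10), 3))
        dark <- dark | (cyst & (truth_l | truth_r))
        truth_l <- truth_l & !cyst
        truth_r <- truth_r & !cyst
      }
    }
  }
  # subtracting the hilum (and cysts) can strand small satellites; keep the
  # largest connected body per kidney and render the rest dark so truth has
  # exactly one component per present kidney
  largest_body <- function(mask) {
    if (!any(mask)) return(mask)
    cc <- connected_components(array(as.integer(mask), dim(mask)))
    cc$labels == 1L
  }
  for (side in c("l", "r")) {
    nm <- paste0("truth_", side)
    cleaned <- largest_body(get(nm))
    dark <- dark | (get(nm) & !cleaned)
    assign(nm, cleaned)
  }

  if (config$anomaly == "fused") {
    # bright isthmus joining the two bodies across the midline
    mid <- (centre_l + centre_r) / 2
    isth2d <- outer(abs(coords$r - mid[1]) <= 10,
                    coords$c >= centre_r[2] & coords$c <= centre_l[2])
    isthmus <- array(isth2d, d) &
      rep(abs(coords$z - mid[3]) <= 12, each = nr * nc)
    truth_l <- truth_l | isthmus
    dark <- dark & !isthmus
  }
  truth <- truth_l | truth_r

  ip <- config$intensity_params
  body_a <- c(0.46 * extent[1], 0.48 * extent[2])
  body <- outer(((coords$r - extent[1] / 2) / body_a[1])^2,
                ((coords$c - extent[2] / 2) / body_a[2])^2, "+")
  fat_rim2d <- body <= 1 & body >= 0.78
  body2d <- body <= 1
  body3d <- array(body2d, d)
  rim3d <- array(fat_rim2d, d)

  water <- array(ip$air, d)
  water[body3d] <- ip$background
  water[truth] <- ip$parenchyma
  water[dark] <- ip$dark
  fat <- array(ip$air, d)
  fat[body3d] <- ip$fat_background
  fat[rim3d] <- ip$fat_rim
  fat[truth | dark] <- ip$fat_parenchyma

  if (config$noise_sd > 0) {
    water <- pmax(water + stats::rnorm(length(water), 0, config$noise_sd), 0)
    fat <- pmax(fat + stats::rnorm(length(fat), 0, config$noise_sd), 0)
  }
  truth_int <- array(as.integer(truth), d)

  s <- config$station_slices
  off_vox <- config$motion_offset_mm / sp
  water_b_src <- shift_volume_array(water, off_vox, "linear")
  fat_b_src <- shift_volume_array(fat, off_vox, "linear")
  truth_b_src <- shift_volume_array(truth_int, off_vox, "nearest")
  za <- seq_len(s)
  zb <- seq(nz - s + 1, nz)
  origin_b <- c(0, 0, (nz - s) * sp[3])

  station <- function(arr, idx, origin_z, channel) {
    volume_image(arr[, , idx, drop = FALSE], spacing = sp,
                 origin = c(0, 0, origin_z), channel = channel)
  }
  subject <- list(
    station_a = list(water = station(water, za, 0, "water"),
                     fat = station(fat, za, 0, "fat")),
    station_b = list(water = station(water_b_src, zb, origin_b[3], "water"),
                     fat = station(fat_b_src, zb, origin_b[3], "fat")),
    truth_a = station(truth_int, za, 0, "label"),
    truth_b = station(truth_b_src, zb, origin_b[3], "label"),
    truth_fused = volume_image(truth_int, spacing = sp, origin = c(0, 0, 0),
                               channel = "label"),
    true_left_volume_cm3 = if (config$anomaly == "fused") NA_real_ else
      true_volume(truth_l, sp),
    true_right_volume_cm3 = if (config$anomaly == "fused") NA_real_ else
      true_volume(truth_r, sp),
    metadata = list(anomaly = config$anomaly,
                    motion_offset_mm = config$motion_offset_mm,
                    seed = config$seed,
                    config = config)
  )
  class(subject) <- "subject_phantom"
  subject
}

#' @export
print.subject_phantom <- function(x, ...) {
  cat(sprintf(paste0("<subject_phantom> anomaly=%s, seed=%d\n",
                     "  true volumes left %.1f / right %.1f cm^3, ",
                     "motion (%g, %g, %g) mm\n"),
              x$metadata$anomaly, x$metadata$seed,
              x$true_left_volume_cm3, x$true_right_volume_cm3,
              x$metadata$motion_offset_mm[1], x$metadata$motion_offset_mm[2],
              x$metadata$motion_offset_mm[3]))
  invisible(x)
}

#' Parenchymal volume of a binary mask
#'
#' Voxel count scaled by the physical voxel volume, in cm^3 — the volumetry
#' rule used throughout the pipeline.
#'
#' @param truth binary 3-D array or label [volume_image].
#' @param spacing voxel spacing in mm (ignored when `truth` carries its own).
#' @return volume in cm^3 (0 for an empty mask).
#' @export
true_volume <- function(truth, spacing = NULL) {
  if (inherits(truth, "volume_image")) {
    spacing <- truth$spacing
    truth <- truth$data
  }
  if (is.null(spacing)) stop("spacing required for a bare array mask")
  sum(truth != 0) * voxel_volume_mm3(spacing) / 1000
}

#' Generate a seeded phantom cohort
#'
#' Derives one reproducible seed per subject from the cohort seed and assigns
#' anomalies deterministically: for each named rate, `round(n * rate)`
#' subjects receive that condition, positions chosen by a seeded permutation.
#' The pseudo-anomaly `"large_motion"` leaves the anatomy intact but sets a
#' 9 mm inter-station shift, the failure mode the fusion quality ratings must
#' detect.
#'
#' @param n number of subjects.
#' @param config base [phantom_config()]; per-subject seeds override its seed.
#' @param anomaly_rates named numeric vector over
#'   `missing_left, missing_right, cysts, fused, border_truncation,
#'   large_motion`; rates must sum to at most 1.
#' @param seed cohort-level RNG seed.
#' @param dir optional directory: when given, stations, truth masks and the
#'   manifest CSV are written there as NIfTI/CSV.
#' @param keep_subjects return the in-memory subject list (default `TRUE`;
#'   set to `FALSE` with `dir` for large cohorts).
#' @return list with `subjects` (or `NULL`) and the `manifest` data.frame.
#' @export
generate_cohort <- function(n, config = phantom_config(),
                            anomaly_rates = numeric(), seed = 1L,
                            dir = NULL, keep_subjects = TRUE) {
  stopifnot(n >= 1)
  if (length(anomaly_rates) && sum(anomaly_rates) > 1)
    stop("anomaly rates must sum to at most 1")
  allowed <- c("missing_left", "missing_right", "cysts", "fused",
               "border_truncation", "large_motion")
  if (length(anomaly_rates) && !all(names(anomaly_rates) %in% allowed))
    stop("unknown anomaly rate name(s): ",
         paste(setdiff(names(anomaly_rates), allowed), collapse = ", "))
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  assignment <- rep("none", n)
  slots <- sample.int(n)
  pos <- 1L
  for (nm in names(anomaly_rates)) {
    k <- round(n * anomaly_rates[[nm]])
    if (k > 0) {
      assignment[slots[pos:(pos + k - 1L)]] <- nm
      pos <- pos + k
    }
  }
  subjects <- if (keep_subjects) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- subject_seeds[i]
    if (assignment[i] == "large_motion") {
      cfg_i$motion_offset_mm <- c(9, 0, 9)
    } else if (assignment[i] != "none") {
      cfg_i$anomaly <- assignment[i]
    }
    subj <- generate_subject(cfg_i)
    id <- sprintf("S%04d", i)
    row <- data.frame(subject_id = id, anomaly = assignment[i],
                      seed = subject_seeds[i],
                      motion_mm = sqrt(sum(cfg_i$motion_offset_mm^2)),
                      true_left_volume_cm3 = subj$true_left_volume_cm3,
                      true_right_volume_cm3 = subj$true_right_volume_cm3,
                      stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      paths <- write_phantom_subject(subj, dir, id)
      row <- cbind(row, as.data.frame(paths, stringsAsFactors = FALSE))
    }
    rows[[i]] <- row
    if (keep_subjects) subjects[[i]] <- subj
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(subjects = subjects, manifest = manifest)
}

write_phantom_subject <- function(subject, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(tag) file.path(dir, paste0(id, "_", tag, ".nii.gz"))
  write_volume(subject$station_a$water, p("station_a"))
  write_volume(subject$station_b$water, p("station_b"))
  write_volume(subject$station_a$fat, p("station_a_fat"))
  write_volume(subject$station_b$fat, p("station_b_fat"))
  write_volume(subject$truth_a, p("truth_a"))
  write_volume(subject$truth_b, p("truth_b"))
  write_volume(subject$truth_fused, p("truth_fused"))
  list(station_a = p("station_a"), station_b = p("station_b"),
       truth_a = p("truth_a"), truth_b = p("truth_b"),
       truth_fused = p("truth_fused"))
}
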