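#' Fuse two overlapping stations onto a common voxel grid
#'
#' The two stations share the in-plane grid and spacing and overlap along
#' the longitudinal axis; their origins place them on a common grid (the
#' longitudinal origin difference must be an integer number of slices).
#' Outside the overlap each station is copied verbatim. Inside the overlap,
#' intensities are blended with a linear ramp: the weight of station B rises
#' from `0.5/m` to `1 - 0.5/m` across the `m` shared slices, so each station
#' dominates near its own interior and the weights sum to one everywhere.
#' Label *probabilities* are blended with the same weights and thresholded
#' at 0.5 (`>=` maps ties to kidney), producing a binary fused mask.
#'
#' @param a,b water-channel [volume_image] stations (A inferior... A first
#'   along the axis, B second).
#' @param labels_a,labels_b label or probability volumes aligned with the
#'   stations (binary masks are handled as probabilities 0/1).
#' @return list of class `fused_subject`: `fused_water`, `fused_labels`
#'   (binary), `fused_probability`, `overlap_range` (slice interval on the
#'   fused grid, `NULL` when the stations merely abut).
#' @export
fuse_stations <- function(a, b, labels_a = NULL, labels_b = NULL) {
  stopifnot(inherits(a, "volume_image"), inherits(b, "volume_image"))
  da <- dim(a$data); db <- dim(b$data)
  if (any(da[1:2] != db[1:2]))
    stop("stations must share the in-plane grid: ",
         paste(da[1:2], collapse = "x"), " vs ", paste(db[1:2], collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("stations must share voxel spacing")
  dz <- a$spacing[3]
  shift <- (b$origin[3] - a$origin[3]) / dz
  k <- as.integer(round(shift))
  if (abs(shift - k) > 0.01)
    stop("station origins are not aligned to the voxel grid ",
         "(longitudinal offset of ", signif(shift, 4), " slices)")
  if (k < 0) stop("station B must not start before station A")
  nz <- max(k + db[3], da[3])
  m <- da[3] - k  # overlap slices
  if (m < 0) {
    warning("stations do not overlap; concatenating with a gap of ",
            -m, " slice(s)")
    m <- 0L
  }

  blend <- function(xa, xb) {
    out <- array(0, c(da[1], da[2], nz))
    out[, , seq_len(da[3])] <- xa
    out[, , k + seq_len(db[3])] <- xb
    if (m > 0) {
      wb <- (seq_len(m) - 0.5) / m
      for (j in seq_len(m)) {
        za <- k + j
        out[, , za] <- (1 - wb[j]) * xa[, , za] + wb[j] * xb[, , j]
      }
    }
    out
  }
  fused_water <- volume_image(blend(a$data, b$data), a$spacing, a$origin,
                              "water")
  out <- list(fused_water = fused_water,
              fused_labels = NULL, fused_probability = NULL,
              overlap_range = if (m > 0) c(k + 1L, da[3]) else NULL)
  if (!is.null(labels_a) && !is.null(labels_b)) {
    pa <- if (inherits(labels_a, "volume_image")) labels_a$data else labels_a
    pb <- if (inherits(labels_b, "volume_image")) labels_b$data else labels_b
    prob <- blend(pa, pb)
    lab <- array(as.integer(prob >= 0.5), dim(prob))
    out$fused_probability <- volume_image(prob, a$spacing, a$origin, "label")
    out$fused_labels <- volume_image(lab, a$spacing, a$origin, "label")
  }
  class(out) <- "fused_subject"
  out
}

#' Connected components of a label volume
#'
#' Flood-fill labelling under face (6-neighbour) connectivity by default;
#' the stricter connectivity resists single-voxel diagonal bridges between
#' the kidney and neighbouring mislabelled organs. Components are returned
#' sorted by voxel count, descending, with ties broken by the smallest
#' linear voxel index of the component.
#'
#' @param labels binary 3-D array or label [volume_image].
#' @param connectivity 6 (faces), 18 or 26 (faces+edges+corners).
#' @return list: `labels` (integer array, 0 = background, components
#'   renumbered in sorted order), `sizes` (voxel counts, descending).
#' @export
connected_components <- function(labels, connectivity = 6L) {
  mask <- as_binary_mask(labels)
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab, n)
  # BFS assigns ids by first (smallest) linear index, so a stable sort on
  # size alone implements the documented tie-break
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(n)
  remap[ord] <- seq_len(n)
  relabelled <- array(ifelse(lab > 0L, remap[pmax(lab, 1L)], 0L), dim(lab))
  storage.mode(relabelled) <- "integer"
  list(labels = relabelled, sizes = sizes[ord])
}

com_mm <- function(component_mask, spacing, origin) {
  idx <- which(component_mask, arr.ind = TRUE)
  (colMeans(idx) - 1) * spacing + origin
}

#' Measure kidney volumes and geometry from a fused segmentation
#'
#' Takes the two largest connected components of the fused label volume as
#' the kidneys; the component whose centre of mass lies at larger
#' left--right (column-axis) coordinate is the subject's *left* kidney.
#' Volumes are voxel counts scaled by the voxel volume; centres of mass are
#' reported in subject coordinates (mm, using spacing and origin); the
#' inter-kidney measurement is the componentwise offset and its Euclidean
#' norm. Voxels outside the two largest components are the scrap set.
#'
#' @param fused a `fused_subject` from [fuse_stations()] (with labels), or a
#'   label [volume_image].
#' @param connectivity passed to [connected_components()].
#' @return list of class `kidney_measurement`: `left_volume_cm3`,
#'   `right_volume_cm3`, `combined_volume_cm3`, `left_com_mm`,
#'   `right_com_mm`, `relative_offset_mm`, `distance_mm`, `scrap_fraction`,
#'   `n_components`. A missing kidney reports volume 0 and `NA` geometry.
#' @export
measure <- function(fused, connectivity = 6L) {
  vol <- if (inherits(fused, "fused_subject")) fused$fused_labels else fused
  stopifnot(inherits(vol, "volume_image"))
  cc <- connected_components(vol, connectivity)
  n <- length(cc$sizes)
  vox_cm3 <- voxel_volume_mm3(vol$spacing) / 1000
  out <- list(left_volume_cm3 = 0, right_volume_cm3 = 0,
              combined_volume_cm3 = 0,
              left_com_mm = rep(NA_real_, 3), right_com_mm = rep(NA_real_, 3),
              relative_offset_mm = rep(NA_real_, 3), distance_mm = NA_real_,
              scrap_fraction = 0, n_components = n)
  class(out) <- "kidney_measurement"
  if (n == 0L) return(out)
  total <- sum(cc$sizes)
  kept <- min(n, 2L)
  out$scrap_fraction <- (total - sum(cc$sizes[seq_len(kept)])) / total
  coms <- lapply(seq_len(kept), function(i)
    com_mm(cc$labels == i, vol$spacing, vol$origin))
  if (kept == 1L) {
    # unilateral: assign by position relative to the volume midline
    mid <- vol$origin[2] + (dim(vol$data)[2] - 1) * vol$spacing[2] / 2
    side <- if (coms[[1]][2] >= mid) "left" else "right"
    out[[paste0(side, "_volume_cm3")]] <- cc$sizes[1] * vox_cm3
    out[[paste0(side, "_com_mm")]] <- coms[[1]]
    out$combined_volume_cm3 <- out$left_volume_cm3 + out$right_volume_cm3
    return(out)
  }
  left_i <- if (coms[[1]][2] >= coms[[2]][2]) 1L else 2L
  right_i <- 3L - left_i
  out$left_volume_cm3 <- cc$sizes[left_i] * vox_cm3
  out$right_volume_cm3 <- cc$sizes[right_i] * vox_cm3
  out$combined_volume_cm3 <- out$left_volume_cm3 + out$right_volume_cm3
  out$left_com_mm <- coms[[left_i]]
  out$right_com_mm <- coms[[right_i]]
  out$relative_offset_mm <- out$left_com_mm - out$right_com_mm
  out$distance_mm <- sqrt(sum(out$relative_offset_mm^2))
  out
}

#' @export
print.kidney_measurement <- function(x, ...) {
  cat(sprintf(paste0("<kidney_measurement> left %.1f + right %.1f = %.1f ",
                     "cm^3\n  distance %.1f mm, %d component(s), ",
                     "scrap fraction %.4f\n"),
              x$left_volume_cm3, x$right_volume_cm3, x$combined_volume_cm3,
              x$distance_mm, x$n_components, x$scrap_fraction))
  invisible(x)
}

#' Measurement table for a list of measured subjects
#'
#' @param measurements named list of `kidney_measurement` objects.
#' @return data.frame with one row per subject.
#' @export
measurement_table <- function(measurements) {
  rows <- lapply(names(measurements), function(id) {
    m <- measurements[[id]]
    data.frame(subject_id = id,
               left_volume_cm3 = m$left_volume_cm3,
               right_volume_cm3 = m$right_volume_cm3,
               combined_volume_cm3 = m$combined_volume_cm3,
               distance_mm = m$distance_mm,
               offset_ap_mm = m$relative_offset_mm[1],
               offset_lr_mm = m$relative_offset_mm[2],
               offset_si_mm = m$relative_offset_mm[3],
               scrap_fraction = m$scrap_fraction,
               n_components = m$n_components,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
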