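#' Algorithmic quality ratings
#'
#' Five rule-based cost terms per subject, higher = worse. The first three
#' rate *image quality* (stage 1): disagreement of the two stations in
#' their shared slices, for the water signal and for the segmented labels,
#' plus the longitudinal off-centring of the segmentation. The last two
#' rate *segmentation quality* (stage 2): slice-wise smoothness of the
#' segmented areas and the share of scrap voxels outside the two largest
#' components. The cost formulas below are the package's normative
#' definitions of these ratings.
#'
#' @name quality_costs
NULL

overlap_slices_of <- function(vol_a, vol_b) {
  dz <- vol_a$spacing[3]
  k <- round((vol_b$origin[3] - vol_a$origin[3]) / dz)
  na <- dim(vol_a$data)[3]
  m <- na - k
  if (m <= 0) return(NULL)
  list(a = seq.int(k + 1L, na), b = seq_len(m))
}

#' @describeIn quality_costs Mean absolute intensity difference between the
#'   two (normalized) stations over all overlap voxels; 0 for perfect
#'   anatomical alignment, up to 1 for maximal disagreement.
#' @param a,b normalized water-channel [volume_image] stations.
#' @param overlap overlap slice mapping; computed from the origins when
#'   omitted.
#' @export
image_fusion_cost <- function(a, b, overlap = NULL) {
  if (is.null(overlap)) overlap <- overlap_slices_of(a, b)
  if (is.null(overlap))
    stop("stations have an empty overlap; flag subject for manual review")
  mean(abs(a$data[, , overlap$a] - b$data[, , overlap$b]))
}

#' @describeIn quality_costs One minus the Dice overlap of the two
#'   stations' binary labels restricted to the shared slices; 0 when both
#'   stations segment identically (also when both are empty there), 1 for
#'   disjoint non-empty masks.
#' @param labels_a,labels_b per-station label volumes.
#' @export
segmentation_fusion_cost <- function(labels_a, labels_b, overlap = NULL) {
  if (is.null(overlap)) overlap <- overlap_slices_of(labels_a, labels_b)
  if (is.null(overlap))
    stop("stations have an empty overlap; flag subject for manual review")
  ma <- as_binary_mask(labels_a)[, , overlap$a]
  mb <- as_binary_mask(labels_b)[, , overlap$b]
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(0)
  1 - 2 * sum(ma & mb) / (sa + sb)
}

#' @describeIn quality_costs Relative longitudinal offset between the centre
#'   line of the fused volume and the centre of mass of all segmented
#'   voxels: `|z_com - z_mid| / (z_extent / 2)`, in `[0, 1]`. Values near 1
#'   mean the kidneys sit at the top or bottom edge and may extend beyond
#'   the field of view; an empty segmentation scores the worst cost 1.
#' @param fused_labels fused label [volume_image].
#' @export
location_cost <- function(fused_labels) {
  stopifnot(inherits(fused_labels, "volume_image"))
  mask <- fused_labels$data != 0
  nz <- dim(fused_labels$data)[3]
  if (!any(mask)) {
    warning("empty segmentation; location cost set to worst case 1")
    return(1)
  }
  z_extent <- (nz - 1) * fused_labels$spacing[3]
  if (z_extent == 0) return(0)
  z_mid <- fused_labels$origin[3] + z_extent / 2
  k <- arrayInd(which(mask), dim(fused_labels$data))[, 3]
  z_com <- fused_labels$origin[3] + (mean(k) - 1) * fused_labels$spacing[3]
  min(abs(z_com - z_mid) / (z_extent / 2), 1)
}

#' @describeIn quality_costs Smoothness of the segmented volume along the
#'   longitudinal axis: with per-slice labelled area `A(z)` over the active
#'   range (first to last slice containing labels), the cost is
#'   `mean |A(z+1) - A(z)| / mean A(z)`. Gradual area changes of a compact
#'   organ give small values; abrupt slice-wise jumps — the typical failure
#'   of a slice-wise 2.5D segmentation — inflate it.
#' @export
smoothness_cost <- function(fused_labels) {
  stopifnot(inherits(fused_labels, "volume_image"))
  area <- apply(fused_labels$data != 0, 3, sum)
  active <- which(area > 0)
  if (length(active) == 0L) {
    warning("empty segmentation; smoothness cost 0")
    return(0)
  }
  if (length(active) == 1L) {
    warning("single-slice segmentation; smoothness cost 0")
    return(0)
  }
  a <- area[seq.int(min(active), max(active))]
  mean(abs(diff(a))) / mean(a)
}

#' @describeIn quality_costs Share of labelled voxels outside the two
#'   largest connected components; identically the `scrap_fraction` of
#'   [measure()]. 0 for at most two components or an empty mask.
#' @param connectivity passed to [connected_components()].
#' @export
scrap_cost <- function(fused_labels, connectivity = 6L) {
  cc <- connected_components(fused_labels, connectivity)
  if (length(cc$sizes) == 0L) return(0)
  total <- sum(cc$sizes)
  (total - sum(cc$sizes[seq_len(min(2L, length(cc$sizes)))])) / total
}

#' Compute all five quality costs for one subject
#'
#' @param station_a,station_b water stations (normalized internally).
#' @param labels_a,labels_b per-station label volumes.
#' @param fused a `fused_subject` with labels; fused internally when
#'   omitted.
#' @return one-row data.frame with the five costs.
#' @export
quality_ratings <- function(station_a, station_b, labels_a, labels_b,
                            fused = NULL) {
  na <- normalize_station(station_a)
  nb <- normalize_station(station_b)
  if (is.null(fused))
    fused <- fuse_stations(station_a, station_b, labels_a, labels_b)
  data.frame(
    image_fusion_cost = image_fusion_cost(na, nb),
    segmentation_fusion_cost = segmentation_fusion_cost(labels_a, labels_b),
    location_cost = location_cost(fused$fused_labels),
    smoothness_cost = smoothness_cost(fused$fused_labels),
    scrap_cost = scrap_cost(fused$fused_labels))
}

#' Two-stage percentile flagging of quality outliers
#'
#' Stage 1 flags, over the whole cohort, the union of the worst tails of
#' the image-quality costs (by default the top 1% of `location_cost` and
#' `image_fusion_cost` and the top 2% of `segmentation_fusion_cost`).
#' Stage 2 then computes percentiles of the segmentation-quality costs over
#' the *stage-1 survivors only* and flags their worst tails (default top 1%
#' of `smoothness_cost` and `scrap_cost`). A subject is flagged only when
#' its cost is strictly greater than the percentile threshold, so a cohort
#' of identical costs flags nobody. Subjects flagged by `location_cost`
#' alone can be small kidneys near the border; re-inclusion is left as a
#' manual override (`excluded` is editable), not automated.
#'
#' @param ratings data.frame with one row per subject containing the five
#'   cost columns (and optionally `subject_id`).
#' @param stage1 named top-fractions for stage 1 over
#'   `location`, `image_fusion`, `segmentation_fusion`.
#' @param stage2 named top-fractions for stage 2 over `smoothness`, `scrap`.
#' @return `ratings` with logical columns `stage1_flag`, `stage2_flag`,
#'   `excluded` plus a `summary` attribute (flagged fractions per stage).
#' @export
flag_outliers <- function(ratings,
                          stage1 = c(location = 0.01, image_fusion = 0.01,
                                     segmentation_fusion = 0.02),
                          stage2 = c(smoothness = 0.01, scrap = 0.01)) {
  n <- nrow(ratings)
  if (n < 10L)
    stop("percentile flagging needs at least 10 subjects, got ", n)
  worst_tail <- function(x, frac) {
    thr <- stats::quantile(x, probs = 1 - frac, names = FALSE, type = 7)
    x > thr
  }
  s1 <- worst_tail(ratings$location_cost, stage1[["location"]]) |
    worst_tail(ratings$image_fusion_cost, stage1[["image_fusion"]]) |
    worst_tail(ratings$segmentation_fusion_cost,
               stage1[["segmentation_fusion"]])
  survivors <- which(!s1)
  s2 <- rep(FALSE, n)
  if (length(survivors) >= 2L) {
    s2[survivors] <-
      worst_tail(ratings$smoothness_cost[survivors], stage2[["smoothness"]]) |
      worst_tail(ratings$scrap_cost[survivors], stage2[["scrap"]])
  }
  ratings$stage1_flag <- s1
  ratings$stage2_flag <- s2
  ratings$excluded <- s1 | s2
  attr(ratings, "summary") <- data.frame(
    n = n,
    stage1_flagged = sum(s1), stage1_fraction = mean(s1),
    stage2_flagged = sum(s2), stage2_fraction = mean(s2),
    excluded = sum(s1 | s2), excluded_fraction = mean(s1 | s2))
  ratings
}
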