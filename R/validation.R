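#' Overlap and volume agreement metrics
#'
#' Dice score `2|A∩B| / (|A| + |B|)` and Jaccard index `|A∩B| / |A∪B|` for
#' voxel masks, and the symmetric mean absolute percentage error (SMAPE)
#' for volume pairs, which divides the absolute difference by the mean of
#' prediction and reference — symmetric in its arguments and robust to
#' which of the two is treated as truth. A pair with mean 250 cm^3 and
#' absolute difference 25 cm^3 scores a SMAPE of 10%.
#'
#' When both masks are empty the Dice (and Jaccard) of the pair is defined
#' as 1 ("perfect agreement"); set `empty_value = 0` for the strict
#' reading. These metrics are intended to be computed after station fusion,
#' on fused volumes, so that empty single stations never enter an average.
#'
#' @param pred,ref binary masks (3-D arrays or label [volume_image]s) on
#'   the same grid.
#' @param empty_value value returned when both masks are empty.
#' @return scalar metric.
#' @export
dice <- function(pred, ref, empty_value = 1) {
  a <- as_binary_mask(pred)
  b <- as_binary_mask(ref)
  if (!identical(dim(a), dim(b)))
    stop("masks must share the grid: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(empty_value)
  2 * sum(a & b) / (sa + sb)
}

#' @rdname dice
#' @export
jaccard <- function(pred, ref, empty_value = 1) {
  a <- as_binary_mask(pred)
  b <- as_binary_mask(ref)
  if (!identical(dim(a), dim(b)))
    stop("masks must share the grid: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  u <- sum(a | b)
  if (u == 0) return(empty_value)
  sum(a & b) / u
}

#' @rdname dice
#' @param pred_vol,ref_vol predicted and reference volumes (cm^3).
#' @return `smape()`: error in percent.
#' @export
smape <- function(pred_vol, ref_vol) {
  if (length(pred_vol) != 1L || length(ref_vol) != 1L)
    stop("smape() takes a single pair; use aggregate_volume_metrics() for sets")
  if (pred_vol + ref_vol == 0) {
    warning("both volumes are zero; SMAPE defined as 0")
    return(0)
  }
  abs(pred_vol - ref_vol) / ((pred_vol + ref_vol) / 2) * 100
}

#' Aggregate volume-agreement metrics over a cohort
#'
#' Mean absolute error, mean per-pair SMAPE, the coefficient of
#' determination against the reference variance
#' (`R^2 = 1 - sum((ref - pred)^2) / sum((ref - mean(ref))^2)`), and the
#' 95% Bland-Altman limits of agreement `mean(d) +/- 1.96 sd(d)` with
#' differences `d = reference - predicted` (sample SD), so systematic
#' oversegmentation shifts the interval negative.
#'
#' @param pred_vol,ref_vol numeric vectors of paired volumes (cm^3).
#' @return list: `n`, `mae_cm3`, `smape_pct`, `r_squared` (`NA` when the
#'   references are constant), `loa_cm3` (low, high), `bias_cm3`.
#' @export
aggregate_volume_metrics <- function(pred_vol, ref_vol) {
  stopifnot(length(pred_vol) == length(ref_vol))
  n <- length(pred_vol)
  if (n < 2L) stop("at least two pairs are required")
  d <- ref_vol - pred_vol
  ss_ref <- sum((ref_vol - mean(ref_vol))^2)
  r2 <- if (ss_ref == 0) NA_real_ else 1 - sum(d^2) / ss_ref
  sdd <- stats::sd(d)
  list(n = n,
       mae_cm3 = mean(abs(d)),
       smape_pct = mean(mapply(smape, pred_vol, ref_vol)),
       r_squared = r2,
       bias_cm3 = mean(d),
       loa_cm3 = c(low = mean(d) - 1.96 * sdd, high = mean(d) + 1.96 * sdd))
}

#' Validation report for predicted vs reference segmentations
#'
#' Per-subject Dice, Jaccard and volumes (computed on fused volumes), plus
#' the aggregate metrics of [aggregate_volume_metrics()].
#'
#' @param pred_masks,ref_masks named lists of fused label volumes.
#' @param spacing voxel spacing (taken from the volumes when they are
#'   [volume_image]s).
#' @return list of class `validation_report`: `per_subject` data.frame and
#'   `aggregate`.
#' @export
validation_report <- function(pred_masks, ref_masks, spacing = NULL) {
  ids <- names(pred_masks)
  stopifnot(!is.null(ids), setequal(ids, names(ref_masks)))
  rows <- lapply(ids, function(id) {
    p <- pred_masks[[id]]; r <- ref_masks[[id]]
    sp <- if (inherits(p, "volume_image")) p$spacing else spacing
    data.frame(subject_id = id,
               dice = dice(p, r),
               jaccard = jaccard(p, r),
               pred_volume_cm3 = true_volume(p, sp),
               ref_volume_cm3 = true_volume(r, sp),
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  agg <- aggregate_volume_metrics(per_subject$pred_volume_cm3,
                                  per_subject$ref_volume_cm3)
  agg$mean_dice <- mean(per_subject$dice)
  structure(list(per_subject = per_subject, aggregate = agg),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(paste0("<validation_report> n=%d  Dice %.3f  MAE %.1f cm^3  ",
                     "SMAPE %.1f%%  R^2 %.3f  LoA (%.1f, %.1f) cm^3\n"),
              a$n, a$mean_dice, a$mae_cm3, a$smape_pct, a$r_squared,
              a$loa_cm3[1], a$loa_cm3[2]))
  invisible(x)
}

#' Subject-level cross-validation plan
#'
#' Partitions the primary set into `k` folds of (near-)even size at subject
#' level; an optional extra pool is added to every training set but never
#' appears in any validation fold — the design that lets additional
#' reference data improve training without touching the validation.
#'
#' @param n_subjects size of the primary set.
#' @param k folds (classical default 8).
#' @param extra_pool indices (relative to a combined cohort) used for
#'   training only, or `NULL`.
#' @param seed fold assignment seed.
#' @return list of class `crossval_plan` with `folds` (list of validation
#'   index vectors) and `extra_pool`.
#' @export
crossval_plan <- function(n_subjects, k = 8L, extra_pool = NULL, seed = 1L) {
  if (n_subjects < k) stop("need at least k subjects for k folds")
  if (length(extra_pool) && any(extra_pool <= n_subjects))
    stop("extra_pool indices must lie outside the primary set 1..n_subjects")
  set.seed(seed)
  perm <- sample.int(n_subjects)
  folds <- split(perm, rep_len(seq_len(k), n_subjects))
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(folds = folds, extra_pool = extra_pool, k = k, seed = seed),
            class = "crossval_plan")
}

#' Cross-validated training and evaluation on a phantom cohort
#'
#' For each fold, trains a fresh network on all remaining folds (plus the
#' extra training-only pool, if any), predicts both stations of every
#' held-out subject, fuses them, and scores the fused labels against the
#' fused ground truth. The pooled report concatenates all per-subject rows.
#'
#' @param subjects list of `subject_phantom` objects (primary set first,
#'   then any extra-pool subjects).
#' @param plan a [crossval_plan()].
#' @param spec [network_spec()] for each fold's network.
#' @param cfg [training_config()].
#' @return list: `fold_reports` (one [validation_report] per fold),
#'   `pooled` ([validation_report] over all subjects).
#' @export
cross_validate <- function(subjects, plan, spec, cfg) {
  stopifnot(inherits(plan, "crossval_plan"))
  primary <- setdiff(seq_along(subjects), plan$extra_pool)
  pred_all <- list()
  ref_all <- list()
  fold_reports <- vector("list", plan$k)
  names(fold_reports) <- names(plan$folds)
  for (f in seq_len(plan$k)) {
    val_idx <- plan$folds[[f]]
    if (length(val_idx) == 0L) stop("fold ", f, " has no subjects")
    train_idx <- c(setdiff(primary, val_idx), plan$extra_pool)
    ts <- make_training_set(subjects[train_idx], cfg$drop_ends,
                            spec$downsampling_factor)
    set.seed(cfg$seed + f)
    model <- build_network(spec)
    model <- train_network(model, ts, cfg)
    pred_f <- list()
    ref_f <- list()
    for (i in val_idx) {
      subj <- subjects[[i]]
      pa <- predict_station(model, subj$station_a$water)
      pb <- predict_station(model, subj$station_b$water)
      fused <- fuse_stations(subj$station_a$water, subj$station_b$water,
                             pa$probability, pb$probability)
      id <- sprintf("S%04d", i)
      pred_f[[id]] <- fused$fused_labels
      ref_f[[id]] <- subj$truth_fused
    }
    fold_reports[[f]] <- validation_report(pred_f, ref_f)
    pred_all <- c(pred_all, pred_f)
    ref_all <- c(ref_all, ref_f)
  }
  list(fold_reports = fold_reports,
       pooled = validation_report(pred_all, ref_all))
}
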