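#' Pipeline configuration
#'
#' One nested list driving every subcommand of [run_pipeline()], round-
#' trippable through YAML. Sections: `paths` (manifest, output_dir,
#' checkpoint), `phantom` (arguments of [phantom_config()] plus cohort `n`
#' and `anomaly_rates`), `network` ([network_spec()] arguments),
#' `training` ([training_config()] arguments), `qc` (stage-1/stage-2
#' percentile settings), `validation` (`k`, segmentation source), and a
#' global `seed`.
#'
#' @param path YAML file to read.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(seed = 1L,
       paths = list(output_dir = "kidneyvol_run"),
       phantom = list(n = 10L, anomaly_rates = list()),
       network = list(encoder_widths = c(64, 128, 256, 512, 512),
                      width_multiplier = 0.25),
       training = list(iterations = 2000L, lr = 1e-4,
                       lr_drop_iteration = 1500L, lr_drop_factor = 10,
                       augment_amplitude_px = 4, drop_ends = 2L),
       qc = list(stage1 = list(location = 0.01, image_fusion = 0.01,
                               segmentation_fusion = 0.02),
                 stage2 = list(smoothness = 0.01, scrap = 0.01)),
       validation = list(k = 3L),
       segmentation = "model")
}

merge_config <- function(config) {
  utils::modifyList(default_pipeline_config(), config)
}

config_phantom <- function(config, seed) {
  args <- config$phantom
  args$n <- NULL
  args$anomaly_rates <- NULL
  args$seed <- seed
  do.call(phantom_config, args)
}

load_subject_from_manifest <- function(row) {
  subj <- list(
    station_a = list(water = read_volume(row$station_a, "water")),
    station_b = list(water = read_volume(row$station_b, "water")))
  for (tag in c("truth_a", "truth_b", "truth_fused"))
    if (!is.null(row[[tag]]) && !is.na(row[[tag]]))
      subj[[tag]] <- read_volume(row[[tag]], "label")
  subj
}

subject_labels <- function(subj, model, segmentation) {
  if (segmentation == "truth") {
    if (is.null(subj$truth_a))
      stop("segmentation = 'truth' requires truth masks in the manifest")
    list(a = subj$truth_a, b = subj$truth_b)
  } else {
    pa <- predict_station(model, subj$station_a$water)
    pb <- predict_station(model, subj$station_b$water)
    list(a = pa$probability, b = pb$probability)
  }
}

#' Run one pipeline subcommand
#'
#' Commands: `"simulate"` writes a phantom cohort (NIfTI stations, truth
#' masks, manifest CSV) to the output directory; `"train"` fits a network
#' on the manifest's subjects and saves a checkpoint plus loss trace;
#' `"infer"` segments every manifest subject (or takes the truth masks when
#' `segmentation: truth`, the ground-truth bypass used for phantom
#' validation), fuses the stations and writes the measurement CSV;
#' `"qc"` computes the five quality costs, applies two-stage flagging and
#' writes the QC table; `"validate"` scores fused predictions against the
#' fused truth; `"crossval"` runs the k-fold design on a fresh phantom
#' cohort; `"report"` summarises retained/excluded counts from the QC
#' table. Each command logs its seed and writes under
#' `config$paths$output_dir`. Inference loads and processes one subject at
#' a time, so memory stays flat in cohort size.
#'
#' @param command one of `simulate`, `train`, `infer`, `qc`, `validate`,
#'   `crossval`, `report`.
#' @param config configuration list (see [read_pipeline_config()]); missing
#'   entries take package defaults.
#' @return command-specific result, invisibly where the product is on disk.
#' @export
run_pipeline <- function(command = c("simulate", "train", "infer", "qc",
                                     "validate", "crossval", "report"),
                         config = list()) {
  command <- match.arg(command)
  config <- merge_config(config)
  out_dir <- config$paths$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  message(sprintf("[kidneyvol] %s (seed %d) -> %s", command, seed, out_dir))

  manifest_path <- function() {
    p <- config$paths$manifest
    if (is.null(p)) p <- file.path(out_dir, "manifest.csv")
    p
  }

  if (command == "simulate") {
    cohort <- generate_cohort(
      n = config$phantom$n,
      config = config_phantom(config, seed),
      anomaly_rates = unlist(config$phantom$anomaly_rates),
      seed = seed, dir = out_dir, keep_subjects = FALSE)
    return(invisible(cohort$manifest))
  }

  spec <- do.call(network_spec, config$network)
  cfg_train <- do.call(training_config, c(config$training, list(seed = seed)))

  if (command == "train") {
    manifest <- load_manifest(manifest_path())
    subjects <- lapply(seq_len(nrow(manifest)), function(i)
      load_subject_from_manifest(manifest[i, ]))
    ts <- make_training_set(subjects, cfg_train$drop_ends,
                            spec$downsampling_factor)
    set.seed(seed)
    model <- build_network(spec)
    model <- train_network(model, ts, cfg_train)
    ck <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(model, ck)
    utils::write.csv(data.frame(iteration = seq_along(model$loss_trace),
                                loss = model$loss_trace,
                                lr = model$lr_trace),
                     file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
    return(invisible(model))
  }

  if (command %in% c("infer", "qc", "validate")) {
    manifest <- load_manifest(manifest_path())
    model <- NULL
    if (!identical(config$segmentation, "truth")) {
      ck <- config$paths$checkpoint
      if (is.null(ck)) ck <- file.path(out_dir, "checkpoint.rds")
      model <- load_checkpoint(ck)
    }
    measurements <- list()
    ratings <- list()
    preds <- list()
    refs <- list()
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      subj <- load_subject_from_manifest(row)
      labs <- subject_labels(subj, model, config$segmentation)
      fused <- fuse_stations(subj$station_a$water, subj$station_b$water,
                             labs$a, labs$b)
      id <- row$subject_id
      if (command == "infer") {
        measurements[[id]] <- measure(fused)
        write_volume(fused$fused_labels,
                     file.path(out_dir, paste0(id, "_fused_labels.nii.gz")))
      } else if (command == "qc") {
        ratings[[id]] <- quality_ratings(subj$station_a$water,
                                         subj$station_b$water,
                                         labs$a, labs$b, fused)
      } else {
        preds[[id]] <- fused$fused_labels
        refs[[id]] <- subj$truth_fused
      }
    }
    if (command == "infer") {
      tab <- measurement_table(measurements)
      utils::write.csv(tab, file.path(out_dir, "measurements.csv"),
                       row.names = FALSE)
      return(invisible(tab))
    }
    if (command == "qc") {
      tab <- do.call(rbind, ratings)
      tab <- cbind(subject_id = names(ratings), tab)
      flagged <- flag_outliers(tab,
                               stage1 = unlist(config$qc$stage1),
                               stage2 = unlist(config$qc$stage2))
      utils::write.csv(flagged, file.path(out_dir, "qc_table.csv"),
                       row.names = FALSE)
      return(invisible(flagged))
    }
    report <- validation_report(preds, refs)
    utils::write.csv(report$per_subject,
                     file.path(out_dir, "validation_per_subject.csv"),
                     row.names = FALSE)
    return(report)
  }

  if (command == "crossval") {
    cohort <- generate_cohort(config$phantom$n,
                              config_phantom(config, seed), seed = seed)
    plan <- crossval_plan(config$phantom$n, k = config$validation$k,
                          seed = seed)
    res <- cross_validate(cohort$subjects, plan, spec, cfg_train)
    utils::write.csv(res$pooled$per_subject,
                     file.path(out_dir, "crossval_per_subject.csv"),
                     row.names = FALSE)
    return(res)
  }

  # report
  qc_path <- file.path(out_dir, "qc_table.csv")
  if (!file.exists(qc_path)) stop("run the qc command before report")
  qc <- utils::read.csv(qc_path)
  summary <- data.frame(cohort = nrow(qc),
                        excluded = sum(qc$excluded),
                        retained = sum(!qc$excluded),
                        stage1_flagged = sum(qc$stage1_flag),
                        stage2_flagged = sum(qc$stage2_flag))
  utils::write.csv(summary, file.path(out_dir, "run_summary.csv"),
                   row.names = FALSE)
  summary
}
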