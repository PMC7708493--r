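#' Specification of the 2.5D segmentation network
#'
#' An encoder--decoder ("U") architecture operating on 2.5D slice stacks:
#' three input channels (slice below, target, slice above), a VGG-style
#' encoder of two-convolution blocks with short residual (identity additive)
#' connections around the second convolution of each block, 2x2 max pooling
#' between stages, a mirrored decoder with nearest-neighbour upsampling and
#' long skip concatenations from each encoder stage, and a 1x1 convolution
#' to two class scores (background, kidney). Output spatial dimensions
#' always equal the input dimensions; inputs must be divisible by the total
#' downsampling factor `2^(stages - 1)`.
#'
#' The full-scale configuration uses encoder widths (64, 128, 256, 512, 512)
#' (downsampling factor 16 under this 5-stage layout); `width_multiplier`
#' scales all widths for desk-scale runs on small phantoms.
#'
#' @param encoder_widths channel counts per encoder stage.
#' @param width_multiplier multiplies all widths (result rounded up).
#' @param in_channels input channels (3 for 2.5D stacks).
#' @param n_classes output classes.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(encoder_widths = c(64, 128, 256, 512, 512),
                         width_multiplier = 1, in_channels = 3L,
                         n_classes = 2L) {
  widths <- as.integer(ceiling(encoder_widths * width_multiplier))
  if (length(widths) < 2L) stop("at least two encoder stages are required")
  if (any(widths < 1L)) stop("encoder widths must be positive")
  structure(list(encoder_widths = widths,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 downsampling_factor = as.integer(2^(length(widths) - 1L))),
            class = "network_spec")
}

#' Training configuration
#'
#' Iteration-based training with batch size one, pixel-wise cross-entropy
#' and the Adam optimizer: the learning rate is held at `lr` until
#' `lr_drop_iteration` and then divided by `lr_drop_factor` for stability.
#' The full-scale schedule is 80,000 iterations at 1e-4 with the drop at
#' 60,000; desk-scale runs use the same shape at reduced counts.
#'
#' @param iterations total training iterations.
#' @param lr initial Adam learning rate.
#' @param lr_drop_iteration iteration after which the rate is lowered.
#' @param lr_drop_factor division factor for the drop.
#' @param augment_amplitude_px elastic-augmentation amplitude (0 disables).
#' @param drop_ends outermost station slices excluded from training.
#' @param seed RNG seed for sampling, initialisation and augmentation.
#' @return list of class `training_config`.
#' @export
training_config <- function(iterations = 80000L, lr = 1e-4,
                            lr_drop_iteration = 60000L, lr_drop_factor = 10,
                            augment_amplitude_px = 10, drop_ends = 2L,
                            seed = 1L) {
  if (lr_drop_iteration >= iterations)
    stop("lr_drop_iteration must be smaller than iterations")
  if (lr <= 0 || lr_drop_factor <= 0) stop("learning rates must be positive")
  structure(list(iterations = as.integer(iterations), lr = lr,
                 lr_drop_iteration = as.integer(lr_drop_iteration),
                 lr_drop_factor = lr_drop_factor,
                 augment_amplitude_px = augment_amplitude_px,
                 drop_ends = as.integer(drop_ends), seed = as.integer(seed)),
            class = "training_config")
}

#' Instantiate the segmentation network
#'
#' Allocates and He-initialises all parameters. Initialisation draws from
#' the R RNG, so `set.seed()` before calling makes the model reproducible.
#' An encoder pre-trained elsewhere can be loaded afterwards with
#' [load_encoder_weights()].
#'
#' @param spec a [network_spec()].
#' @return list of class `unet_model` holding the native model handle.
#' @export
build_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  ptr <- cpp_unet_create(spec$encoder_widths, spec$in_channels,
                         spec$n_classes)
  model <- structure(list(ptr = ptr, spec = spec, trained = FALSE),
                     class = "unet_model")
  model
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(paste0("<unet_model> %d stages (widths %s), downsampling x%d, ",
                     "%.0f parameters, %s\n"),
              length(x$spec$encoder_widths),
              paste(x$spec$encoder_widths, collapse = "-"),
              x$spec$downsampling_factor, cpp_unet_nparams(x$ptr),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Assemble a training set of slice stacks from phantom subjects
#'
#' For every station of every subject: normalize, drop the outermost
#' `drop_ends` slices, and build one padded 2.5D stack plus padded label per
#' retained slice.
#'
#' @param subjects list of `subject_phantom` objects.
#' @param drop_ends outermost slices excluded per station end.
#' @param pad_multiple in-plane padding multiple (the network's
#'   downsampling factor).
#' @return list with parallel lists `stacks` and `labels`.
#' @export
make_training_set <- function(subjects, drop_ends = 2L, pad_multiple = 32L) {
  stacks <- list()
  labels <- list()
  for (subj in subjects) {
    for (st in c("a", "b")) {
      vol <- normalize_station(subj[[paste0("station_", st)]]$water)
      truth <- subj[[paste0("truth_", st)]]$data
      for (k in select_training_slices(vol, drop_ends)) {
        stk <- build_stack(vol, k, pad_multiple)
        lab <- matrix(0L, dim(stk$pixels)[1], dim(stk$pixels)[2])
        pr <- stk$pad_spec$row; pc <- stk$pad_spec$col
        lab[pr[1] + seq_len(dim(truth)[1]), pc[1] + seq_len(dim(truth)[2])] <-
          truth[, , k]
        stacks[[length(stacks) + 1L]] <- stk
        labels[[length(labels) + 1L]] <- lab
      }
    }
  }
  list(stacks = stacks, labels = labels)
}

#' Train the segmentation network
#'
#' Iteration loop sampling slices uniformly with replacement, applying
#' online elastic augmentation, and taking one Adam step per slice (batch
#' size one) on the pixel-wise cross-entropy. Deterministic for a fixed
#' `cfg$seed` in single-threaded execution.
#'
#' @param model a [build_network()] model.
#' @param training_set result of [make_training_set()] (lists `stacks`,
#'   `labels`).
#' @param cfg a [training_config()].
#' @return The model, with `loss_trace` and `lr_trace` attached.
#' @export
train_network <- function(model, training_set, cfg = training_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "training_config"))
  n <- length(training_set$stacks)
  if (n == 0L) stop("empty training set")
  for (lab in training_set$labels)
    if (!all(lab %in% c(0L, 1L))) stop("labels must be binary")
  set.seed(cfg$seed)
  loss_trace <- numeric(cfg$iterations)
  lr_trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    lr <- if (it > cfg$lr_drop_iteration) cfg$lr / cfg$lr_drop_factor else
      cfg$lr
    i <- sample.int(n, 1L)
    stk <- training_set$stacks[[i]]
    lab <- training_set$labels[[i]]
    if (cfg$augment_amplitude_px > 0) {
      aug <- elastic_augment(stk, lab, cfg$augment_amplitude_px)
      stk <- aug$stack
      lab <- round(aug$label2d)
    }
    loss_trace[it] <- cpp_unet_step(model$ptr, stk$pixels,
                                    as.integer(lab), lr)
    lr_trace[it] <- lr
  }
  model$trained <- TRUE
  model$loss_trace <- loss_trace
  model$lr_trace <- lr_trace
  model
}

#' Segment a full station slice by slice
#'
#' Normalizes the station, builds the 2.5D stack for every slice, pads to
#' the network's downsampling multiple, runs the forward pass, and reverts
#' the padding, stacking the per-slice labels back into a station-shaped
#' label volume. The softmax foreground probability is retained for
#' probability-weighted label fusion across stations.
#'
#' @param model a trained `unet_model`.
#' @param station a water-channel [volume_image].
#' @param threshold probability threshold for the hard label (argmax at the
#'   default 0.5).
#' @return list with `labels` (binary label [volume_image]) and
#'   `probability` (same grid, foreground probability).
#' @export
predict_station <- function(model, station, threshold = 0.5) {
  stopifnot(inherits(model, "unet_model"))
  if (!isTRUE(model$trained))
    warning("predicting with an untrained network")
  vol <- normalize_station(station)
  d <- dim(vol$data)
  prob <- array(0, d)
  for (k in seq_len(d[3])) {
    stk <- build_stack(vol, k, model$spec$downsampling_factor)
    p <- cpp_unet_predict(model$ptr, stk$pixels)
    prob[, , k] <- unpad(p, stk$pad_spec)
  }
  labels <- array(as.integer(prob >= threshold), d)
  list(labels = volume_image(labels, vol$spacing, vol$origin, "label"),
       probability = volume_image(prob, vol$spacing, vol$origin, "label"))
}

#' Save / load model checkpoints
#'
#' Checkpoints are plain R lists of parameter matrices written with
#' `saveRDS()`.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = cpp_unet_params(model$ptr),
               trained = model$trained), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param spec optional [network_spec()]; defaults to the one stored in the
#'   checkpoint.
#' @export
load_checkpoint <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  ck <- readRDS(path)
  if (is.null(spec)) spec <- ck$spec
  model <- build_network(spec)
  cpp_unet_set_params(model$ptr, ck$params, FALSE)
  model$trained <- isTRUE(ck$trained)
  model
}

#' Initialise the encoder from externally trained weights
#'
#' Loads only `enc*` parameters from a checkpoint file, leaving the decoder
#' untouched — the hook for starting from a pre-trained encoder. Shapes must
#' match the model exactly.
#'
#' @param model a `unet_model`.
#' @param path checkpoint `.rds` with a `params` list.
#' @return The model with encoder weights replaced.
#' @export
load_encoder_weights <- function(model, path) {
  if (!file.exists(path)) stop("no such weight file: ", path)
  ck <- readRDS(path)
  params <- if (!is.null(ck$params)) ck$params else ck
  cpp_unet_set_params(model$ptr, params, TRUE)
  model
}
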