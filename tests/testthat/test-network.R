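test_that("network spec validates and reports the downsampling factor", {
  spec <- network_spec()
  expect_identical(spec$encoder_widths, c(64L, 128L, 256L, 512L, 512L))
  expect_identical(spec$downsampling_factor, 16L)
  quarter <- network_spec(width_multiplier = 0.25)
  expect_identical(quarter$encoder_widths, c(16L, 32L, 64L, 128L, 128L))
  expect_error(network_spec(c(8)), "two encoder stages")
  expect_error(training_config(iterations = 100, lr_drop_iteration = 100),
               "smaller")
})

test_that("forward pass preserves spatial dimensions and rejects odd sizes", {
  set.seed(1)
  model <- build_network(tiny_spec())  # factor 2
  x <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  p <- kidneyvol:::cpp_unet_predict(model$ptr, x)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  x2 <- array(stats::runif(32 * 48 * 3), c(32, 48, 3))
  expect_identical(dim(kidneyvol:::cpp_unet_predict(model$ptr, x2)),
                   c(32L, 48L))
  odd <- array(0, c(33, 33, 3))
  expect_error(kidneyvol:::cpp_unet_predict(model$ptr, odd),
               "not divisible")
})

test_that("training descends on learnable phantom slices", {
  subj <- generate_subject(desk_config(seed = 21))
  ts <- make_training_set(list(subj), drop_ends = 2L, pad_multiple = 2L)
  ts$stacks <- ts$stacks[1:20]
  ts$labels <- ts$labels[1:20]
  set.seed(2)
  model <- build_network(tiny_spec())
  cfg <- training_config(iterations = 200, lr = 1e-3,
                         lr_drop_iteration = 150, lr_drop_factor = 10,
                         augment_amplitude_px = 0, seed = 3)
  model <- train_network(model, ts, cfg)
  expect_lt(mean(tail(model$loss_trace, 20)),
            mean(head(model$loss_trace, 20)))
})

test_that("learning-rate trace is a step function with exactly one drop", {
  subj <- generate_subject(desk_config(seed = 21))
  ts <- make_training_set(list(subj), drop_ends = 6L, pad_multiple = 2L)
  set.seed(2)
  model <- build_network(tiny_spec())
  cfg <- training_config(iterations = 40, lr = 1e-3, lr_drop_iteration = 25,
                         lr_drop_factor = 10, augment_amplitude_px = 0,
                         seed = 3)
  model <- train_network(model, ts, cfg)
  expect_identical(unique(model$lr_trace), c(1e-3, 1e-4))
  expect_identical(sum(diff(model$lr_trace) != 0), 1L)
  expect_equal(model$lr_trace[25], 1e-3)
  expect_equal(model$lr_trace[26], 1e-3 / 10)
})

test_that("training is deterministic for a fixed seed", {
  subj <- generate_subject(desk_config(seed = 21))
  ts <- make_training_set(list(subj), drop_ends = 6L, pad_multiple = 2L)
  run <- function() {
    set.seed(5)
    model <- build_network(tiny_spec())
    cfg <- training_config(iterations = 30, lr = 1e-3,
                           lr_drop_iteration = 20,
                           augment_amplitude_px = 3, seed = 7)
    train_network(model, ts, cfg)$loss_trace
  }
  expect_identical(run(), run())
})

test_that("station prediction aligns voxel-for-voxel with the input", {
  subj <- generate_subject(desk_config(seed = 21))
  set.seed(4)
  model <- build_network(tiny_spec())
  model$trained <- TRUE
  pred <- predict_station(model, subj$station_a$water)
  expect_identical(dim(pred$labels$data), dim(subj$station_a$water$data))
  expect_identical(pred$labels$origin, subj$station_a$water$origin)
  expect_true(all(pred$labels$data %in% c(0L, 1L)))
  expect_true(all(pred$probability$data >= 0 & pred$probability$data <= 1))
})

test_that("checkpoints round-trip and encoder loading enforces shapes", {
  dir <- withr::local_tempdir()
  set.seed(6)
  model <- build_network(tiny_spec())
  ck <- file.path(dir, "model.rds")
  save_checkpoint(model, ck)
  back <- load_checkpoint(ck)
  expect_identical(kidneyvol:::cpp_unet_params(model$ptr),
                   kidneyvol:::cpp_unet_params(back$ptr))

  set.seed(7)
  other <- build_network(tiny_spec())
  other <- load_encoder_weights(other, ck)
  po <- kidneyvol:::cpp_unet_params(other$ptr)
  pm <- kidneyvol:::cpp_unet_params(model$ptr)
  expect_identical(po$enc0_W1, pm$enc0_W1)      # encoder replaced
  expect_false(identical(po$dec0_W1, pm$dec0_W1))  # decoder untouched

  set.seed(8)
  wrong <- build_network(network_spec(c(4, 8)))
  expect_error(load_encoder_weights(wrong, ck), "shape mismatch")
  expect_error(load_encoder_weights(model, file.path(dir, "nope.rds")),
               "no such")
})
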