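test_that("phantom generation is deterministic for a fixed config", {
  s1 <- generate_subject(desk_config(seed = 3))
  s2 <- generate_subject(desk_config(seed = 3))
  expect_identical(s1$station_a$water$data, s2$station_a$water$data)
  expect_identical(s1$station_b$fat$data, s2$station_b$fat$data)
  expect_identical(s1$truth_fused$data, s2$truth_fused$data)
  s3 <- generate_subject(desk_config(seed = 4))
  expect_false(identical(s1$station_a$water$data, s3$station_a$water$data))
})

test_that("station geometry invariants are enforced", {
  expect_error(phantom_config(grid_shape = c(48, 48, 24), station_slices = 16,
                              overlap_slices = 10), "inconsistent")
  expect_error(phantom_config(grid_shape = c(48, 48, 24), station_slices = 16,
                              overlap_slices = 0), "overlap")
  expect_error(phantom_config(voxel_spacing_mm = c(2, -1, 4)), "positive")
})

test_that("zero-motion stations agree exactly on the overlap slices", {
  s <- generate_subject(desk_config(seed = 5, motion_offset_mm = c(0, 0, 0)))
  # overlap: last 8 slices of station A are the first 8 of station B
  expect_identical(s$station_a$water$data[, , 9:16],
                   s$station_b$water$data[, , 1:8])
  expect_identical(s$truth_a$data[, , 9:16], s$truth_b$data[, , 1:8])
})

test_that("anomalies honour their construction contracts", {
  miss <- generate_subject(desk_config(seed = 6, anomaly = "missing_left"))
  expect_identical(miss$true_left_volume_cm3, 0)
  expect_gt(miss$true_right_volume_cm3, 0)
  expect_length(connected_components(miss$truth_fused)$sizes, 1L)

  fused <- generate_subject(desk_config(seed = 6, anomaly = "fused"))
  expect_length(connected_components(fused$truth_fused)$sizes, 1L)

  none <- generate_subject(desk_config(seed = 6))
  expect_length(connected_components(none$truth_fused)$sizes, 2L)

  cysts <- generate_subject(desk_config(seed = 6, anomaly = "cysts"))
  plain <- generate_subject(desk_config(seed = 6))
  expect_lt(sum(cysts$truth_fused$data), sum(plain$truth_fused$data))
})

test_that("full-scale defaults give plausible anatomy", {
  s <- generate_subject(phantom_config(seed = 2))
  expect_identical(dim(s$station_a$water$data), c(224L, 174L, 44L))
  expect_equal(s$station_a$water$spacing, c(2.232, 2.232, 4.5))
  cc <- connected_components(s$truth_fused)
  expect_length(cc$sizes, 2L)
  # adult parenchymal volumes land in the population range
  expect_gt(s$true_left_volume_cm3, 60)
  expect_lt(s$true_left_volume_cm3, 250)
  m <- measure(fuse_stations(s$station_a$water, s$station_b$water,
                             s$truth_a, s$truth_b))
  expect_gt(m$distance_mm, 80)
  expect_lt(m$distance_mm, 160)
})

test_that("true_volume scales voxel counts by the physical voxel volume", {
  arr <- array(0L, c(20, 10, 10))
  arr[seq_len(1000)] <- 1L
  expect_equal(true_volume(arr, c(2.232, 2.232, 4.5)),
               1000 * 2.232 * 2.232 * 4.5 / 1000)
  expect_equal(true_volume(arr, c(2.232, 2.232, 4.5)), 22.418208)
  expect_identical(true_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)), 0)
  one <- array(0L, c(3, 3, 3)); one[14] <- 1L
  expect_equal(true_volume(one, c(10, 10, 10)), 1)
})

test_that("cohort generation is reproducible with exact anomaly counts", {
  c1 <- generate_cohort(10, desk_config(), seed = 9)
  expect_identical(nrow(c1$manifest), 10L)
  expect_true(all(c1$manifest$anomaly == "none"))

  c2 <- generate_cohort(20, desk_config(),
                        anomaly_rates = c(large_motion = 0.1,
                                          missing_left = 0.05),
                        seed = 9)
  expect_identical(sum(c2$manifest$anomaly == "large_motion"), 2L)
  expect_identical(sum(c2$manifest$anomaly == "missing_left"), 1L)
  c3 <- generate_cohort(20, desk_config(),
                        anomaly_rates = c(large_motion = 0.1,
                                          missing_left = 0.05),
                        seed = 9)
  expect_identical(c2$manifest, c3$manifest)
  expect_error(generate_cohort(5, desk_config(),
                               anomaly_rates = c(cysts = 0.9, fused = 0.3)),
               "at most 1")
})

test_that("truth masks recover true volumes through fusion and measurement", {
  for (sd in 11:14) {
    s <- generate_subject(desk_config(seed = sd))
    f <- fuse_stations(s$station_a$water, s$station_b$water,
                       s$truth_a, s$truth_b)
    m <- measure(f)
    expect_lt(abs(m$left_volume_cm3 - s$true_left_volume_cm3) /
                s$true_left_volume_cm3, 0.02)
    expect_lt(abs(m$right_volume_cm3 - s$true_right_volume_cm3) /
                s$true_right_volume_cm3, 0.02)
  }
})
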