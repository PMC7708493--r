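overlapping_pair <- function(value_a, value_b, nz = 8L, k = 4L) {
  a <- vol3(array(value_a, c(6, 6, nz)), spacing = c(1, 1, 2),
            channel = "water")
  b <- vol3(array(value_b, c(6, 6, nz)), spacing = c(1, 1, 2),
            origin = c(0, 0, k * 2), channel = "water")
  list(a = a, b = b)
}

test_that("image fusion cost measures overlap disagreement in [0, 1]", {
  same <- overlapping_pair(0.4, 0.4)
  expect_equal(image_fusion_cost(same$a, same$b), 0)
  opposite <- overlapping_pair(0, 1)
  expect_equal(image_fusion_cost(opposite$a, opposite$b), 1)
  none <- overlapping_pair(0, 1, k = 8L)
  expect_error(image_fusion_cost(none$a, none$b), "empty overlap")
})

test_that("image fusion cost grows with injected inter-station motion", {
  costs <- sapply(c(0, 3, 6, 9), function(sh) {
    s <- generate_subject(desk_config(seed = 5,
                                      motion_offset_mm = c(sh, 0, sh)))
    image_fusion_cost(normalize_station(s$station_a$water),
                      normalize_station(s$station_b$water))
  })
  expect_true(all(diff(costs) >= 0))
  expect_gt(costs[4], costs[1])
})

test_that("segmentation fusion cost is one minus overlap Dice", {
  la <- array(0L, c(6, 6, 8)); lb <- array(0L, c(6, 6, 8))
  mk <- function(la, lb) {
    p <- overlapping_pair(0, 0)
    list(a = vol3(la, c(1, 1, 2)), b = vol3(lb, c(1, 1, 2),
                                            origin = c(0, 0, 8)))
  }
  # both empty in overlap
  p <- mk(la, lb)
  expect_equal(segmentation_fusion_cost(p$a, p$b), 0)
  # identical non-empty
  la[2:4, 2:4, 5:8] <- 1L
  lb[2:4, 2:4, 1:4] <- 1L
  p <- mk(la, lb)
  expect_equal(segmentation_fusion_cost(p$a, p$b), 0)
  # disjoint
  lb2 <- array(0L, dim(lb)); lb2[5:6, 5:6, 1:4] <- 1L
  p <- mk(la, lb2)
  expect_equal(segmentation_fusion_cost(p$a, p$b), 1)
  # |A| = 4, |B| = 6, |A∩B| = 3 -> 1 - 2*3/10
  la2 <- array(0L, c(6, 6, 8)); la2[1, 1:4, 5] <- 1L
  lb3 <- array(0L, c(6, 6, 8)); lb3[1, 2:6, 1] <- 1L; lb3[2, 1, 1] <- 1L
  p <- mk(la2, lb3)
  expect_equal(segmentation_fusion_cost(p$a, p$b), 0.4)
})

test_that("location cost is the relative longitudinal off-centring", {
  base <- array(0L, c(5, 5, 21))
  mid <- base; mid[3, 3, 11] <- 1L
  expect_equal(location_cost(vol3(mid, c(1, 1, 1))), 0)
  top <- base; top[3, 3, 21] <- 1L
  expect_equal(location_cost(vol3(top, c(1, 1, 1))), 1)
  quarter <- base; quarter[3, 3, 16] <- 1L
  expect_equal(location_cost(vol3(quarter, c(1, 1, 1))), 0.5)
  expect_warning(c0 <- location_cost(vol3(base, c(1, 1, 1))), "empty")
  expect_equal(c0, 1)
})

test_that("smoothness cost penalizes abrupt slice-wise area jumps", {
  profile_mask <- function(areas) {
    arr <- array(0L, c(12, 12, length(areas)))
    for (k in seq_along(areas)) {
      n <- areas[k]
      if (n > 0) arr[, , k][seq_len(n)] <- 1L
    }
    vol3(arr, c(1, 1, 1))
  }
  flat <- profile_mask(c(0, 50, 50, 50, 0))
  expect_equal(smoothness_cost(flat), 0)
  spiky <- profile_mask(c(0, 100, 1, 100, 0))
  gentle <- profile_mask(c(80, 100, 100, 80))
  expect_gt(smoothness_cost(spiky), smoothness_cost(gentle))

  s <- generate_subject(desk_config(seed = 8))
  f <- fuse_stations(s$station_a$water, s$station_b$water,
                     s$truth_a, s$truth_b)
  clean <- smoothness_cost(f$fused_labels)
  island <- f$fused_labels
  island$data[1:3, 1:3, 2:3] <- 1L   # spurious disconnected island
  expect_gt(smoothness_cost(island), clean)
  expect_gt(scrap_cost(island), 0)
  expect_equal(scrap_cost(f$fused_labels), 0)

  single <- array(0L, c(4, 4, 5)); single[2, 2, 3] <- 1L
  expect_warning(sc <- smoothness_cost(vol3(single)), "single-slice")
  expect_equal(sc, 0)
})

test_that("scrap cost equals the out-of-two-largest share", {
  m <- array(0L, c(20, 20, 6))
  m[1:4, 1:5, 1:5] <- 1L
  m[10:13, 10:13, 1:5] <- 1L
  m[17, 17, 1:5] <- 1L
  expect_equal(scrap_cost(vol3(m)), 5 / 185)
  three <- array(0L, c(12, 4, 4))
  three[1:2, 1:2, 1:2] <- 1L; three[5:6, 1:2, 1:2] <- 1L
  three[9:10, 1:2, 1:2] <- 1L
  expect_equal(scrap_cost(vol3(three)), 8 / 24)
  expect_equal(scrap_cost(vol3(array(0L, c(4, 4, 4)))), 0)
  # consistency with the measurement path
  expect_equal(scrap_cost(vol3(m)), measure(vol3(m))$scrap_fraction)
})

test_that("two-stage flagging respects tie rules and union bounds", {
  n <- 200
  same <- data.frame(image_fusion_cost = rep(0.1, n),
                     segmentation_fusion_cost = rep(0.2, n),
                     location_cost = rep(0.1, n),
                     smoothness_cost = rep(0.3, n),
                     scrap_cost = rep(0, n))
  flagged <- flag_outliers(same)
  expect_identical(sum(flagged$excluded), 0L)

  set.seed(17)
  rnd <- data.frame(image_fusion_cost = runif(n),
                    segmentation_fusion_cost = runif(n),
                    location_cost = runif(n),
                    smoothness_cost = runif(n),
                    scrap_cost = runif(n))
  fr <- flag_outliers(rnd)
  s <- attr(fr, "summary")
  expect_lte(s$stage1_fraction, 0.01 + 0.01 + 0.02)
  # discrete union bound: each strict tail holds at most ceil(n * p) subjects
  n_surv <- n - s$stage1_flagged
  expect_lte(s$stage2_flagged, ceiling(n_surv * 0.01) + ceiling(n_surv * 0.01))
  expect_identical(fr$excluded, fr$stage1_flag | fr$stage2_flag)
  # stage 2 only ever flags stage-1 survivors
  expect_false(any(fr$stage1_flag & fr$stage2_flag))

  expect_error(flag_outliers(rnd[1:5, ]), "at least 10")
})
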