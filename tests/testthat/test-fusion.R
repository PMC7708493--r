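make_station_pair <- function(nz = 10L, k = 6L, fill_a = NULL, fill_b = NULL) {
  # station A slices 1..nz, station B starts k slices later (same length)
  a <- array(stats::runif(8 * 8 * nz), c(8, 8, nz))
  b <- array(0, c(8, 8, nz))
  b[, , seq_len(nz - k)] <- a[, , k + seq_len(nz - k)]  # identical overlap
  b[, , (nz - k + 1):nz] <- stats::runif(8 * 8 * k)
  if (!is.null(fill_a)) a[] <- fill_a
  if (!is.null(fill_b)) b[] <- fill_b
  list(a = vol3(a, spacing = c(2, 2, 3), channel = "water"),
       b = vol3(b, spacing = c(2, 2, 3), origin = c(0, 0, k * 3),
                channel = "water"))
}

test_that("identical overlap content fuses to either input verbatim", {
  p <- make_station_pair()
  f <- fuse_stations(p$a, p$b)
  expect_identical(dim(f$fused_water$data), c(8L, 8L, 16L))
  expect_equal(f$fused_water$data[, , 1:10], p$a$data)
  expect_equal(f$fused_water$data[, , 7:16], p$b$data)
  expect_identical(f$overlap_range, c(7L, 10L))
})

test_that("blend weights sum to one and intensities stay in the hull", {
  p <- make_station_pair(fill_a = 0, fill_b = 1)
  f <- fuse_stations(p$a, p$b)
  ov <- f$fused_water$data[, , 7:10]
  expect_true(all(ov >= 0 & ov <= 1))
  # weight of B rises across the overlap
  w <- apply(ov, 3, mean)
  expect_true(all(diff(w) > 0))
  expect_equal(w, 1 - rev(w))  # symmetric ramp: weights sum to 1
})

test_that("label probabilities blend with the ramp and threshold at 0.5", {
  nz <- 10L; k <- 6L
  la <- array(1L, c(8, 8, nz))
  lb <- array(0L, c(8, 8, nz))
  p <- make_station_pair(nz, k)
  f <- fuse_stations(p$a, p$b, vol3(la, c(2, 2, 3)),
                     vol3(lb, c(2, 2, 3), origin = c(0, 0, k * 3)))
  # overlap m = 4, w_b = (0.5, 1.5, 2.5, 3.5)/4; blended = 1 - w_b,
  # thresholded with >= 0.5: first two overlap slices stay kidney
  got <- apply(f$fused_labels$data, 3, function(s) unique(as.vector(s)))
  expect_equal(unlist(got[7:8]), c(1L, 1L))
  expect_equal(unlist(got[9:10]), c(0L, 0L))
  expect_equal(f$fused_probability$data[1, 1, 8], 1 - 1.5 / 4)
})

test_that("mismatched or misaligned stations are rejected", {
  p <- make_station_pair()
  wrong <- vol3(array(0, c(6, 8, 10)), spacing = c(2, 2, 3), channel = "water")
  expect_error(fuse_stations(p$a, wrong), "in-plane")
  off <- p$b; off$origin[3] <- 19.4
  expect_error(fuse_stations(p$a, off), "not aligned")
  gap <- p$b; gap$origin[3] <- 45
  expect_warning(fuse_stations(p$a, gap), "do not overlap")
})

test_that("connected components match counts, order and face connectivity", {
  m <- array(0L, c(12, 12, 12))
  m[1:3, 1:3, 1:3] <- 1L          # 27 voxels
  m[8:12, 8:12, 8:11] <- 1L       # 100 voxels
  m[6:9, 1:4, 6:10] <- 1L         # 80 voxels
  m[1, 12, 1:5] <- 1L             # 5 voxels of scrap
  cc <- connected_components(m)
  expect_identical(cc$sizes, c(100L, 80L, 27L, 5L))
  expect_identical(sum(cc$sizes), sum(m))

  diag2 <- array(0L, c(4, 4, 4))
  diag2[1, 1, 1] <- 1L
  diag2[2, 2, 1] <- 1L
  expect_length(connected_components(diag2, 6)$sizes, 2L)
  expect_length(connected_components(diag2, 26)$sizes, 1L)

  expect_length(connected_components(array(0L, c(3, 3, 3)))$sizes, 0L)
})

test_that("component labelling matches the brute-force flood-fill oracle", {
  set.seed(31)
  for (i in 1:8) {
    m <- array(rbinom(12^3, 1, 0.25), c(12, 12, 12))
    fast <- connected_components(m)$labels
    slow <- oracle_components(m)
    # same partition: each oracle component maps to exactly one fast label
    expect_identical(sort(tabulate(fast)), sort(tabulate(slow)))
    expect_identical(max(fast), max(slow))
    for (l in seq_len(max(slow)))
      expect_length(unique(fast[slow == l]), 1L)
    expect_identical(sum(tabulate(fast)), sum(m))
  }
})

test_that("measurement reports volumes, sides, distance and scrap", {
  arr <- array(0L, c(30, 40, 10))
  arr[1:10, 1:10, 1:10] <- 1L    # right kidney (low column)
  arr[1:10, 31:40, 1:10] <- 1L   # left kidney (high column)
  v <- vol3(arr, spacing = c(2.232, 2.232, 4.5))
  m <- measure(v)
  expect_equal(m$left_volume_cm3, 22.418208)  # 1000 voxels x 22.418208 mm^3
  expect_equal(m$right_volume_cm3, 22.418208)
  expect_equal(m$combined_volume_cm3, m$left_volume_cm3 + m$right_volume_cm3)
  expect_gt(m$left_com_mm[2], m$right_com_mm[2])
  expect_equal(m$distance_mm, sqrt(sum(m$relative_offset_mm^2)))

  # 3-4-5 triangle: COMs 30 mm apart in rows, 40 mm in columns
  tri <- array(0L, c(60, 60, 3))
  tri[1, 1, 2] <- 1L
  tri[31, 41, 2] <- 1L
  mt <- measure(vol3(tri, spacing = c(1, 1, 1)))
  expect_equal(mt$distance_mm, 50)

  scrap <- array(0L, c(20, 20, 6))
  scrap[1:4, 1:5, 1:5] <- 1L        # 100
  scrap[10:13, 10:13, 1:5] <- 1L    # 80
  scrap[18:19, 18:19, 6] <- 0L
  scrap[17, 17, 1:5] <- 1L          # 5
  ms <- measure(vol3(scrap))
  expect_equal(ms$scrap_fraction, 5 / 185)
  expect_identical(ms$n_components, 3L)

  empty <- measure(vol3(array(0L, c(5, 5, 5))))
  expect_identical(empty$combined_volume_cm3, 0)
  expect_true(is.na(empty$distance_mm))

  uni <- array(0L, c(10, 10, 4))
  uni[3:5, 7:9, 2:3] <- 1L
  mu <- measure(vol3(uni))
  expect_gt(mu$left_volume_cm3, 0)
  expect_identical(mu$right_volume_cm3, 0)
  expect_true(is.na(mu$distance_mm))
})
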