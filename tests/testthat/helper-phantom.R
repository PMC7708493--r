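# Desk-scale phantom configuration used throughout the suite: same station
# layout as the acquisition (two overlapping stations, 2s - overlap = z
# extent) on a coarse 48 x 48 x 24 grid so whole cohorts stay cheap.
desk_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = c(48L, 48L, 24L),
                 voxel_spacing_mm = c(4, 4, 6),
                 station_slices = 16L, overlap_slices = 8L,
                 kidney_size_range = list(ap = c(28, 36), lr = c(16, 22),
                                          si = c(38, 50)),
                 seed = seed, ...)
}

# Tiny network + schedule for plumbing tests (not for accuracy checks).
tiny_spec <- function() network_spec(c(6, 12), in_channels = 3L)

# Independent brute-force connected-component oracle: repeated breadth-first
# flood fill in plain R over an explicit neighbour list.
oracle_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  man <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[man > 0 & (connectivity == 26L | man == 1L), ]
  labels <- array(0L, d)
  nextl <- 0L
  for (start in which(mask != 0)) {
    if (labels[start] != 0L) next
    nextl <- nextl + 1L
    queue <- start
    labels[start] <- nextl
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      pos <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        p <- pos + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(p < 1L) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1L) + d[2] * (p[3] - 1L))
        if (mask[w] != 0 && labels[w] == 0L) {
          labels[w] <- nextl
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# volume_image wrapper for quickly built arrays
vol3 <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 channel = "label") {
  volume_image(arr, spacing = spacing, origin = origin, channel = channel)
}
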