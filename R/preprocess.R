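#' Normalize a station volume for the network
#'
#' Clips the brightest fraction of intensity values (for stability against
#' hot voxels) at the `1 - clip_fraction` quantile of the station's
#' intensity distribution and rescales linearly to `[0, 1]`. The quantile is
#' estimated over all voxels of the station.
#'
#' @param volume a [volume_image].
#' @param clip_fraction fraction of brightest values clipped (default 0.01).
#' @return A normalized [volume_image] with intensities in `[0, 1]`.
#' @export
normalize_station <- function(volume, clip_fraction = 0.01) {
  stopifnot(inherits(volume, "volume_image"))
  x <- volume$data
  if (length(x) == 0) stop("empty volume")
  q <- stats::quantile(x, probs = 1 - clip_fraction, names = FALSE, type = 7)
  mn <- min(x)
  if (q <= mn) {
    warning("constant-intensity volume; returning zeros")
    volume$data <- array(0, dim(x))
    return(volume)
  }
  volume$data <- (pmin(x, q) - mn) / (q - mn)
  volume
}

next_multiple <- function(n, m) as.integer(ceiling(n / m) * m)

# symmetric split of a pad width; the extra voxel of an odd pad goes after
pad_split <- function(total) {
  total <- as.integer(total)
  c(before = total %/% 2L, after = total - total %/% 2L)
}

#' Build a 2.5D slice stack for one axial slice
#'
#' Extracts the target slice together with its immediate neighbours below
#' and above as three channels, using a periodic border condition at the
#' station ends (slice 1 wraps to slice S and vice versa), then zero-pads
#' both in-plane dimensions symmetrically up to the next multiple of
#' `pad_multiple` so the stack is evenly divisible through the network's
#' downsampling stages. With the acquisition in-plane matrix of 224 x 174
#' and the default multiple of 32 this yields 224 x 192 x 3 stacks. The pad
#' widths are recorded for exact inversion by [unpad()].
#'
#' @param volume a (normalized) [volume_image].
#' @param slice_index target slice, 1-based.
#' @param pad_multiple in-plane dimensions are padded up to a multiple of
#'   this (the network's total downsampling factor).
#' @return list of class `slice_stack`: `pixels` (H' x W' x 3 array),
#'   `pad_spec`, `slice_index`.
#' @export
build_stack <- function(volume, slice_index, pad_multiple = 32L) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$data)
  s <- d[3]
  if (s < 1L) stop("station has no slices")
  if (slice_index < 1L || slice_index > s)
    stop("slice_index out of range 1..", s)
  wrap <- function(i) ((i - 1L) %% s) + 1L
  idx <- wrap(slice_index + c(-1L, 0L, 1L))
  stack <- volume$data[, , idx, drop = FALSE]
  target <- c(next_multiple(d[1], pad_multiple),
              next_multiple(d[2], pad_multiple))
  pr <- pad_split(target[1] - d[1])
  pc <- pad_split(target[2] - d[2])
  padded <- array(0, c(target[1], target[2], 3L))
  padded[pr[1] + seq_len(d[1]), pc[1] + seq_len(d[2]), ] <- stack
  structure(list(pixels = padded,
                 pad_spec = list(row = pr, col = pc),
                 slice_index = slice_index),
            class = "slice_stack")
}

#' Revert the in-plane zero padding of a slice stack
#'
#' Exact inverse of the padding applied by [build_stack()], used to map the
#' network's per-slice label images back onto the station grid.
#'
#' @param labels2d matrix with the padded in-plane dimensions.
#' @param pad_spec the `pad_spec` recorded by [build_stack()].
#' @return matrix cropped to the original in-plane dimensions.
#' @export
unpad <- function(labels2d, pad_spec) {
  d <- dim(labels2d)
  pr <- pad_spec$row
  pc <- pad_spec$col
  nr <- d[1] - sum(pr)
  nc <- d[2] - sum(pc)
  if (nr <= 0 || nc <= 0)
    stop("pad_spec inconsistent with input dimensions ", d[1], " x ", d[2])
  labels2d[pr[1] + seq_len(nr), pc[1] + seq_len(nc), drop = FALSE]
}

#' Random elastic deformation of a slice stack and its label
#'
#' Draws a coarse grid of random displacements, interpolates it bilinearly
#' to a smooth dense field, and warps all three channels of the stack and
#' the label image with the *same* field — linear interpolation for the
#' images, nearest-neighbour for the label so it stays binary. Used as
#' online augmentation during training; deterministic given the RNG state.
#'
#' @param stack a `slice_stack` from [build_stack()].
#' @param label2d label matrix aligned with the stack.
#' @param amplitude_px maximum displacement magnitude in pixels (0 disables).
#' @param grid_size control points per in-plane axis (default 4).
#' @return list with the warped `stack` and `label2d`.
#' @export
elastic_augment <- function(stack, label2d, amplitude_px = 10,
                            grid_size = 4L) {
  if (amplitude_px <= 0) return(list(stack = stack, label2d = label2d))
  d <- dim(stack$pixels)
  coarse_field <- function() {
    g <- matrix(stats::rnorm(grid_size^2, sd = amplitude_px / 2),
                grid_size, grid_size)
    g[g > amplitude_px] <- amplitude_px
    g[g < -amplitude_px] <- -amplitude_px
    # bilinear upsample of the control grid to the full resolution
    ri <- seq(1, grid_size, length.out = d[1])
    ci <- seq(1, grid_size, length.out = d[2])
    r0 <- pmin(floor(ri), grid_size - 1L); fr <- ri - r0
    c0 <- pmin(floor(ci), grid_size - 1L); fc <- ci - c0
    a <- g[cbind(rep(r0, d[2]), rep(c0, each = d[1]))]
    b <- g[cbind(rep(r0 + 1, d[2]), rep(c0, each = d[1]))]
    cc <- g[cbind(rep(r0, d[2]), rep(c0 + 1, each = d[1]))]
    dd <- g[cbind(rep(r0 + 1, d[2]), rep(c0 + 1, each = d[1]))]
    wr <- rep(fr, d[2]); wc <- rep(fc, each = d[1])
    matrix((1 - wr) * (1 - wc) * a + wr * (1 - wc) * b +
             (1 - wr) * wc * cc + wr * wc * dd, d[1], d[2])
  }
  dr <- coarse_field()
  dc <- coarse_field()
  for (ch in 1:3)
    stack$pixels[, , ch] <- cpp_warp_bilinear(stack$pixels[, , ch], dr, dc)
  label2d <- cpp_warp_nearest(label2d, dr, dc)
  list(stack = stack, label2d = label2d)
}

#' Training slice selection excluding station ends
#'
#' The outermost station slices suffer the strongest acquisition artefacts
#' (signal loss, fold-over), so a configurable number at each end is
#' excluded from training.
#'
#' @param n_slices total slices in the station, or a [volume_image].
#' @param drop_ends slices dropped at each end.
#' @return integer vector of retained slice indices (1-based).
#' @export
select_training_slices <- function(n_slices, drop_ends = 2L) {
  if (inherits(n_slices, "volume_image")) n_slices <- dim(n_slices$data)[3]
  n_slices <- as.integer(n_slices)
  drop_ends <- as.integer(drop_ends)
  if (drop_ends < 0L) stop("drop_ends must be >= 0")
  if (2L * drop_ends >= n_slices)
    stop("drop_ends = ", drop_ends, " leaves no slices out of ", n_slices)
  seq.int(drop_ends + 1L, n_slices - drop_ends)
}
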