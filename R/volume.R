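#' In-memory 3-D image volume
#'
#' The package-wide container for station volumes and label masks: a 3-D
#' array with voxel spacing and origin in millimetres. The axis convention is
#' fixed across all modules: the first array dimension runs
#' anterior--posterior (rows of an axial slice), the second left--right
#' (columns; the subject's left is at *increasing* column index), and the
#' third inferior--superior (axial slice position). Voxel `(i, j, k)` sits at
#' physical position `origin + (i - 1, j - 1, k - 1) * spacing` mm.
#'
#' @param data numeric 3-D array of intensities (or 0/1 labels).
#' @param spacing numeric length-3 voxel spacing in mm, all entries positive.
#' @param origin numeric length-3 position of voxel `(1, 1, 1)` in mm.
#' @param channel signal channel tag: `"water"`, `"fat"` or `"label"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0),
                         channel = c("water", "fat", "label")) {
  channel <- match.arg(channel)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 channel = channel),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %s, %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              x$channel, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param spacing length-3 voxel spacing in mm.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(spacing) prod(as.numeric(spacing))

as_binary_mask <- function(x) {
  arr <- if (inherits(x, "volume_image")) x$data else x
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("mask must be a 3-D array or volume_image")
  arr <- (arr >= 0.5) * 1L
  storage.mode(arr) <- "integer"
  arr
}
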