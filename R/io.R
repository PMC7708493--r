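#' Read a station volume or label mask from NIfTI
#'
#' Populates spacing and origin from the NIfTI header (qform/sform offset).
#' NIfTI (`.nii` / `.nii.gz`) is the canonical on-disk format of the package;
#' the cohort-native DICOM series layout is not supported by this build and
#' is rejected with an informative error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param channel channel tag to attach (`"water"`, `"fat"` or `"label"`).
#' @return A [volume_image].
#' @export
read_volume <- function(path, channel = "water") {
  if (!file.exists(path))
    stop("cannot read volume: no such file: ", path)
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series import is not supported, ",
         "convert the series to NIfTI first")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3-D image (", length(dim(img)),
         " dimensions found)")
  arr <- array(as.numeric(img), dim(img))  # plain array, no header baggage
  xf <- RNifti::xform(img)
  spacing <- as.numeric(RNifti::pixdim(img)[1:3])
  origin <- as.numeric(xf[1:3, 4])
  volume_image(arr, spacing = spacing, origin = origin, channel = channel)
}

#' Write a station volume or label mask to NIfTI
#'
#' Spacing goes to pixdim and the origin into the qform offset, so a
#' `write_volume()` / [read_volume()] round-trip is lossless for the stored
#' datatype. Label volumes are stored as unsigned 8-bit integers, images as
#' 32-bit floats.
#'
#' @param image a [volume_image].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "volume_image"))
  if (anyNA(image$data) || any(!is.finite(image$data)))
    stop("refusing to write volume with NA or non-finite voxels")
  datatype <- if (image$channel == "label") "uint8" else "float"
  img <- RNifti::asNifti(image$data)
  RNifti::pixdim(img) <- image$spacing
  m <- diag(c(image$spacing, 1))
  m[1:3, 4] <- image$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' A manifest is a CSV with one row per subject naming the two station files
#' and, optionally, ground-truth label files and an anomaly tag. Required
#' columns: `subject_id`, `station_a`, `station_b`. Recognised optional
#' columns: `truth_a`, `truth_b`, `truth_fused`, `anomaly`, `seed`,
#' `true_left_volume_cm3`, `true_right_volume_cm3`.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced files exist (default `TRUE`).
#' @return A `data.frame` with class `cohort_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("manifest '", path, "' is empty")
    df <- data.frame(subject_id = character(), station_a = character(),
                     station_b = character(), stringsAsFactors = FALSE)
    class(df) <- c("cohort_manifest", "data.frame")
    return(df)
  }
  required <- c("subject_id", "station_a", "station_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (check_files) {
    base <- dirname(path)
    path_cols <- intersect(c("station_a", "station_b", "truth_a", "truth_b",
                             "truth_fused"), names(df))
    for (col in path_cols) {
      p <- df[[col]]
      p <- ifelse(file.exists(p), p, file.path(base, p))
      absent <- !file.exists(p)
      if (any(absent))
        stop("manifest column '", col, "' references missing file(s): ",
             paste(utils::head(df[[col]][absent], 3), collapse = ", "))
      df[[col]] <- p
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}
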