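# Volume / MIP / mask I/O and the subtraction + projection steps.
#
# Axis convention: volumes are arrays indexed (slice, row, col); the axial
# MIP reduces the slice axis. NIfTI files written by this package store the
# array in that order with matching pixdim; DICOM series are re-ordered into
# it on load.

#' Load a 3D volume from NIfTI or a DICOM series directory
#'
#' @param path Path to a `.nii`/`.nii.gz` file or to a directory of
#'   single-frame DICOM files (one slice each).
#' @param format `"nifti"` or `"dicom_dir"`.
#' @return A list with `volume` (3D array, `(slice, row, col)`) and
#'   `spacing` (`(dz, dy, dx)` in mm). Negative spacings found in headers
#'   are normalized to their absolute value with a warning.
#' @export
load_volume <- function(path, format = c("nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("load_volume: file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3) {
      stop("load_volume: expected a 3D NIfTI volume, got ",
           length(dim(arr)), "D", call. = FALSE)
    }
    sp <- RNifti::pixdim(img)[seq_len(3)]
    if (any(sp < 0)) {
      warning("load_volume: negative voxel spacing in header; using absolute values")
      sp <- abs(sp)
    }
    sp[sp == 0] <- 1
    list(volume = arr, spacing = as.numeric(sp))
  } else {
    read_dicom_series(path)
  }
}

#' Write a 3D volume to NIfTI
#'
#' @param volume 3D array `(slice, row, col)`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing `(dz, dy, dx)` voxel spacing in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Subtraction volume (post-contrast minus pre-contrast)
#'
#' Element-wise `post - pre` with negative values clamped to zero, the
#' standard display convention for subtraction DCE-MRI.
#'
#' @param pre,post 3D arrays of identical shape.
#' @return 3D array of non-negative enhancement values.
#' @export
compute_subtraction <- function(pre, post) {
  if (!identical(dim(pre), dim(post))) {
    stop("compute_subtraction: pre and post shapes differ", call. = FALSE)
  }
  pmax(post - pre, 0)
}

#' Axial maximum intensity projection
#'
#' Per-pixel maximum along the slice axis (axis 1 of the `(slice, row, col)`
#' convention).
#'
#' @param volume Non-empty 3D array.
#' @param pixel_spacing `(dy, dx)` in mm for the resulting image; defaults to
#'   `(1, 1)`.
#' @param case_id Case identifier carried onto the image.
#' @return A [mip_image].
#' @export
compute_axial_mip <- function(volume, pixel_spacing = c(1, 1), case_id = "case") {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3 || any(d == 0)) {
    stop("compute_axial_mip: volume must be a non-empty 3D array", call. = FALSE)
  }
  mip <- apply(volume, c(2, 3), max)
  mip_image(pmax(mip, 0), pixel_spacing = pixel_spacing, case_id = case_id)
}

#' Read a binary mask from PNG or NIfTI
#'
#' Any nonzero pixel becomes foreground. If `expect_dim` is given, the raster
#' must match it (the mask must live on its MIP grid).
#'
#' @param path `.png`, `.nii` or `.nii.gz` file.
#' @param role Mask role; see [binary_mask].
#' @param case_id Case identifier.
#' @param expect_dim Optional `(rows, cols)` the mask must match.
#' @return A [binary_mask]. An all-zero vessel mask is accepted with a
#'   warning (a valid edited state for cases without visible vessels).
#' @export
read_mask <- function(path, role = "tumor", case_id = "case", expect_dim = NULL) {
  if (!file.exists(path)) stop("read_mask: file not found: ", path, call. = FALSE)
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  } else {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
    if (length(dim(arr)) != 2) stop("read_mask: expected a 2D mask", call. = FALSE)
    arr
  }
  if (!is.null(expect_dim) && !identical(dim(px), as.integer(expect_dim))) {
    stop("read_mask: mask raster does not match the expected MIP grid",
         call. = FALSE)
  }
  m <- binary_mask(px != 0, role = role, case_id = case_id)
  if (role == "vessel" && !any(m$pixels)) {
    warning("read_mask: vessel mask is empty (accepted as an edited state)")
  }
  m
}

#' Write a binary mask to PNG or NIfTI
#'
#' PNG output is 8-bit with foreground = 255; NIfTI output stores 0/1.
#'
#' @param mask A [binary_mask].
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(mask$pixels * 1, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(mask$pixels * 1L), path)
  }
  invisible(path)
}

#' Read a pre-computed 2D MIP image
#'
#' Accepts NIfTI (2D or single-slice 3D) and 16-bit TIFF.
#'
#' @param path `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @param pixel_spacing Used for TIFF input (no spacing metadata); NIfTI
#'   spacing comes from the header.
#' @param case_id Case identifier.
#' @return A [mip_image].
#' @export
read_mip <- function(path, pixel_spacing = c(1, 1), case_id = "case") {
  if (!file.exists(path)) stop("read_mip: file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3) px <- px[, , 1]
    mip_image(px, pixel_spacing = pixel_spacing, case_id = case_id)
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
    if (length(dim(arr)) != 2) stop("read_mip: expected a 2D image", call. = FALSE)
    arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))  # drop NIfTI attrs
    sp <- abs(RNifti::pixdim(img)[seq_len(2)])
    sp[sp == 0] <- 1
    mip_image(arr, pixel_spacing = sp, case_id = case_id)
  }
}

#' Write a 2D MIP image
#'
#' NIfTI keeps native intensities; TIFF output is 16-bit with intensities
#' rescaled to the full range (lossy for non-integer data).
#'
#' @param mip A [mip_image].
#' @param path Output path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return The path, invisibly.
#' @export
write_mip <- function(mip, path) {
  stopifnot(inherits(mip, "mip_image"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(mip$pixels)
    scaled <- if (mx > 0) mip$pixels / mx else mip$pixels
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else {
    img <- RNifti::asNifti(mip$pixels)
    RNifti::pixdim(img) <- mip$pixel_spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}
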