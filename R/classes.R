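# Core raster containers. Images and masks are plain matrices wrapped with
# light S3 classes; tabular results everywhere downstream are tibbles.

#' Construct a MIP image
#'
#' A `mip_image` is a 2D non-negative intensity raster, typically the axial
#' maximum intensity projection of a subtraction DCE-MRI volume, plus its
#' pixel spacing and a case identifier.
#'
#' @param pixels Numeric matrix (rows = image rows, columns = image columns).
#'   All values must be finite and non-negative.
#' @param pixel_spacing Numeric length-2 vector `(dy, dx)` in mm.
#' @param case_id Character scalar identifying the case.
#' @return An object of class `mip_image`.
#' @export
mip_image <- function(pixels, pixel_spacing = c(1, 1), case_id = "case") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) {
    stop("mip_image: pixels must all be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("mip_image: pixels must be non-negative", call. = FALSE)
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("mip_image: pixel_spacing must be two positive numbers", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         case_id = as.character(case_id)[1]),
    class = "mip_image"
  )
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image '%s': %d x %d px, spacing %.3g x %.3g mm, range [%.3g, %.3g]>\n",
              x$case_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mip_image <- function(x) dim(x$pixels)

.mask_roles <- c("breast", "lateral_breast", "tumor", "vessel")

#' Construct a binary mask
#'
#' A `binary_mask` is a 2D logical raster on the same grid as its MIP image,
#' with a role tag (`breast`, `lateral_breast`, `tumor` or `vessel`).
#'
#' @param pixels Logical (or coercible 0/1) matrix.
#' @param role One of `"breast"`, `"lateral_breast"`, `"tumor"`, `"vessel"`.
#' @param case_id Character scalar identifying the case.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, role = "tumor", case_id = "case") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    pixels <- matrix(pixels != 0, nrow = nrow(pixels))
  }
  role <- match.arg(role, .mask_roles)
  structure(
    list(pixels = pixels, role = role, case_id = as.character(case_id)[1]),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s' role=%s: %d x %d px, %d foreground>\n",
              x$case_id, x$role, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' Construct a DCE-MRI series
#'
#' Holds the pre-contrast and first post-contrast volumes of one case.
#' Volumes are 3D arrays indexed `(slice, row, col)`; both must share a shape
#' and the voxel spacing must be strictly positive.
#'
#' @param pre_volume,post_volume 3D numeric arrays with identical dimensions.
#' @param voxel_spacing Numeric length-3 `(dz, dy, dx)` in mm.
#' @param case_id Character scalar.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(pre_volume, post_volume, voxel_spacing = c(1, 1, 1),
                       case_id = "case") {
  if (!identical(dim(pre_volume), dim(post_volume))) {
    stop("dce_series: pre and post volumes must have identical shapes",
         call. = FALSE)
  }
  if (length(dim(pre_volume)) != 3) {
    stop("dce_series: volumes must be 3D arrays", call. = FALSE)
  }
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0)) {
    stop("dce_series: voxel_spacing must be three positive numbers",
         call. = FALSE)
  }
  structure(
    list(pre_volume = pre_volume, post_volume = post_volume,
         voxel_spacing = voxel_spacing, case_id = as.character(case_id)[1]),
    class = "dce_series"
  )
}

# internal: check that a mask sits on the raster of a given image/mask
check_same_raster <- function(a, b, what = "inputs") {
  da <- if (inherits(a, c("mip_image", "binary_mask"))) dim(a$pixels) else dim(a)
  db <- if (inherits(b, c("mip_image", "binary_mask"))) dim(b$pixels) else dim(b)
  if (!identical(da, db)) {
    stop(sprintf("%s must share the same raster (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
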