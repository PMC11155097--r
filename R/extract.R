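# Full feature-vector assembly: 99 features for vessel ROIs (original
# channel only), 455 for tumor ROIs (plus four undecimated wavelet
# channels). Shape features are computed once, on the original mask.

# 19 first-order + 70 texture features of one channel
.channel_features <- function(px, mk, bin_width, gldm_alpha, gldm_delta,
                              pixel_spacing) {
  gl <- discretize(px, mk, bin_width)
  fo <- first_order_features(px, mk, bin_width, pixel_spacing)
  glcm <- glcm_features(gl)
  glrlm <- glrlm_features(gl)
  glszm <- glszm_features(gl)
  gldm <- gldm_features(gldm_matrix(gl, gldm_alpha, gldm_delta))
  c(stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(glcm, paste0("glcm_", names(glcm))),
    stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
    stats::setNames(glszm, paste0("glszm_", names(glszm))),
    stats::setNames(gldm, paste0("gldm_", names(gldm))))
}

#' Extract a radiomics feature vector for one ROI
#'
#' For `roi_type = "vessel"`: 10 shape, 19 first-order and 70 texture
#' features on the original image (99 features). For `roi_type = "tumor"`:
#' the same 99 plus first-order and texture features on the four
#' undecimated wavelet sub-bands (4 x 89 = 356), 455 in total. Feature
#' names follow `<channel>_<family>_<feature>` with channels `original`,
#' `wavelet-LL`, `wavelet-LH`, `wavelet-HL`, `wavelet-HH`.
#'
#' @param mip A [mip_image].
#' @param mask A non-empty [binary_mask] on the same raster.
#' @param roi_type `"tumor"` or `"vessel"`.
#' @param bin_width Discretization bin width (native intensity units).
#' @param gldm_alpha,gldm_delta GLDM tolerance and neighbourhood distance.
#' @param wavelet_family Passed to [wavelet_decompose()].
#' @return A tibble with columns `feature` and `value`, in fixed order
#'   (455 rows for tumor, 99 for vessel), all values finite.
#' @export
extract_feature_vector <- function(mip, mask, roi_type = c("tumor", "vessel"),
                                   bin_width = 25, gldm_alpha = 0L,
                                   gldm_delta = 1L,
                                   wavelet_family = "coif1") {
  roi_type <- match.arg(roi_type)
  stopifnot(inherits(mip, "mip_image"), inherits(mask, "binary_mask"))
  check_same_raster(mip, mask, "extract_feature_vector: image and mask")
  if (!any(mask$pixels)) {
    stop("extract_feature_vector: empty mask", call. = FALSE)
  }
  sp <- mip$pixel_spacing
  shp <- shape2d_features(mask, sp)
  orig <- .channel_features(mip$pixels, mask$pixels, bin_width, gldm_alpha,
                            gldm_delta, sp)
  out <- c(
    stats::setNames(shp, paste0("original_shape2D_", names(shp))),
    stats::setNames(orig, paste0("original_", names(orig)))
  )
  if (roi_type == "tumor") {
    bands <- wavelet_decompose(mip, family = wavelet_family)
    for (b in names(bands)) {
      ch <- .channel_features(bands[[b]], mask$pixels, bin_width, gldm_alpha,
                              gldm_delta, sp)
      out <- c(out, stats::setNames(ch, paste0("wavelet-", b, "_", names(ch))))
    }
  }
  if (!all(is.finite(out))) {
    stop("extract_feature_vector: non-finite feature values", call. = FALSE)
  }
  expected <- if (roi_type == "tumor") 455L else 99L
  stopifnot(length(out) == expected)
  tibble::tibble(feature = names(out), value = unname(out))
}

#' Extract features for a list of cases into a wide table
#'
#' @param mips List of [mip_image]s.
#' @param masks List of [binary_mask]s, aligned with `mips`.
#' @param roi_type `"tumor"` or `"vessel"`.
#' @param ... Passed to [extract_feature_vector()].
#' @return A tibble with `case_id` plus one column per feature.
#' @export
extract_cohort_features <- function(mips, masks, roi_type = "tumor", ...) {
  stopifnot(length(mips) == length(masks))
  rows <- purrr::map2(mips, masks, function(im, mk) {
    fv <- extract_feature_vector(im, mk, roi_type, ...)
    tibble::as_tibble_row(stats::setNames(as.list(fv$value), fv$feature)) |>
      dplyr::mutate(case_id = im$case_id, .before = 1)
  })
  dplyr::bind_rows(rows)
}
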