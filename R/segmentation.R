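# Breast / lateral-breast segmentation, vessel binarization and
# post-processing, and tumor-vessel disjointness.

# Otsu threshold on a numeric vector (256-bin histogram)
.otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * nbins) + 1L, nbins),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

.disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, "disc")

#' Segment the breast region of a MIP
#'
#' Otsu threshold of a median-smoothed MIP, keeping the largest connected
#' component, followed by morphological closing (disc radius 5) and hole
#' filling.
#'
#' @param mip A [mip_image]; must not be constant.
#' @return A [binary_mask] with role `"breast"`.
#' @export
segment_breast <- function(mip) {
  stopifnot(inherits(mip, "mip_image"))
  px <- mip$pixels
  if (diff(range(px)) == 0) {
    stop("segment_breast: constant image cannot be segmented", call. = FALSE)
  }
  sm <- as.matrix(EBImage::medianFilter(px / max(px), size = 2L))
  thr <- .otsu_threshold(sm)
  fg <- sm > thr
  if (!any(fg)) fg <- sm >= thr
  if (all(fg)) {
    warning("segment_breast: whole frame is foreground after thresholding")
  } else {
    lab <- label_components(fg, 8L)
    sizes <- tabulate(lab[lab > 0])
    fg <- lab == which.max(sizes)
  }
  fg <- as.matrix(EBImage::closing(fg * 1, .disc_brush(5L))) > 0
  fg <- as.matrix(EBImage::fillHull(fg * 1)) > 0
  binary_mask(fg, role = "breast", case_id = mip$case_id)
}

#' Restrict the breast mask to the tumor's lateral half
#'
#' The image is split at the vertical midline; the breast mask is kept on
#' the side containing the tumor centroid. A centroid exactly on the
#' midline is assigned to the left half with a warning.
#'
#' @param breast Breast [binary_mask].
#' @param tumor Non-empty tumor [binary_mask] on the same raster.
#' @return A [binary_mask] with role `"lateral_breast"`.
#' @export
lateral_breast_mask <- function(breast, tumor) {
  check_same_raster(breast, tumor, "lateral_breast_mask: masks")
  if (!any(tumor$pixels)) {
    stop("lateral_breast_mask: tumor mask is empty", call. = FALSE)
  }
  W <- ncol(breast$pixels)
  centroid0 <- mean(which(tumor$pixels, arr.ind = TRUE)[, 2]) - 1  # 0-based
  if (centroid0 == W / 2) {
    warning("lateral_breast_mask: tumor centroid on the midline; using left half")
  }
  left <- centroid0 <= W / 2
  keep <- if (left) seq_len(floor(W / 2)) else (floor(W / 2) + 1L):W
  out <- matrix(FALSE, nrow(breast$pixels), W)
  out[, keep] <- breast$pixels[, keep]
  binary_mask(out, role = "lateral_breast", case_id = breast$case_id)
}

#' Binarize a vesselness map into the peritumoral vessel mask
#'
#' Thresholds the vesselness (Otsu over nonzero values inside the lateral
#' mask unless a fixed threshold is given), closes small gaps (disc radius
#' 1), fills holes, removes components below `min_size` pixels and
#' intersects with the lateral breast mask.
#'
#' @param vmap A `vesselness_map` from [hessian_vesselness()].
#' @param lateral Non-empty lateral-breast [binary_mask].
#' @param threshold Fixed vesselness threshold, or `NULL` (Otsu).
#' @param min_size Minimum connected-component size in pixels (default 20).
#' @return A [binary_mask] with role `"vessel"`; empty (with a warning)
#'   when the vesselness carries no signal.
#' @export
binarize_and_clean <- function(vmap, lateral, threshold = NULL, min_size = 20L) {
  stopifnot(inherits(vmap, "vesselness_map"), inherits(lateral, "binary_mask"))
  check_same_raster(vmap$values, lateral$pixels, "binarize_and_clean: rasters")
  if (!any(lateral$pixels)) {
    stop("binarize_and_clean: empty lateral mask", call. = FALSE)
  }
  v <- vmap$values
  vals <- v[lateral$pixels & v > 0]
  if (length(vals) == 0) {
    warning("binarize_and_clean: vesselness is zero everywhere in the mask; no vessels")
    return(binary_mask(matrix(FALSE, nrow(v), ncol(v)), role = "vessel",
                       case_id = lateral$case_id))
  }
  thr <- if (is.null(threshold)) .otsu_threshold(vals) else threshold
  bw <- v > thr
  bw <- as.matrix(EBImage::closing(bw * 1, .disc_brush(1L))) > 0
  bw <- as.matrix(EBImage::fillHull(bw * 1)) > 0
  lab <- label_components(bw, 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    bw[lab > 0 & sizes[pmax(lab, 1)] < min_size] <- FALSE
  }
  bw <- bw & lateral$pixels
  binary_mask(bw, role = "vessel", case_id = lateral$case_id)
}

#' Remove tumor-vessel overlap
#'
#' The tumor contour is the authoritative input, so contested pixels stay
#' with the tumor and are erased from the algorithmic vessel mask; the
#' returned masks are disjoint (the vessel mask is strictly peritumoral).
#' A vessel mask emptied this way is returned empty; downstream code treats
#' that like any other vessel-free segmentation.
#'
#' @param tumor,vessel [binary_mask]s on the same raster.
#' @return A list with the unchanged `tumor` and updated `vessel` masks.
#' @export
remove_tumor_overlap <- function(tumor, vessel) {
  check_same_raster(tumor, vessel, "remove_tumor_overlap: masks")
  if (!any(tumor$pixels)) {
    stop("remove_tumor_overlap: empty tumor mask", call. = FALSE)
  }
  out <- vessel$pixels & !tumor$pixels
  list(tumor = tumor,
       vessel = binary_mask(out, role = "vessel", case_id = vessel$case_id))
}

#' Segment peritumoral vessels of one case
#'
#' Convenience wrapper running breast segmentation, lateral restriction,
#' multiscale vesselness, binarization/cleaning and tumor-overlap removal.
#'
#' @param mip A [mip_image].
#' @param tumor Tumor [binary_mask].
#' @param params A [vesselness_params].
#' @param threshold,min_size Passed to [binarize_and_clean()].
#' @return List with `vessel`, `tumor` (disjoint masks), `breast`,
#'   `lateral`, and the `vesselness` map.
#' @export
segment_vessels <- function(mip, tumor, params = vesselness_params(),
                            threshold = NULL, min_size = 20L) {
  breast <- segment_breast(mip)
  lateral <- lateral_breast_mask(breast, tumor)
  vmap <- hessian_vesselness(mip, params)
  vessel <- binarize_and_clean(vmap, lateral, threshold, min_size)
  if (any(tumor$pixels & vessel$pixels)) {
    res <- remove_tumor_overlap(tumor, vessel)
    vessel <- res$vessel
  }
  list(vessel = vessel, tumor = tumor, breast = breast, lateral = lateral,
       vesselness = vmap)
}
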