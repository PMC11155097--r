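# Discretization, first-order statistics and 2D shape features.

#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the in-mask minimum:
#' `level = floor((x - min) / bin_width) + 1`. Pixels outside the mask get
#' level 0.
#'
#' @param mip A [mip_image] or numeric matrix.
#' @param mask A [binary_mask] or logical matrix on the same raster.
#' @param bin_width Bin width in native intensity units (default 25).
#' @return A `gray_level_image` list: `levels` (integer matrix, 0 outside
#'   the mask), `n_levels`, `bin_width`.
#' @export
discretize <- function(mip, mask, bin_width = 25) {
  px <- if (inherits(mip, "mip_image")) mip$pixels else as.matrix(mip)
  mk <- if (inherits(mask, "binary_mask")) mask$pixels else as.matrix(mask) != 0
  check_same_raster(px, mk, "discretize: image and mask")
  if (!any(mk)) stop("discretize: empty mask", call. = FALSE)
  if (bin_width <= 0) stop("discretize: bin_width must be positive", call. = FALSE)
  lv <- matrix(0L, nrow(px), ncol(px))
  x <- px[mk]
  lv[mk] <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  structure(list(levels = lv, n_levels = max(lv), bin_width = bin_width),
            class = "gray_level_image")
}

#' First-order intensity statistics of an ROI
#'
#' The 19 standard first-order features (energy, total energy, entropy,
#' minimum, 10th/90th percentiles, maximum, mean, median, interquartile
#' range, range, mean absolute deviation, robust MAD, RMS, standard
#' deviation, skewness, kurtosis, variance, uniformity). Entropy and
#' uniformity are computed on the fixed-bin-width discretized histogram;
#' variance and the standardized moments use the population convention, and
#' skewness/kurtosis of a constant ROI are defined as 0.
#'
#' @inheritParams discretize
#' @param pixel_spacing `(dy, dx)` in mm, used for total energy.
#' @return Named numeric vector of length 19.
#' @export
first_order_features <- function(mip, mask, bin_width = 25,
                                 pixel_spacing = NULL) {
  px <- if (inherits(mip, "mip_image")) mip$pixels else as.matrix(mip)
  mk <- if (inherits(mask, "binary_mask")) mask$pixels else as.matrix(mask) != 0
  if (is.null(pixel_spacing)) {
    pixel_spacing <- if (inherits(mip, "mip_image")) mip$pixel_spacing else c(1, 1)
  }
  check_same_raster(px, mk, "first_order_features: image and mask")
  if (!any(mk)) stop("first_order_features: empty mask", call. = FALSE)
  x <- px[mk]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  robust <- x[x >= q[1] & x <= q[5]]
  lev <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(
    Energy = sum(x^2),
    TotalEnergy = prod(pixel_spacing) * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# marching-squares style mesh area and perimeter of a binary mask
.mesh_geometry <- function(mk, dy, dx) {
  H <- nrow(mk); W <- ncol(mk)
  pm <- matrix(FALSE, H + 2, W + 2)
  pm[2:(H + 1), 2:(W + 1)] <- mk
  a <- pm[-nrow(pm), -ncol(pm)]   # top-left corners of each cell
  b <- pm[-nrow(pm), -1]          # top-right
  d <- pm[-1, -ncol(pm)]         # bottom-left
  e <- pm[-1, -1]                # bottom-right
  code <- a + 2 * b + 4 * d + 8 * e
  counts <- tabulate(code + 1, nbins = 16)
  cell <- dy * dx
  hyp <- sqrt((dy / 2)^2 + (dx / 2)^2)
  # area fraction and perimeter length per marching-squares case
  area_frac <- c(0, 1/8, 1/8, 1/2, 1/8, 1/2, 1/4, 7/8,
                 1/8, 1/4, 1/2, 7/8, 1/2, 7/8, 7/8, 1)
  perim_len <- c(0, hyp, hyp, dy, hyp, dy, 2 * hyp, hyp,
                 hyp, 2 * hyp, dy, hyp, dx, hyp, hyp, 0)
  # cases 3 (a+b) and 12 (d+e) cut vertically through the cell: length dx;
  # cases 5 (a+d) and 10 (b+e) cut horizontally: length dy
  perim_len[c(4, 13)] <- dx
  perim_len[c(6, 11)] <- dy
  list(area = sum(counts * area_frac) * cell,
       perimeter = sum(counts * perim_len))
}

#' 2D shape features of an ROI mask
#'
#' Ten standard shape descriptors: mesh surface, pixel surface, perimeter,
#' perimeter-to-surface ratio, sphericity, spherical disproportion, maximum
#' diameter, major/minor axis length and elongation. Axis lengths are
#' `4 * sqrt(lambda)` from the PCA of physical pixel coordinates. Pixel
#' spacing (mm) is honoured when supplied; otherwise units are pixels.
#'
#' @param mask A [binary_mask] or logical matrix (all components pooled).
#' @param pixel_spacing `(dy, dx)`.
#' @return Named numeric vector of length 10.
#' @export
shape2d_features <- function(mask, pixel_spacing = c(1, 1)) {
  mk <- if (inherits(mask, "binary_mask")) mask$pixels else as.matrix(mask) != 0
  if (!any(mk)) stop("shape2d_features: empty mask", call. = FALSE)
  dy <- pixel_spacing[1]; dx <- pixel_spacing[2]
  geo <- .mesh_geometry(mk, dy, dx)
  idx <- which(mk, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * dy, idx[, 2] * dx)
  # maximum diameter over the convex hull of boundary points
  maxdiam <- if (nrow(pts) == 1) 0 else {
    hull <- pts[unique(grDevices::chull(pts)), , drop = FALSE]
    if (nrow(hull) < 2) 0 else max(stats::dist(hull))
  }
  if (nrow(pts) > 1) {
    ev <- eigen(stats::cov(pts) * (nrow(pts) - 1) / nrow(pts),
                symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0)
  sph <- if (geo$perimeter > 0) 2 * sqrt(pi * geo$area) / geo$perimeter else 0
  c(
    MeshSurface = geo$area,
    PixelSurface = sum(mk) * dy * dx,
    Perimeter = geo$perimeter,
    PerimeterSurfaceRatio = if (geo$area > 0) geo$perimeter / geo$area else 0,
    Sphericity = sph,
    SphericalDisproportion = if (sph > 0) 1 / sph else 0,
    MaximumDiameter = maxdiam,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  )
}
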