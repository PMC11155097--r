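# Texture features from gray-level matrices. Counting is done in C++
# (see src/texture_matrices.cpp); all formulas here operate on the counts.
# Conventions: GLCM symmetric, distance 1, features averaged over the four
# 2D angles; GLRLM averaged over the four run directions; GLSZM zones are
# 8-connected; GLDM dependence is the 0-based neighbour count within
# Chebyshev distance delta and tolerance alpha.

.eps <- 2.2e-16

.glcm_angles <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# features of one normalized symmetric GLCM
.glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # difference and sum marginals
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  DA <- sum(k_diff * p_diff)
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0] + .eps))
  HXY2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  # MCC: sqrt of the second largest eigenvalue of Q
  mcc <- if (ng == 1) 1 else {
    denom <- outer(px, py)
    Q <- matrix(0, ng, ng)
    ok <- px > 0
    Pn <- P
    Q <- (Pn %*% t(Pn / pmax(py, .eps))) / pmax(px, .eps)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(i * j * P) - mux * muy) / (sigx * sigy)
  } else 1
  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    DifferenceVariance = sum((k_diff - DA)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p_diff[k_diff > 0] / k_diff[k_diff > 0]^2),
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = sum((i - mux)^2 * P)
  )
}

#' Gray level co-occurrence (GLCM) features
#'
#' 24 features from symmetric distance-1 co-occurrence matrices, computed
#' per angle (0, 45, 90, 135 degrees) and averaged.
#'
#' @param gl A `gray_level_image` from [discretize()].
#' @param distance Pixel offset distance (default 1).
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(gl, distance = 1L) {
  per_angle <- lapply(.glcm_angles, function(a) {
    M <- cpp_glcm(gl$levels, gl$n_levels, a[1] * distance, a[2] * distance)
    M <- M + t(M)
    if (sum(M) == 0) return(NULL)
    .glcm_features_one(M / sum(M))
  })
  per_angle <- per_angle[!vapply(per_angle, is.null, logical(1))]
  if (length(per_angle) == 0) {
    stop("glcm_features: no co-occurring in-mask pixel pairs", call. = FALSE)
  }
  colMeans(do.call(rbind, per_angle))
}

.glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
  "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

.glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
  "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

# shared run/zone-style features from a (level x size) count matrix
.size_features <- function(M, np, feature_names) {
  ng <- nrow(M)
  ns <- ncol(M)
  nz <- sum(M)
  i <- matrix(seq_len(ng), ng, ns)
  s <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  P <- M / nz
  mu_i <- sum(i * P); mu_s <- sum(s * P)
  p_pos <- P[P > 0]
  vals <- c(
    sum(M / s^2) / nz,                       # small emphasis
    sum(M * s^2) / nz,                       # large emphasis
    sum(rowSums(M)^2) / nz,                  # gray level non-uniformity
    sum(rowSums(M)^2) / nz^2,                # ... normalized
    sum(colSums(M)^2) / nz,                  # size non-uniformity
    sum(colSums(M)^2) / nz^2,                # ... normalized
    nz / np,                                 # percentage
    sum((i - mu_i)^2 * P),                   # gray level variance
    sum((s - mu_s)^2 * P),                   # size variance
    -sum(p_pos * log2(p_pos)),               # entropy
    sum(M / i^2) / nz,                       # low gray level
    sum(M * i^2) / nz,                       # high gray level
    sum(M / (i^2 * s^2)) / nz,               # small + low
    sum(M * i^2 / s^2) / nz,                 # small + high
    sum(M * s^2 / i^2) / nz,                 # large + low
    sum(M * s^2 * i^2) / nz                  # large + high
  )
  names(vals) <- feature_names
  vals
}

#' Gray level run length (GLRLM) features
#'
#' 16 features from run-length matrices in the four 2D directions, averaged
#' over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(gl) {
  np <- sum(gl$levels > 0)
  per_dir <- lapply(.glcm_angles, function(a) {
    M <- cpp_glrlm(gl$levels, gl$n_levels, a[1], a[2])
    .size_features(M, np, .glrlm_names)
  })
  colMeans(do.call(rbind, per_dir))
}

#' Gray level size zone (GLSZM) features
#'
#' 16 features from the size-zone matrix (8-connected zones of equal level).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(gl) {
  np <- sum(gl$levels > 0)
  M <- cpp_glszm(gl$levels, gl$n_levels)
  .size_features(M, np, .glszm_names)
}

#' Gray level dependence matrix
#'
#' For each in-mask pixel, the dependence `d` is the number of in-mask
#' neighbours within Chebyshev distance `delta` whose absolute level
#' difference is at most `alpha`; counts are accumulated at
#' `(level, d)`. Column `j` of the returned matrix holds dependence
#' `d = j - 1`.
#'
#' @inheritParams glcm_features
#' @param alpha Level-difference tolerance (default 0).
#' @param delta Chebyshev neighbourhood distance (default 1).
#' @return A `gldm_matrix` list: `counts` (`n_levels` x `max_dependence+1`),
#'   `alpha`, `delta`.
#' @export
gldm_matrix <- function(gl, alpha = 0L, delta = 1L) {
  M <- cpp_gldm(gl$levels, gl$n_levels, as.integer(alpha), as.integer(delta))
  structure(list(counts = M, alpha = alpha, delta = delta),
            class = "gldm_matrix")
}

#' Gray level dependence (GLDM) features
#'
#' The 14 standard GLDM features. Dependence values are the raw (0-based)
#' neighbour counts; cells at dependence 0 contribute nothing to the
#' features that divide by the dependence (an isolated pixel carries no
#' small-dependence evidence). A 1-based convention is available via
#' `dependence_base = 1`.
#'
#' @param m A `gldm_matrix` from [gldm_matrix()], or a `gray_level_image`
#'   (the matrix is then built with defaults).
#' @param dependence_base 0 (default) or 1; added to the stored neighbour
#'   count before computing dependence-weighted features.
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(m, dependence_base = 0) {
  if (inherits(m, "gray_level_image")) m <- gldm_matrix(m)
  M <- m$counts
  nz <- sum(M)
  if (nz == 0) stop("gldm_features: empty dependence matrix", call. = FALSE)
  ng <- nrow(M); nd <- ncol(M)
  i <- matrix(seq_len(ng), ng, nd)
  d <- matrix(0:(nd - 1) + dependence_base, ng, nd, byrow = TRUE)
  P <- M / nz
  mu_i <- sum(i * P); mu_d <- sum(d * P)
  p_pos <- P[P > 0]
  inv_d2 <- ifelse(d > 0, 1 / d^2, 0)
  c(
    SmallDependenceEmphasis = sum(P * inv_d2),
    LargeDependenceEmphasis = sum(P * d^2),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * P),
    DependenceVariance = sum((d - mu_d)^2 * P),
    DependenceEntropy = -sum(p_pos * log2(p_pos)),
    LowGrayLevelEmphasis = sum(P / i^2),
    HighGrayLevelEmphasis = sum(P * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(P * inv_d2 / i^2),
    SmallDependenceHighGrayLevelEmphasis = sum(P * inv_d2 * i^2),
    LargeDependenceLowGrayLevelEmphasis = sum(P * d^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(P * d^2 * i^2)
  )
}

#' Connected components of a logical matrix
#'
#' @param m Logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(m, connectivity = 8L) {
  cpp_label_components(as.matrix(m) != 0, as.integer(connectivity))
}
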