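# Multiscale Hessian eigenvalue (Frangi-type) vesselness for 2D MIPs.
# Bright-on-dark polarity: a tubular pixel has one eigenvalue near zero
# (along the vessel) and one strongly negative (across it).

# 1D convolution along rows (axis 1) or columns (axis 2), replicate border
.conv1d <- function(m, k, axis) {
  n <- if (axis == 1) nrow(m) else ncol(m)
  half <- (length(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (t - 1 - half), 1), n)
    out <- out + k[t] * (if (axis == 1) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

# gaussian and derivative kernels at scale sigma
.gauss_kernels <- function(sigma) {
  half <- max(ceiling(3 * sigma), 2)
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  # enforce the vanishing zeroth moment of the truncated kernel so a
  # constant image has an exactly zero Hessian response
  g2 <- g2 - mean(g2)
  list(g = g, g1 = -x / sigma^2 * g, g2 = g2)
}

#' Vesselness filter parameters
#'
#' @param scales Gaussian scales (sigma, pixels), strictly increasing.
#' @param beta Ridge-anisotropy sensitivity (default 0.5).
#' @param c Structureness sensitivity; `NULL` (default) uses half the
#'   maximum Hessian Frobenius norm of the image, per scale.
#' @return A `vesselness_params` list.
#' @export
vesselness_params <- function(scales = 1:6, beta = 0.5, c = NULL) {
  scales <- as.numeric(scales)
  if (length(scales) < 1 || any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("vesselness_params: scales must be strictly positive and increasing",
         call. = FALSE)
  }
  if (beta <= 0) stop("vesselness_params: beta must be > 0", call. = FALSE)
  if (!is.null(c) && c <= 0) stop("vesselness_params: c must be > 0", call. = FALSE)
  structure(list(scales = scales, beta = beta, c = c),
            class = "vesselness_params")
}

#' Multiscale Hessian vesselness of a MIP image
#'
#' Per scale sigma: the image is convolved with Gaussian-derivative kernels
#' to obtain the scale-normalized Hessian (gamma = 2, i.e. multiplied by
#' sigma^2); its eigenvalues `|lambda1| <= |lambda2|` give the Frangi
#' response `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with
#' `R_B = lambda1/lambda2` and `S = sqrt(lambda1^2 + lambda2^2)`, set to 0
#' where `lambda2 > 0` (dark-on-bright). The final map takes the maximum
#' over scales.
#'
#' @param mip A [mip_image] or numeric matrix, at least 7 x 7, all finite.
#' @param params A [vesselness_params].
#' @return A `vesselness_map` list: `values` in `[0, 1]`, `scales_used`,
#'   `best_scale` (argmax sigma per pixel).
#' @export
hessian_vesselness <- function(mip, params = vesselness_params()) {
  px <- if (inherits(mip, "mip_image")) mip$pixels else as.matrix(mip)
  if (!all(is.finite(px))) stop("hessian_vesselness: non-finite pixels", call. = FALSE)
  if (nrow(px) < 7 || ncol(px) < 7) {
    stop("hessian_vesselness: image must be at least 7 x 7", call. = FALSE)
  }
  best <- matrix(0, nrow(px), ncol(px))
  best_scale <- matrix(params$scales[1], nrow(px), ncol(px))
  for (s in params$scales) {
    k <- .gauss_kernels(s)
    # axis 1 = rows (y), axis 2 = columns (x)
    hyy <- s^2 * .conv1d(.conv1d(px, k$g2, 1), k$g, 2)
    hxx <- s^2 * .conv1d(.conv1d(px, k$g, 1), k$g2, 2)
    hxy <- s^2 * .conv1d(.conv1d(px, k$g1, 1), k$g1, 2)
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)   # |l1| <= |l2|
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    smax <- sqrt(max(S2))
    # an (essentially) flat image at this scale: only roundoff remains, and
    # normalizing c by it would amplify noise into spurious responses
    if (smax <= 1e-8 * max(1, max(abs(px)))) next
    cc <- if (is.null(params$c)) smax / 2 else params$c
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 > 0] <- 0
    upd <- v > best
    best[upd] <- v[upd]
    best_scale[upd] <- s
  }
  structure(list(values = best, scales_used = params$scales,
                 best_scale = best_scale),
            class = "vesselness_map")
}
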