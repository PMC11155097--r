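# Single-level undecimated 2D wavelet decomposition. Sub-bands keep the
# original raster so ROI masks apply unchanged.

# coiflet-1 analysis filters (low-pass sums to sqrt(2), high-pass to 0)
.coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255, 0.337897662457809, -0.072732619512854)
.coif1_hi <- c(-0.072732619512854, -0.337897662457809, 0.852572020212255,
               -0.384864846864203, -0.072732619512854, 0.015655728135465)
.haar_lo <- c(1, 1) / sqrt(2)
.haar_hi <- c(1, -1) / sqrt(2)

# circular convolution of each column of `m` with kernel `k`
.circ_filter_cols <- function(m, k) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    sh <- (seq_len(n) - 1 - (t - 1)) %% n + 1
    out <- out + k[t] * m[sh, , drop = FALSE]
  }
  out
}

#' Undecimated single-level 2D wavelet decomposition
#'
#' Separable circular convolution with the analysis filter pair of the
#' chosen family, applied along rows and columns without downsampling.
#' Sub-band naming follows the (row-axis filter, column-axis filter)
#' convention: `LH` is low-pass along the row axis (vertical) and high-pass
#' along the column axis (horizontal), so it responds to vertical stripes.
#'
#' @param mip A [mip_image] or numeric matrix, at least 8 x 8.
#' @param family `"coif1"` (default) or `"haar"`.
#' @return Named list of four matrices `LL`, `LH`, `HL`, `HH`, each with the
#'   input raster.
#' @export
wavelet_decompose <- function(mip, family = c("coif1", "haar")) {
  family <- match.arg(family)
  px <- if (inherits(mip, "mip_image")) mip$pixels else as.matrix(mip)
  if (nrow(px) < 8 || ncol(px) < 8) {
    stop("wavelet_decompose: image must be at least 8 x 8", call. = FALSE)
  }
  lo <- if (family == "coif1") .coif1_lo else .haar_lo
  hi <- if (family == "coif1") .coif1_hi else .haar_hi
  ax1 <- function(m, k) .circ_filter_cols(m, k)          # along row axis
  ax2 <- function(m, k) t(.circ_filter_cols(t(m), k))    # along column axis
  lo1 <- ax1(px, lo); hi1 <- ax1(px, hi)
  list(
    LL = ax2(lo1, lo),
    LH = ax2(lo1, hi),
    HL = ax2(hi1, lo),
    HH = ax2(hi1, hi)
  )
}
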