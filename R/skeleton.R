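# Morphological skeletonization (Zhang-Suen thinning) and segment-level
# vessel detection metrics.

# shift a logical matrix by (dr, dc), zero-filled
.shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param m Logical matrix (or [binary_mask]).
#' @return Logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(m) {
  if (inherits(m, "binary_mask")) m <- m$pixels
  m <- as.matrix(m) != 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .shift_mat(m, -1, 0); p3 <- .shift_mat(m, -1, 1)
      p4 <- .shift_mat(m, 0, 1);  p5 <- .shift_mat(m, 1, 1)
      p6 <- .shift_mat(m, 1, 0);  p7 <- .shift_mat(m, 1, -1)
      p8 <- .shift_mat(m, 0, -1); p9 <- .shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (sub == 1) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# split a skeleton into segments: remove branch points (more than two
# 8-neighbours), then label the 8-connected remnants
.skeleton_segments <- function(skel) {
  nb <- matrix(0L, nrow(skel), ncol(skel))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + .shift_mat(skel, dr, dc)
  }
  body <- skel & nb <= 2
  label_components(body, 8L)
}

#' Segment-level vessel detection metrics
#'
#' Both masks are skeletonized and split into segments at branch points.
#' A reference segment is counted CORRECT when at least 50% of its skeleton
#' pixels lie within 2 px of the predicted mask, otherwise MISSED; a
#' predicted segment is INCORRECT when fewer than 50% of its pixels lie
#' within 2 px of the reference mask. Correct and missed rates are
#' percentages of reference segments (they sum to 100); the incorrect rate
#' is a percentage of predicted segments.
#'
#' @param pred Predicted vessel [binary_mask] (may be empty: by convention
#'   correct 0, missed 100, incorrect 0).
#' @param reference Non-empty reference vessel [binary_mask].
#' @param match_radius Matching distance in pixels (default 2).
#' @param coverage Minimum matched fraction of a segment (default 0.5).
#' @return A one-row tibble: `correct_rate`, `incorrect_rate`,
#'   `missed_rate` (percent), `n_gt_segments`, `n_pred_segments`.
#' @export
detection_metrics <- function(pred, reference, match_radius = 2L,
                              coverage = 0.5) {
  predm <- if (inherits(pred, "binary_mask")) pred$pixels else as.matrix(pred) != 0
  refm <- if (inherits(reference, "binary_mask")) reference$pixels else as.matrix(reference) != 0
  check_same_raster(predm, refm, "detection_metrics: masks")
  if (!any(refm)) stop("detection_metrics: empty reference mask", call. = FALSE)

  ref_seg <- .skeleton_segments(skeletonize(refm))
  n_gt <- max(ref_seg)
  if (n_gt == 0) stop("detection_metrics: reference skeleton has no segments",
                      call. = FALSE)
  if (!any(predm)) {
    return(tibble::tibble(correct_rate = 0, incorrect_rate = 0,
                          missed_rate = 100, n_gt_segments = n_gt,
                          n_pred_segments = 0L))
  }
  brush <- .disc_brush(as.integer(match_radius))
  near_pred <- as.matrix(EBImage::dilate(predm * 1, brush)) > 0
  near_ref <- as.matrix(EBImage::dilate(refm * 1, brush)) > 0

  seg_cov <- function(seg_lab, near) {
    n <- max(seg_lab)
    tot <- tabulate(seg_lab[seg_lab > 0], nbins = n)
    hit <- tabulate(seg_lab[seg_lab > 0 & near], nbins = n)
    hit / tot
  }
  cov_ref <- seg_cov(ref_seg, near_pred)
  n_correct <- sum(cov_ref >= coverage)

  pred_seg <- .skeleton_segments(skeletonize(predm))
  n_pred <- max(pred_seg)
  n_incorrect <- if (n_pred > 0) sum(seg_cov(pred_seg, near_ref) < coverage) else 0L

  tibble::tibble(
    correct_rate = 100 * n_correct / n_gt,
    incorrect_rate = if (n_pred > 0) 100 * n_incorrect / n_pred else 0,
    missed_rate = 100 * (n_gt - n_correct) / n_gt,
    n_gt_segments = n_gt,
    n_pred_segments = n_pred
  )
}
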