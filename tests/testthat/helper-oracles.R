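# Independent brute-force oracles used to cross-check the compiled texture
# counting and the rank-based AUC. Everything here is written as plain
# double loops over pixels -- slow but unambiguous.

# symmetric co-occurrence counts for one (dr, dc) offset
oracle_glcm <- function(levels, n_levels, dr, dc) {
  H <- nrow(levels); W <- ncol(levels)
  M <- matrix(0, n_levels, n_levels)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    a <- levels[r, c]
    if (a == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
    b <- levels[r2, c2]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# run-length counts for one direction
oracle_glrlm <- function(levels, n_levels, dr, dc) {
  H <- nrow(levels); W <- ncol(levels)
  maxlen <- max(H, W)
  M <- matrix(0, n_levels, maxlen)
  inb <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W
  for (r in seq_len(H)) for (c in seq_len(W)) {
    a <- levels[r, c]
    if (a == 0) next
    # only count runs at their start (no same-level predecessor)
    pr <- r - dr; pc <- c - dc
    if (inb(pr, pc) && levels[pr, pc] == a) next
    len <- 1
    nr <- r + dr; nc <- c + dc
    while (inb(nr, nc) && levels[nr, nc] == a) {
      len <- len + 1
      nr <- nr + dr; nc <- nc + dc
    }
    M[a, len] <- M[a, len] + 1
  }
  M[, seq_len(max(1, max(which(colSums(M) > 0), 1))), drop = FALSE]
}

# 8-connected equal-level zones -> (level, zone size) counts
oracle_glszm <- function(levels, n_levels) {
  H <- nrow(levels); W <- ncol(levels)
  seen <- matrix(FALSE, H, W)
  zones <- list()
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (seen[r, c] || levels[r, c] == 0) next
    a <- levels[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
        if (!seen[r2, c2] && levels[r2, c2] == a) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  maxsize <- max(vapply(zones, `[`, numeric(1), 2))
  M <- matrix(0, n_levels, maxsize)
  for (z in zones) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

# dependence counts: column j holds 0-based dependence d = j - 1
oracle_gldm <- function(levels, n_levels, alpha = 0, delta = 1) {
  H <- nrow(levels); W <- ncol(levels)
  counts <- matrix(0, n_levels, (2 * delta + 1)^2)
  maxd <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    a <- levels[r, c]
    if (a == 0) next
    d <- 0
    for (dr in -delta:delta) for (dc in -delta:delta) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      b <- levels[r2, c2]
      if (b > 0 && abs(b - a) <= alpha) d <- d + 1
    }
    counts[a, d + 1] <- counts[a, d + 1] + 1
    maxd <- max(maxd, d)
  }
  counts[, seq_len(maxd + 1), drop = FALSE]
}

# AUC by explicit positive/negative pair counting with half tie credit
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# random discretized test image: values 0 (out of mask) .. n_levels
random_level_image <- function(h = 8, w = 8, n_levels = 4, p_mask = 0.8) {
  lv <- matrix(sample(0:n_levels, h * w, replace = TRUE,
                      prob = c(1 - p_mask, rep(p_mask / n_levels, n_levels))),
               h, w)
  if (all(lv == 0)) lv[1, 1] <- 1L
  lv
}

as_gray_level <- function(lv) {
  structure(list(levels = lv, n_levels = max(lv), bin_width = 1),
            class = "gray_level_image")
}

# pad a (level x size) matrix with zero columns up to `ncols`
pad_cols <- function(M, ncols) {
  if (ncol(M) < ncols) M <- cbind(M, matrix(0, nrow(M), ncols - ncol(M)))
  M
}
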