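# Synthetic MIP phantoms: a breast-shaped enhancing region, a heterogeneous
# tumor blob and a branching vessel tree with ground-truth masks, plus
# labelled cohorts whose classes differ through vessel-intensity and
# tumor-texture heterogeneity. Everything is driven by one integer seed.

#' Phantom generation parameters
#'
#' @param image_size `(H, W)` in pixels; both at least 64.
#' @param vessel_count Number of peritumoral vessel trees.
#' @param vessel_width_range Tube widths in pixels, drawn per segment.
#' @param tumor_radius_range Tumor ellipse radii in pixels.
#' @param background_noise_sd SD of the acquisition noise floor (intensity
#'   units).
#' @param class_effect Separation strength (>= 0). For the non-responder
#'   class (label 0) the along-vessel intensity modulation amplitude and the
#'   intratumoral texture amplitude are multiplied by `1 + class_effect`;
#'   at 0 the two classes are identical in law.
#' @param seed Integer seed; fully determines the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(256, 256),
                         vessel_count = 8,
                         vessel_width_range = c(1, 4),
                         tumor_radius_range = c(12, 20),
                         background_noise_sd = 2,
                         class_effect = 0,
                         seed = 1L) {
  if (any(image_size < 64)) stop("phantom_spec: image_size must be >= 64", call. = FALSE)
  if (vessel_width_range[1] < 1) stop("phantom_spec: vessel widths must be >= 1", call. = FALSE)
  if (class_effect < 0) stop("phantom_spec: class_effect must be >= 0", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    vessel_count = as.integer(vessel_count),
    vessel_width_range = as.numeric(vessel_width_range),
    tumor_radius_range = as.numeric(tumor_radius_range),
    background_noise_sd = background_noise_sd,
    class_effect = class_effect,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Intensity scales of the phantom (arbitrary units, chosen so that the
# default discretization bin width of 25 resolves the injected texture).
.phantom_levels <- list(
  breast_base = 80, bpe_sd = 8,
  tumor_base = 180, tumor_tex_sd = 8,
  vessel_base = 220, vessel_mod_sd = 8
)

# smooth 2D gaussian noise field
.smooth_noise <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  as.matrix(EBImage::gblur(z, sigma = sigma))
}

# rasterize a quadratic Bezier tube; returns logical mask of stamped pixels
.stamp_tube <- function(mask_dim, p0, p1, p2, width) {
  t <- seq(0, 1, length.out = 4 * ceiling(sqrt(sum((p2 - p0)^2)) + 4))
  xy <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  r <- max(width / 2, 0.5)
  out <- matrix(FALSE, mask_dim[1], mask_dim[2])
  ir <- ceiling(r)
  offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 + 0.25, ]
  rows <- round(rep(xy[, 1], each = nrow(offs)) + offs$dr)
  cols <- round(rep(xy[, 2], each = nrow(offs)) + offs$dc)
  keep <- rows >= 1 & rows <= mask_dim[1] & cols >= 1 & cols <= mask_dim[2]
  out[cbind(rows[keep], cols[keep])] <- TRUE
  out
}

#' Generate one synthetic MIP phantom
#'
#' Builds a half-ellipse breast with low-amplitude smoothed background
#' enhancement, an irregular heterogeneous tumor blob in one lateral half,
#' and `vessel_count` branching vessel trees around the tumor, then returns
#' the image together with ground-truth breast/tumor/vessel masks. When
#' `label = 0` the vessel intensity modulation and intratumoral texture are
#' amplified by `1 + class_effect` (see [phantom_spec]).
#'
#' @param spec A [phantom_spec].
#' @param label Binary outcome; 1 is the responder (pCR) analogue.
#' @return A `phantom` list: `image` ([mip_image]), `tumor_mask_gt`,
#'   `vessel_mask_gt`, `breast_mask_gt` ([binary_mask]s) and `label`.
#' @export
generate_phantom <- function(spec, label = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), label %in% c(0L, 1L))
  withr::with_seed(spec$seed, .generate_phantom_impl(spec, as.integer(label)))
}

.generate_phantom_impl <- function(spec, label) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  lv <- .phantom_levels
  amp <- 1 + spec$class_effect * (1 - label)

  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))

  # breast: half-ellipse anchored at the bottom edge
  breast <- ((rr - H) / (0.92 * H))^2 + ((cc - W / 2) / (0.46 * W))^2 <= 1

  img <- matrix(0, H, W)
  img[breast] <- lv$breast_base
  img <- img + .smooth_noise(H, W, sigma = 8) * lv$bpe_sd * breast

  # tumor: irregular ellipse in one lateral half, inside the breast
  side <- sample(c(-1, 1), 1)
  rad <- runif(2, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
  ctr <- c(H - round(0.45 * H) + sample(-10:10, 1),
           W / 2 + side * round(0.22 * W) + sample(-8:8, 1))
  ang <- atan2(rr - ctr[1], cc - ctr[2])
  wob <- 1 + 0.18 * sin(3 * ang + runif(1, 0, 2 * pi)) +
             0.12 * sin(5 * ang + runif(1, 0, 2 * pi))
  tumor <- (((rr - ctr[1]) / rad[1])^2 + ((cc - ctr[2]) / rad[2])^2) <= wob^2
  tumor <- tumor & breast
  tumor_tex <- .smooth_noise(H, W, sigma = 1.5) * lv$tumor_tex_sd * amp
  img[tumor] <- lv$tumor_base + tumor_tex[tumor]

  # vessels: branching quadratic Bezier tubes around the tumor, same side
  vessel <- matrix(FALSE, H, W)
  vmod_field <- .smooth_noise(H, W, sigma = 3) * lv$vessel_mod_sd * amp
  n_placed <- 0
  tries <- 0
  while (n_placed < spec$vessel_count) {
    tries <- tries + 1
    if (tries > 60 * max(spec$vessel_count, 1)) {
      stop("generate_phantom: vessel placement failed after bounded retries",
           call. = FALSE)
    }
    theta <- runif(1, 0, 2 * pi)
    d0 <- runif(1, max(rad) + 6, max(rad) + 45)
    p0 <- ctr + d0 * c(sin(theta), cos(theta))
    dir <- runif(1, 0, 2 * pi)
    len <- runif(1, 35, 75)
    p2 <- p0 + len * c(sin(dir), cos(dir))
    p1 <- (p0 + p2) / 2 + runif(2, -18, 18)
    w0 <- runif(1, spec$vessel_width_range[1], spec$vessel_width_range[2])
    tube <- .stamp_tube(c(H, W), p0, p1, p2, w0) & breast & !tumor
    if (sum(tube) < 25) next
    # 1-3 branches off the parent
    for (b in seq_len(sample(1:3, 1))) {
      tb <- runif(1, 0.25, 0.85)
      q0 <- (1 - tb)^2 * p0 + 2 * tb * (1 - tb) * p1 + tb^2 * p2
      bd <- dir + runif(1, -1.2, 1.2)
      bl <- runif(1, 15, 40)
      q2 <- q0 + bl * c(sin(bd), cos(bd))
      q1 <- (q0 + q2) / 2 + runif(2, -8, 8)
      wb <- runif(1, spec$vessel_width_range[1], spec$vessel_width_range[2])
      tube <- tube | (.stamp_tube(c(H, W), q0, q1, q2, wb) & breast & !tumor)
    }
    vessel <- vessel | tube
    n_placed <- n_placed + 1
  }
  img[vessel] <- lv$vessel_base + vmod_field[vessel]

  img <- img + matrix(rnorm(H * W, sd = spec$background_noise_sd), H, W)
  img <- pmax(img, 0)

  cid <- sprintf("phantom_seed%d", spec$seed)
  list(
    image = mip_image(img, case_id = cid),
    tumor_mask_gt = binary_mask(tumor, role = "tumor", case_id = cid),
    vessel_mask_gt = binary_mask(vessel, role = "vessel", case_id = cid),
    breast_mask_gt = binary_mask(breast, role = "breast", case_id = cid),
    label = label
  )
}

#' Generate a labelled phantom cohort
#'
#' The number of positive (pCR-analogue) labels is exactly
#' `round(n * prevalence)`; per-case seeds are derived deterministically
#' from `spec$seed`, so two calls with the same arguments are identical.
#'
#' @param n Number of cases (>= 2).
#' @param prevalence Positive-label fraction in (0, 1); the default mirrors
#'   the 35.5% pCR rate typical of TNBC NAC cohorts.
#' @param spec A [phantom_spec]; its `seed` drives the whole cohort.
#' @param cohort Cohort tag stored in the table (`"train"` or `"validation"`).
#' @return A list with `phantoms` (list of phantom objects) and `table`
#'   (tibble: `case_id`, `label`, `cohort`).
#' @export
generate_cohort <- function(n, prevalence = 0.355, spec = phantom_spec(),
                            cohort = c("train", "validation")) {
  cohort <- match.arg(cohort)
  if (n < 2) stop("generate_cohort: n must be >= 2", call. = FALSE)
  n_pos <- round(n * prevalence)
  if (n_pos <= 0 || n_pos >= n) {
    stop("generate_cohort: prevalence rounds to an empty class", call. = FALSE)
  }
  draws <- withr::with_seed(spec$seed, list(
    labels = sample(rep(c(1L, 0L), c(n_pos, n - n_pos))),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  phantoms <- purrr::map(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- draws$seeds[i]
    ph <- generate_phantom(sp, draws$labels[i])
    cid <- sprintf("%s_%03d", cohort, i)
    ph$image$case_id <- cid
    ph$tumor_mask_gt$case_id <- cid
    ph$vessel_mask_gt$case_id <- cid
    ph$breast_mask_gt$case_id <- cid
    ph
  })
  tab <- tibble::tibble(
    case_id = sprintf("%s_%03d", cohort, seq_len(n)),
    label = draws$labels,
    cohort = cohort
  )
  list(phantoms = phantoms, table = tab)
}

#' Degrade a ground-truth vessel mask in a controlled way
#'
#' Removes `round(miss_fraction * n_components)` whole connected components
#' and adds `spurious_count` short tubes outside the ground truth, producing
#' inputs with designed correct/missed/incorrect detection rates.
#'
#' @param gt Ground-truth vessel [binary_mask].
#' @param miss_fraction Fraction of components to delete, in `[0, 1]`.
#' @param spurious_count Number of spurious short tubes to add.
#' @param seed Integer seed.
#' @return A degraded [binary_mask] with role `"vessel"`.
#' @export
degrade_vessel_mask <- function(gt, miss_fraction = 0, spurious_count = 0,
                                seed = 1L) {
  stopifnot(inherits(gt, "binary_mask"), miss_fraction >= 0, miss_fraction <= 1)
  withr::with_seed(seed, {
    lab <- label_components(gt$pixels, connectivity = 8L)
    ncomp <- max(lab)
    out <- gt$pixels
    n_drop <- round(miss_fraction * ncomp)
    if (n_drop > 0) {
      drop <- sample.int(ncomp, n_drop)
      out[lab %in% drop] <- FALSE
    }
    dil <- if (any(gt$pixels)) {
      as.matrix(EBImage::dilate(gt$pixels * 1,
                                EBImage::makeBrush(9, "disc"))) > 0
    } else gt$pixels
    placed <- 0; tries <- 0
    H <- nrow(out); W <- ncol(out)
    while (placed < spurious_count) {
      tries <- tries + 1
      if (tries > 200 * max(spurious_count, 1)) {
        stop("degrade_vessel_mask: spurious tube placement failed", call. = FALSE)
      }
      p0 <- c(runif(1, 5, H - 5), runif(1, 5, W - 5))
      dir <- runif(1, 0, 2 * pi)
      p2 <- p0 + runif(1, 12, 25) * c(sin(dir), cos(dir))
      p1 <- (p0 + p2) / 2 + runif(2, -4, 4)
      tube <- .stamp_tube(c(H, W), p0, p1, p2, runif(1, 1, 2))
      if (!any(tube) || any(tube & dil)) next
      out <- out | tube
      placed <- placed + 1
    }
    binary_mask(out, role = "vessel", case_id = gt$case_id)
  })
}
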