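# End-to-end orchestration: simulate -> segment -> extract -> select ->
# score -> fuse -> evaluate, plus the file-based runner driven by a YAML
# config.

.derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# segmentation + feature extraction for one phantom case
.process_case <- function(ph, params, threshold, min_size, bin_width,
                          gldm_alpha, gldm_delta, wavelet_family,
                          use_ground_truth_masks = FALSE) {
  if (use_ground_truth_masks) {
    vessel <- ph$vessel_mask_gt
    tumor <- ph$tumor_mask_gt
    det <- NULL
  } else {
    seg <- segment_vessels(ph$image, ph$tumor_mask_gt, params, threshold,
                           min_size)
    vessel <- seg$vessel
    tumor <- seg$tumor
    if (!any(vessel$pixels)) {
      # analogue of the radiologist painting in missed vessels: fall back
      # to the reference mask when the algorithm finds nothing
      warning(sprintf("case %s: empty algorithmic vessel mask; using the reference mask",
                      ph$image$case_id))
      vessel <- ph$vessel_mask_gt
    }
    det <- detection_metrics(vessel, ph$vessel_mask_gt)
    det$case_id <- ph$image$case_id
  }
  tumor_fv <- extract_feature_vector(ph$image, tumor, "tumor", bin_width,
                                     gldm_alpha, gldm_delta, wavelet_family)
  vessel_fv <- extract_feature_vector(ph$image, vessel, "vessel", bin_width,
                                      gldm_alpha, gldm_delta, wavelet_family)
  to_row <- function(fv, cid) {
    tibble::as_tibble_row(stats::setNames(as.list(fv$value), fv$feature)) |>
      dplyr::mutate(case_id = cid, .before = 1)
  }
  list(tumor = to_row(tumor_fv, ph$image$case_id),
       vessel = to_row(vessel_fv, ph$image$case_id),
       detection = det, vessel_mask = vessel, tumor_mask = tumor)
}

#' Run the full synthetic study
#'
#' Generates training and validation phantom cohorts, segments peritumoral
#' vessels, extracts tumor (455) and vessel (99) feature vectors, scales
#' features to `[0, 1]` on the training rows, selects `n_target` features
#' per source by LASSO-RFE, scores cases with k-NN (k = 5), fuses tumor and
#' vessel scores over the min/max/weighted grid and evaluates AUCs with
#' DeLong intervals.
#'
#' @param n_train,n_val Cohort sizes.
#' @param prevalence Positive fraction (default 0.355).
#' @param class_effect Injected class separation (see [phantom_spec]);
#'   0 gives a null study.
#' @param seed Master seed; all randomness derives from it.
#' @param image_size,vessel_count Passed to [phantom_spec()].
#' @param params [vesselness_params()].
#' @param n_target Features retained per source by RFE.
#' @param rfe_step Features eliminated per RFE iteration (default 1).
#' @param k k-NN neighbours.
#' @param bin_width,gldm_alpha,gldm_delta,wavelet_family Radiomics settings.
#' @param use_ground_truth_masks Skip algorithmic segmentation and use the
#'   phantom ground truth (for ablation).
#' @return A list: `cohort` (case table), `detection` (per-case rates),
#'   `selection` (per source), `scores` (tumor/vessel per cohort),
#'   `fusion_grid` (per cohort), `auc` (summary tibble), `comparisons`
#'   (paired DeLong tests on the validation cohort).
#' @export
run_synthetic_study <- function(n_train = 120, n_val = 120,
                                prevalence = 0.355, class_effect = 2,
                                seed = 1L,
                                image_size = c(256, 256), vessel_count = 8,
                                params = vesselness_params(),
                                n_target = 10L, rfe_step = 1L, k = 5L,
                                bin_width = 25, gldm_alpha = 0L,
                                gldm_delta = 1L, wavelet_family = "coif1",
                                use_ground_truth_masks = FALSE) {
  seeds <- .derive_seeds(seed, 3L)
  spec_tr <- phantom_spec(image_size = image_size, vessel_count = vessel_count,
                          class_effect = class_effect, seed = seeds[1])
  spec_va <- phantom_spec(image_size = image_size, vessel_count = vessel_count,
                          class_effect = class_effect, seed = seeds[2])
  tr <- generate_cohort(n_train, prevalence, spec_tr, cohort = "train")
  va <- generate_cohort(n_val, prevalence, spec_va, cohort = "validation")

  proc <- function(cohort) {
    purrr::map(cohort$phantoms, .process_case, params = params,
               threshold = NULL, min_size = 20L, bin_width = bin_width,
               gldm_alpha = gldm_alpha, gldm_delta = gldm_delta,
               wavelet_family = wavelet_family,
               use_ground_truth_masks = use_ground_truth_masks)
  }
  ptr <- proc(tr)
  pva <- proc(va)

  feats <- function(pl, what) dplyr::bind_rows(purrr::map(pl, what))
  detection <- dplyr::bind_rows(purrr::map(c(ptr, pva), "detection"))

  cohort <- dplyr::bind_rows(tr$table, va$table)
  out_scores <- list()
  selection <- list()
  features <- list()
  for (src in c("tumor", "vessel")) {
    Xtr <- feats(ptr, src)
    Xva <- feats(pva, src)
    features[[src]] <- dplyr::bind_rows(Xtr, Xva)
    scaler <- fit_minmax(Xtr)
    Xtr_s <- apply_minmax(scaler, Xtr)
    Xva_s <- apply_minmax(scaler, Xva)
    sel <- select_features_lasso_rfe(Xtr_s, tr$table$label, n_target,
                                     step = rfe_step, seed = seeds[3])
    selection[[src]] <- sel
    keep <- c("case_id", sel$selected)
    model <- fit_knn(Xtr_s[keep], tr$table$label, k = k)
    strain <- predict_scores(model, dplyr::mutate(Xtr_s[keep],
                                                  label = tr$table$label),
                             source = src)
    sval <- predict_scores(model, dplyr::mutate(Xva_s[keep],
                                                label = va$table$label),
                           source = src)
    out_scores[[src]] <- list(train = strain, validation = sval)
  }

  grids <- list(
    train = fusion_weight_grid(out_scores$tumor$train,
                               out_scores$vessel$train),
    validation = fusion_weight_grid(out_scores$tumor$validation,
                                    out_scores$vessel$validation)
  )
  # fused validation scores at the rule that is best on the training cohort
  best_tr <- grids$train[grids$train$best, ]
  fused_val <- if (best_tr$rule == "weighted") {
    fuse_scores(out_scores$tumor$validation, out_scores$vessel$validation,
                "weighted", best_tr$w)
  } else {
    fuse_scores(out_scores$tumor$validation, out_scores$vessel$validation,
                best_tr$rule)
  }
  auc_rows <- purrr::map(c("train", "validation"), function(coh) {
    dplyr::bind_rows(
      dplyr::mutate(delong_ci(out_scores$tumor[[coh]]), model = "tumor"),
      dplyr::mutate(delong_ci(out_scores$vessel[[coh]]), model = "vessel"),
      dplyr::mutate(
        delong_ci(if (coh == "validation") fused_val else {
          if (best_tr$rule == "weighted") {
            fuse_scores(out_scores$tumor[[coh]], out_scores$vessel[[coh]],
                        "weighted", best_tr$w)
          } else {
            fuse_scores(out_scores$tumor[[coh]], out_scores$vessel[[coh]],
                        best_tr$rule)
          }
        }), model = "fused")
    ) |> dplyr::mutate(cohort = coh)
  }) |> dplyr::bind_rows()

  comparisons <- dplyr::bind_rows(
    dplyr::mutate(delong_test(fused_val, out_scores$tumor$validation),
                  comparison = "fused_vs_tumor"),
    dplyr::mutate(delong_test(fused_val, out_scores$vessel$validation),
                  comparison = "fused_vs_vessel")
  )

  list(cohort = cohort, detection = detection, selection = selection,
       features = features,
       scores = out_scores, fused_validation = fused_val,
       fusion_grid = grids, auc = auc_rows, comparisons = comparisons,
       fusion_rule = best_tr)
}

.default_config <- list(
  mode = "synthetic",
  out_dir = "mipvasc_run",
  seed = 1L,
  n_train = 120L, n_val = 120L,
  prevalence = 0.355, class_effect = 2,
  image_size = c(256L, 256L), vessel_count = 8L,
  vesselness = list(scales = 1:6, beta = 0.5, c = NULL, threshold = NULL,
                    min_size = 20L, match_radius = 2L),
  radiomics = list(bin_width = 25, gldm_alpha = 0L, gldm_delta = 1L,
                   wavelet_family = "coif1"),
  modeling = list(k = 5L, n_target = 10L, rfe_step = 1L),
  paths = list(mips = NULL, tumor_masks = NULL, cohort = NULL)
)

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON-as-YAML) config, applies defaults, rejects unknown
#' keys and checks value constraints.
#'
#' @param path Config file path, or a named list.
#' @return The validated config list with all defaults filled in.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  merge_known <- function(defaults, given, prefix = "") {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      stop("validate_config: unknown key(s): ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(given)) {
      if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
        defaults[[nm]] <- merge_known(defaults[[nm]], given[[nm]],
                                      paste0(prefix, nm, "."))
      } else {
        defaults[[nm]] <- given[[nm]]
      }
    }
    defaults
  }
  out <- merge_known(.default_config, cfg)
  if (!out$mode %in% c("synthetic", "real")) {
    stop("validate_config: mode must be 'synthetic' or 'real'", call. = FALSE)
  }
  if (out$modeling$k < 1) stop("validate_config: k must be >= 1", call. = FALSE)
  sc <- out$vesselness$scales
  if (length(sc) < 1 || any(sc <= 0) || is.unsorted(sc, strictly = TRUE)) {
    stop("validate_config: vesselness scales must be strictly increasing",
         call. = FALSE)
  }
  if (out$mode == "real" &&
      (is.null(out$paths$mips) || is.null(out$paths$tumor_masks) ||
       is.null(out$paths$cohort))) {
    stop("validate_config: real-data mode needs paths$mips, paths$tumor_masks and paths$cohort",
         call. = FALSE)
  }
  out
}

#' Run the pipeline from a config and write all stage outputs
#'
#' Synthetic mode simulates the cohorts and runs the full study; outputs
#' (vessel masks, feature tables, model description, score tables, metric
#' tables and a JSON-lines run log) are written as plain files under
#' `out_dir` so edited vessel masks can be swapped in between stages.
#'
#' @param config Path to a YAML config or a config list; see
#'   [validate_config()].
#' @return The output directory, invisibly; its contents are the declared
#'   artifacts (`cohort.csv`, `features_tumor.csv`, `features_vessel.csv`,
#'   `scores.csv`, `detection_metrics.csv`, `auc_summary.csv`,
#'   `fusion_grid.csv`, `run_log.jsonl`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (cfg$mode != "synthetic") {
    stop("run_pipeline: only synthetic mode is executed by this runner; ",
         "use the stage functions directly for patient data", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.jsonl")
  log_line <- function(...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    cat(paste0("{", paste(sprintf('"%s":"%s"', names(rec),
                                  vapply(rec, paste, character(1),
                                         collapse = ",")),
                          collapse = ","), "}\n"),
        file = log_path, append = TRUE)
  }
  log_line(event = "start", seed = cfg$seed,
           n_train = cfg$n_train, n_val = cfg$n_val,
           class_effect = cfg$class_effect)
  res <- run_synthetic_study(
    n_train = cfg$n_train, n_val = cfg$n_val, prevalence = cfg$prevalence,
    class_effect = cfg$class_effect, seed = cfg$seed,
    image_size = cfg$image_size, vessel_count = cfg$vessel_count,
    params = vesselness_params(cfg$vesselness$scales, cfg$vesselness$beta,
                               cfg$vesselness$c),
    n_target = cfg$modeling$n_target, rfe_step = cfg$modeling$rfe_step,
    k = cfg$modeling$k,
    bin_width = cfg$radiomics$bin_width,
    gldm_alpha = cfg$radiomics$gldm_alpha,
    gldm_delta = cfg$radiomics$gldm_delta,
    wavelet_family = cfg$radiomics$wavelet_family
  )
  utils::write.csv(res$cohort, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(res$features$tumor,
                   file.path(cfg$out_dir, "features_tumor.csv"),
                   row.names = FALSE)
  utils::write.csv(res$features$vessel,
                   file.path(cfg$out_dir, "features_vessel.csv"),
                   row.names = FALSE)
  scores <- dplyr::bind_rows(
    dplyr::mutate(res$scores$tumor$train, cohort = "train"),
    dplyr::mutate(res$scores$tumor$validation, cohort = "validation"),
    dplyr::mutate(res$scores$vessel$train, cohort = "train"),
    dplyr::mutate(res$scores$vessel$validation, cohort = "validation"),
    dplyr::mutate(res$fused_validation, cohort = "validation")
  )
  utils::write.csv(scores, file.path(cfg$out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$detection,
                   file.path(cfg$out_dir, "detection_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(res$auc, file.path(cfg$out_dir, "auc_summary.csv"),
                   row.names = FALSE)
  grid <- dplyr::bind_rows(
    dplyr::mutate(res$fusion_grid$train, cohort = "train"),
    dplyr::mutate(res$fusion_grid$validation, cohort = "validation"))
  utils::write.csv(grid, file.path(cfg$out_dir, "fusion_grid.csv"),
                   row.names = FALSE)
  sel <- dplyr::bind_rows(
    dplyr::mutate(tidy(res$selection$tumor), source = "tumor"),
    dplyr::mutate(tidy(res$selection$vessel), source = "vessel"))
  utils::write.csv(sel, file.path(cfg$out_dir, "selected_features.csv"),
                   row.names = FALSE)
  log_line(event = "done",
           fused_val_auc = sprintf("%.4f",
                                   res$auc$auc[res$auc$model == "fused" &
                                               res$auc$cohort == "validation"]))
  invisible(cfg$out_dir)
}
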