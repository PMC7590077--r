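# Model training / prediction surface that binds the modules together:
# fit the screening model on a labelled library, then predict verdicts for
# new scans (the deployment path, as opposed to the cross-validation path
# in loso_cross_validate()).

#' Preprocess raw scans outside a library
#'
#' Applies the same SNV -> Savitzky-Golay derivative -> ROI chain as
#' [preprocess_library()] to a bare `nir_scans` object (e.g. incoming query
#' scans that have no metadata yet).
#'
#' @param scans A `nir_scans` object.
#' @param config A [preprocess_config()].
#' @return List with `matrix` (preprocessed values), `meta`, `wavelengths`
#'   and `preprocess_tag`.
#' @export
preprocess_scans <- function(scans, config = preprocess_config()) {
  stopifnot(inherits(scans, "nir_scans"))
  snv_mat <- snv(scans$values, sd_type = config$snv_sd)
  step <- scans$grid$step_nm
  deriv <- savgol_derivative(snv_mat, config, step_nm = step)
  wl <- interior_wavelengths(scans$grid$wavelengths, config)
  out <- select_roi(deriv, wl, config)
  wl_out <- select_roi(wl, wl, config)
  colnames(out) <- wavelength_colnames(list(wavelengths = wl_out))
  list(matrix = out, meta = scans$meta, wavelengths = wl_out,
       preprocess_tag = preprocess_tag(config))
}

#' Fit the full screening model
#'
#' Trains the complete multistage model on a labelled library: preprocesses
#' the spectra, flags outlying replicate scans (excluded from all training
#' sets), retains the non-outlier preprocessed library for kNN matching, and
#' fits the gated form classifier plus both per-form bagged-tree
#' concentration regressors on the cocaine scans.
#'
#' @param library A raw `nir_library` from [build_library()].
#' @param preprocess A [preprocess_config()].
#' @param outlier An [outlier_config()].
#' @param knn A [knn_config()].
#' @param ann An [ann_config()].
#' @param decision A [decision_config()].
#' @param B,min_leaf Bagged-tree hyperparameters.
#' @param seed Integer seed for all model fits.
#' @return An object of class `screening_model`.
#' @export
fit_screening_model <- function(library,
                                preprocess = preprocess_config(),
                                outlier = outlier_config(),
                                knn = knn_config(),
                                ann = ann_config(),
                                decision = decision_config(),
                                B = 25, min_leaf = 5, seed = 1) {
  stopifnot(inherits(library, "nir_library"))
  prep <- if (identical(library$preprocess_tag, "raw")) {
    preprocess_library(library, preprocess)
  } else library
  out_mask <- flag_outliers(prep, outlier)
  keep <- !out_mask
  lib <- prep
  lib$matrix <- prep$matrix[keep, , drop = FALSE]
  lib$scan_meta <- prep$scan_meta[keep, , drop = FALSE]
  truth <- library_scan_truth(lib)
  coc <- which(truth$cocaine_form %in% c("hcl", "base"))
  ann2 <- ann
  ann2$seed <- seed
  clf <- fit_form_classifier(lib$matrix[coc, , drop = FALSE],
                             truth$cocaine_form[coc], ann2,
                             preprocess_tag = lib$preprocess_tag)
  regressors <- list()
  for (fm in c("hcl", "base")) {
    rows <- coc[truth$cocaine_form[coc] == fm]
    regressors[[fm]] <- fit_concentration_regressor(
      lib$matrix[rows, , drop = FALSE], truth$cocaine_wt_pct[rows], form = fm,
      B = B, min_leaf = min_leaf, seed = seed,
      preprocess_tag = lib$preprocess_tag)
  }
  structure(list(library = lib, classifier = clf, regressors = regressors,
                 n_outliers_removed = sum(out_mask),
                 configs = list(preprocess = preprocess, outlier = outlier,
                                knn = knn, ann = ann2, decision = decision,
                                B = B, min_leaf = min_leaf, seed = seed)),
            class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf(paste0("<screening_model> library %d scans x %d variables (%s), ",
                     "%d outliers removed\n"),
              nrow(x$library$matrix), ncol(x$library$matrix),
              x$library$preprocess_tag, x$n_outliers_removed))
  invisible(x)
}

#' Predict verdicts for new scans
#'
#' Runs the deployment path of the model on incoming scans: preprocess, dual
#' kNN match against the model library (abstaining outside the thresholds),
#' gated form classification plus concentration regression for abstentions,
#' fusion by the decision hierarchy, and per-sample majority voting over the
#' scans sharing a `sample_id`.
#'
#' @param object A `screening_model`.
#' @param scans A `nir_scans` object on the model's wavelength grid.
#' @param ... Unused.
#' @return List of class `screening_prediction` with `scan_verdicts` and
#'   `sample_verdicts` data frames (same columns as [loso_cross_validate()]
#'   output).
#' @export
predict.screening_model <- function(object, scans, ...) {
  stopifnot(inherits(scans, "nir_scans"))
  if (!identical(scans$grid$wavelengths,
                 seq(scans$grid$start_nm, scans$grid$end_nm,
                     by = scans$grid$step_nm))) {
    stop("invalid scan grid", call. = FALSE)
  }
  prep <- preprocess_scans(scans, object$configs$preprocess)
  if (!identical(prep$preprocess_tag, object$library$preprocess_tag)) {
    stop("preprocessing mismatch between scans and model", call. = FALSE)
  }
  if (ncol(prep$matrix) != ncol(object$library$matrix)) {
    stop("scan grid does not match the model library grid", call. = FALSE)
  }
  knn_cfg <- object$configs$knn
  decision <- object$configs$decision
  pb <- predict_submodel_b(prep$matrix, object$classifier, object$regressors,
                           config = object$configs$ann,
                           preprocess_tag = prep$preprocess_tag)
  verdicts <- do.call(rbind, lapply(seq_len(nrow(prep$matrix)), function(i) {
    ns <- query_neighbors(prep$matrix[i, ], object$library, knn_cfg)
    kr <- knn_predict(ns, object$library$sample_meta)
    v <- decide_spectrum(kr, b_form = pb$form[i], b_conc = pb$predicted_conc[i],
                         config = decision)
    cbind(data.frame(scan_id = prep$meta$scan_id[i],
                     sample_id = prep$meta$sample_id[i],
                     stringsAsFactors = FALSE),
          v,
          data.frame(knn_status = kr$status, knn_conc = kr$predicted_conc,
                     b_form = pb$form[i], b_conc = pb$predicted_conc[i],
                     stringsAsFactors = FALSE))
  }))
  rownames(verdicts) <- NULL
  sample_verdicts <- do.call(rbind, lapply(split(verdicts, verdicts$sample_id),
                                           function(sv) {
    cbind(data.frame(sample_id = sv$sample_id[1], stringsAsFactors = FALSE),
          decide_sample(sv))
  }))
  rownames(sample_verdicts) <- NULL
  structure(list(scan_verdicts = verdicts, sample_verdicts = sample_verdicts),
            class = "screening_prediction")
}

#' @export
print.screening_prediction <- function(x, ...) {
  cat(sprintf("<screening_prediction> %d scans (%d positive), %d samples (%d positive)\n",
              nrow(x$scan_verdicts), sum(x$scan_verdicts$result == "positive"),
              nrow(x$sample_verdicts),
              sum(x$sample_verdicts$result == "positive")))
  invisible(x)
}

#' Run the benchmark pipeline end to end
#'
#' Convenience wrapper used by the test suite and the acceptance script:
#' generates the frozen benchmark library, runs the cross-validated
#' pipeline, and computes the standard reports (scan- and sample-level
#' confusion, kNN concentration fit, threshold curve).
#'
#' @param design A [library_design()]; default [benchmark_design()].
#' @param preprocess,outlier,knn,ann,decision,n_folds,B,min_leaf,seed
#'   Passed to [loso_cross_validate()].
#' @return List with `library`, `cv` (the [loso_cross_validate()] result),
#'   `scan_report`, `sample_report`, `knn_fit` and `curve`.
#' @export
run_benchmark <- function(design = benchmark_design(),
                          preprocess = preprocess_config(),
                          outlier = outlier_config(),
                          knn = knn_config(),
                          ann = ann_config(),
                          decision = decision_config(),
                          n_folds = 10, B = 25, min_leaf = 5, seed = 1) {
  gen <- generate_library(design)
  library <- build_library(gen$scans, gen$sample_meta)
  cv <- loso_cross_validate(library, preprocess = preprocess,
                            outlier = outlier, knn = knn, ann = ann,
                            decision = decision, n_folds = n_folds, B = B,
                            min_leaf = min_leaf, seed = seed)
  idx <- match(cv$knn$sample_id, library$sample_meta$sample_id)
  knn_fit <- concentration_fit_metrics(
    cv$knn$predicted_conc,
    library$sample_meta$cocaine_wt_pct[idx])
  list(library = library,
       corrupted = gen$corrupted,
       cv = cv,
       scan_report = confusion_report(cv$scan_verdicts, library$sample_meta,
                                      decision, level = "scan"),
       sample_report = confusion_report(cv$sample_verdicts, library$sample_meta,
                                        decision, level = "sample"),
       knn_fit = knn_fit,
       curve = threshold_curve(cv$scan_verdicts, library$sample_meta,
                               truth_config = decision))
}
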