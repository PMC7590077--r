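# Decision hierarchy at scan and sample level, cross-validation
# orchestration, confusion and concentration-fit metrics, and
# threshold sweep curves.

#' Decision configuration
#'
#' @param conc_threshold_wt_pct Cocaine weight-percent cutoff above which a
#'   scan is called positive (default 20). The comparison is strict: a
#'   predicted concentration exactly equal to the threshold is negative.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(conc_threshold_wt_pct = 20) {
  if (conc_threshold_wt_pct < 0 || conc_threshold_wt_pct > 100) {
    stop("conc_threshold_wt_pct must be in [0, 100]", call. = FALSE)
  }
  structure(list(conc_threshold_wt_pct = conc_threshold_wt_pct),
            class = "decision_config")
}

#' Decide one scan from the two submodels
#'
#' Implements the decision hierarchy: when the kNN submodel returned a
#' result, the scan is positive if and only if the kNN-predicted
#' concentration exceeds the threshold, and submodel B is ignored. When the
#' kNN submodel abstained (`no_match`), the scan is positive if and only if
#' the gated form call is `"hcl"` or `"base"` and the submodel-B predicted
#' concentration exceeds the threshold. In all other cases the scan is
#' negative.
#'
#' @param knn A `knn_result` from [knn_predict()], or a list with elements
#'   `status`, `predicted_conc`, `predicted_identity`.
#' @param b_form Gated form call from [assign_form()] (`"hcl"`, `"base"` or
#'   `"unassigned"`).
#' @param b_conc Submodel-B predicted concentration (wt%), or `NA` when
#'   unassigned.
#' @param config A [decision_config()].
#' @return A one-row data frame (`spectrum_verdict`): columns `result`
#'   (`"positive"`/`"negative"`), `decided_by` (`"knn"`/`"ann_treebag"`),
#'   `predicted_conc` and `predicted_identity`.
#' @export
decide_spectrum <- function(knn, b_form = "unassigned", b_conc = NA_real_,
                            config = decision_config()) {
  thr <- config$conc_threshold_wt_pct
  if (identical(knn$status, "ok")) {
    positive <- isTRUE(knn$predicted_conc > thr)
    return(data.frame(result = if (positive) "positive" else "negative",
                      decided_by = "knn",
                      predicted_conc = knn$predicted_conc,
                      predicted_identity = knn$predicted_identity,
                      stringsAsFactors = FALSE))
  }
  positive <- b_form %in% c("hcl", "base") && isTRUE(b_conc > thr)
  data.frame(result = if (positive) "positive" else "negative",
             decided_by = "ann_treebag",
             predicted_conc = if (b_form %in% c("hcl", "base")) b_conc else NA_real_,
             predicted_identity = NA_character_,
             stringsAsFactors = FALSE)
}

#' Majority-vote a sample verdict from its replicate scans
#'
#' The sample is positive when strictly more than half of the replicate
#' verdicts are positive; ties resolve to negative (false positives being
#' the costlier error in a screening test). The sample identity is the modal
#' kNN-predicted identity among kNN-decided scans, or `NA` when no scan had
#' one.
#'
#' @param verdicts Data frame of spectrum verdicts for one sample (columns
#'   `result`, `decided_by`, `predicted_identity`, optionally
#'   `predicted_conc`).
#' @return A one-row data frame (`sample_verdict`): columns `result`,
#'   `n_positive`, `n_negative`, `predicted_identity`.
#' @export
decide_sample <- function(verdicts) {
  if (is.null(nrow(verdicts)) || nrow(verdicts) == 0) {
    stop("decide_sample needs at least one spectrum verdict", call. = FALSE)
  }
  n_pos <- sum(verdicts$result == "positive")
  n_neg <- sum(verdicts$result == "negative")
  knn_ids <- verdicts$predicted_identity[verdicts$decided_by == "knn" &
                                           !is.na(verdicts$predicted_identity)]
  identity <- NA_character_
  if (length(knn_ids) > 0) {
    votes <- table(knn_ids)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1 && "predicted_conc" %in% names(verdicts)) {
      # tie: prefer the identity whose scans matched closest (proxy: first
      # by library order among ties after sorting)
      top <- sort(top)[1]
    } else {
      top <- top[1]
    }
    identity <- top
  }
  data.frame(result = if (n_pos > n_neg) "positive" else "negative",
             n_positive = n_pos, n_negative = n_neg,
             predicted_identity = identity, stringsAsFactors = FALSE)
}

#' Cross-validated verdicts for a whole library
#'
#' Orchestrates the full pipeline under cross-validation. Outlier-flagged
#' scans are removed from every training set (kNN library, classifier,
#' regressors) and receive no verdict. The kNN submodel is cross-validated
#' leave-one-sample-out: each scan is matched against all non-outlier scans
#' of other samples. Submodel B is cross-validated on grouped folds: for
#' each fold, the form classifier and both concentration regressors are
#' fitted on the remaining folds' cocaine scans and used to score the
#' held-out fold. Per-scan verdicts are fused by [decide_spectrum()] and
#' majority-voted per sample.
#'
#' @param library A raw `nir_library` (preprocessing is applied internally).
#' @param preprocess A [preprocess_config()].
#' @param outlier An [outlier_config()].
#' @param knn A [knn_config()].
#' @param ann An [ann_config()].
#' @param decision A [decision_config()].
#' @param n_folds Grouped folds for submodel B (default 10).
#' @param B,min_leaf Bagged-tree hyperparameters (defaults 25 and 5).
#' @param seed Integer seed driving fold assignment and all model fits.
#' @return A list of class `cv_result`: `scan_verdicts` (one row per
#'   non-outlier scan with submodel provenance and predictions),
#'   `sample_verdicts`, `knn` (raw kNN results), `submodel_b` (raw gated
#'   calls), `outliers` (logical mask over library rows) and the configs.
#' @export
loso_cross_validate <- function(library,
                                preprocess = preprocess_config(),
                                outlier = outlier_config(),
                                knn = knn_config(),
                                ann = ann_config(),
                                decision = decision_config(),
                                n_folds = 10, B = 25, min_leaf = 5,
                                seed = 1) {
  stopifnot(inherits(library, "nir_library"))
  if (nrow(library$sample_meta) < 2) {
    stop("cross-validation needs at least 2 samples", call. = FALSE)
  }
  prep <- if (identical(library$preprocess_tag, "raw")) {
    preprocess_library(library, preprocess)
  } else library
  out_mask <- flag_outliers(prep, outlier)

  knn_res <- knn_loso(prep, knn, outlier_mask = out_mask)

  truth <- library_scan_truth(prep)
  folds <- grouped_cv_folds(prep$sample_meta$sample_id, n_folds = n_folds,
                            seed = seed)
  scan_fold <- folds[truth$sample_id]
  b_res <- data.frame(scan_id = truth$scan_id, probability = NA_real_,
                      form = NA_character_, predicted_conc = NA_real_,
                      stringsAsFactors = FALSE)
  for (f in sort(unique(scan_fold))) {
    train <- which(scan_fold != f & !out_mask)
    test <- which(scan_fold == f)
    coc <- train[truth$cocaine_form[train] %in% c("hcl", "base")]
    if (length(unique(truth$cocaine_form[coc])) < 2) {
      stop(sprintf("fold %d training set lacks one cocaine form", f),
           call. = FALSE)
    }
    ann_f <- ann
    ann_f$seed <- ann$seed + f
    clf <- fit_form_classifier(prep$matrix[coc, , drop = FALSE],
                               truth$cocaine_form[coc], ann_f,
                               preprocess_tag = prep$preprocess_tag)
    regs <- list()
    for (fm in c("hcl", "base")) {
      rows <- coc[truth$cocaine_form[coc] == fm]
      regs[[fm]] <- fit_concentration_regressor(
        prep$matrix[rows, , drop = FALSE], truth$cocaine_wt_pct[rows],
        form = fm, B = B, min_leaf = min_leaf, seed = seed + f,
        preprocess_tag = prep$preprocess_tag)
    }
    pb <- predict_submodel_b(prep$matrix[test, , drop = FALSE], clf, regs,
                             config = ann_f,
                             preprocess_tag = prep$preprocess_tag)
    b_res[test, c("probability", "form", "predicted_conc")] <- pb
  }

  keep <- which(!out_mask)
  scan_verdicts <- do.call(rbind, lapply(keep, function(i) {
    v <- decide_spectrum(list(status = knn_res$status[i],
                              predicted_conc = knn_res$predicted_conc[i],
                              predicted_identity = knn_res$predicted_identity[i]),
                         b_form = b_res$form[i],
                         b_conc = b_res$predicted_conc[i],
                         config = decision)
    cbind(data.frame(scan_id = truth$scan_id[i], sample_id = truth$sample_id[i],
                     stringsAsFactors = FALSE),
          v,
          data.frame(knn_status = knn_res$status[i],
                     knn_conc = knn_res$predicted_conc[i],
                     b_form = b_res$form[i], b_conc = b_res$predicted_conc[i],
                     stringsAsFactors = FALSE))
  }))
  rownames(scan_verdicts) <- NULL
  sample_verdicts <- do.call(rbind, lapply(split(scan_verdicts,
                                                 scan_verdicts$sample_id),
                                           function(sv) {
    cbind(data.frame(sample_id = sv$sample_id[1], stringsAsFactors = FALSE),
          decide_sample(sv))
  }))
  rownames(sample_verdicts) <- NULL
  sample_verdicts <- sample_verdicts[match(
    intersect(prep$sample_meta$sample_id, sample_verdicts$sample_id),
    sample_verdicts$sample_id), , drop = FALSE]
  rownames(sample_verdicts) <- NULL
  structure(list(scan_verdicts = scan_verdicts,
                 sample_verdicts = sample_verdicts,
                 knn = knn_res, submodel_b = b_res, outliers = out_mask,
                 preprocess_tag = prep$preprocess_tag,
                 configs = list(preprocess = preprocess, outlier = outlier,
                                knn = knn, ann = ann, decision = decision,
                                n_folds = n_folds, B = B,
                                min_leaf = min_leaf, seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("<cv_result> %d scan verdicts (%d positive), ",
                     "%d sample verdicts (%d positive), %d outliers removed\n"),
              nrow(x$scan_verdicts),
              sum(x$scan_verdicts$result == "positive"),
              nrow(x$sample_verdicts),
              sum(x$sample_verdicts$result == "positive"),
              sum(x$outliers)))
  invisible(x)
}

# Ground-truth positivity of samples at the evaluation convention:
# positive <=> cocaine present (form != none) and wt% above threshold.
# Cocaine-containing samples at or below the threshold are deliberate
# false negatives of the screening rule and are excluded from tallies
# unless include_subthreshold = TRUE.
truth_labels <- function(sample_meta, config) {
  thr <- config$conc_threshold_wt_pct
  pos <- sample_meta$cocaine_form != "none" & sample_meta$cocaine_wt_pct > thr
  sub <- sample_meta$cocaine_form != "none" & sample_meta$cocaine_wt_pct <= thr
  data.frame(sample_id = sample_meta$sample_id, positive = pos,
             subthreshold = sub, stringsAsFactors = FALSE)
}

#' Confusion report of verdicts against ground truth
#'
#' Tallies verdicts against the metadata ground truth. A sample is truly
#' positive when it contains cocaine above the decision threshold;
#' cocaine-containing samples at or below the threshold (deliberate false
#' negatives of the screening rule) are excluded from the tally by default.
#'
#' @param verdicts Scan- or sample-level verdict data frame (columns
#'   `sample_id`, `result`).
#' @param sample_meta Sample-metadata data frame.
#' @param config A [decision_config()] fixing the ground-truth convention.
#' @param level `"scan"` or `"sample"` (bookkeeping only).
#' @param include_subthreshold Keep sub-threshold cocaine samples in the
#'   tally (as true positives)? Default `FALSE`.
#' @return An object of class `evaluation_report`: list with `level`,
#'   `counts` (tp, fn, tn, fp), `rates` (percentages; `tp_rate` =
#'   tp / (tp + fn) etc.) and `n_excluded`.
#' @export
confusion_report <- function(verdicts, sample_meta,
                             config = decision_config(),
                             level = c("scan", "sample"),
                             include_subthreshold = FALSE) {
  level <- match.arg(level)
  tl <- truth_labels(sample_metadata(sample_meta), config)
  idx <- match(verdicts$sample_id, tl$sample_id)
  if (anyNA(idx)) {
    stop("verdict sample_id(s) not in metadata: ",
         paste(unique(verdicts$sample_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  pos_truth <- tl$positive[idx] | (include_subthreshold & tl$subthreshold[idx])
  keep <- include_subthreshold | !tl$subthreshold[idx]
  pred_pos <- verdicts$result == "positive"
  tp <- sum(keep & pos_truth & pred_pos)
  fn <- sum(keep & pos_truth & !pred_pos)
  tn <- sum(keep & !pos_truth & !pred_pos)
  fp <- sum(keep & !pos_truth & pred_pos)
  rate <- function(a, b) if (a + b == 0) NA_real_ else 100 * a / (a + b)
  structure(list(level = level,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 rates = c(tp_rate = rate(tp, fn), fn_rate = rate(fn, tp),
                           tn_rate = rate(tn, fp), fp_rate = rate(fp, tn)),
                 n_excluded = sum(!keep)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s level\n", x$level))
  cat(sprintf("  TP %d (%.1f%%)  FN %d (%.1f%%)  TN %d (%.1f%%)  FP %d (%.1f%%)\n",
              x$counts["tp"], x$rates["tp_rate"], x$counts["fn"], x$rates["fn_rate"],
              x$counts["tn"], x$rates["tn_rate"], x$counts["fp"], x$rates["fp_rate"]))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d sub-threshold cocaine verdicts excluded)\n", x$n_excluded))
  }
  invisible(x)
}

#' Concentration-fit metrics
#'
#' Squared Pearson correlation and root-mean-square error between predicted
#' and known cocaine concentrations. Pairs with a missing prediction (kNN
#' abstentions) are dropped and counted.
#'
#' @param predicted Predicted concentrations (wt%); may contain `NA`.
#' @param known Known concentrations (wt%), same length.
#' @return List with `r_squared`, `rmse`, `n_used`, `n_dropped`.
#' @export
concentration_fit_metrics <- function(predicted, known) {
  if (length(predicted) != length(known)) {
    stop("predicted and known must have equal length", call. = FALSE)
  }
  keep <- !is.na(predicted) & !is.na(known)
  p <- predicted[keep]
  k <- known[keep]
  if (length(p) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(p) == 0 || stats::sd(k) == 0) {
    stop("zero variance in predictions or truth: R-squared undefined",
         call. = FALSE)
  }
  list(r_squared = stats::cor(p, k)^2,
       rmse = sqrt(mean((p - k)^2)),
       n_used = length(p),
       n_dropped = sum(!keep))
}

#' Threshold sweep of the decision rule
#'
#' Re-applies the decision hierarchy at each threshold of a grid to
#' predictions computed once (no retraining), tallying rates against a fixed
#' ground truth. Reports the curve plus three operating points: the smallest
#' threshold with zero false positives, the maximum-accuracy threshold, and
#' the largest threshold keeping the false-negative rate at or below
#' `fn_tolerance_pct`.
#'
#' @param scan_verdicts Scan-verdict data frame from [loso_cross_validate()]
#'   (needs columns `sample_id`, `knn_status`, `knn_conc`, `b_form`,
#'   `b_conc`).
#' @param sample_meta Sample-metadata data frame.
#' @param thresholds Strictly increasing grid of wt% thresholds
#'   (default 0..100).
#' @param truth_config [decision_config()] fixing the ground-truth labels
#'   (held fixed across the sweep).
#' @param fn_tolerance_pct Tolerated FN rate for the minimal-FN point
#'   (default 0.1).
#' @return An object of class `threshold_curve`: data frame with columns
#'   `threshold`, `tp_rate`, `fp_rate`, `fn_rate`, `accuracy`, and
#'   attributes `zero_fp_threshold`, `max_accuracy_threshold`,
#'   `min_fn_threshold`.
#' @export
threshold_curve <- function(scan_verdicts, sample_meta,
                            thresholds = 0:100,
                            truth_config = decision_config(),
                            fn_tolerance_pct = 0.1) {
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  tl <- truth_labels(sample_metadata(sample_meta), truth_config)
  idx <- match(scan_verdicts$sample_id, tl$sample_id)
  keep <- !tl$subthreshold[idx]
  truth_pos <- tl$positive[idx][keep]
  knn_ok <- (scan_verdicts$knn_status == "ok")[keep]
  knn_conc <- scan_verdicts$knn_conc[keep]
  b_assigned <- (scan_verdicts$b_form %in% c("hcl", "base"))[keep]
  b_conc <- scan_verdicts$b_conc[keep]
  n_pos <- sum(truth_pos)
  n_neg <- sum(!truth_pos)
  rows <- lapply(thresholds, function(t) {
    pos <- ifelse(knn_ok, !is.na(knn_conc) & knn_conc > t,
                  b_assigned & !is.na(b_conc) & b_conc > t)
    tp <- sum(pos & truth_pos); fp <- sum(pos & !truth_pos)
    data.frame(threshold = t,
               tp_rate = if (n_pos) 100 * tp / n_pos else NA_real_,
               fp_rate = if (n_neg) 100 * fp / n_neg else NA_real_,
               fn_rate = if (n_pos) 100 * (n_pos - tp) / n_pos else NA_real_,
               accuracy = 100 * (tp + (n_neg - fp)) / (n_pos + n_neg))
  })
  curve <- do.call(rbind, rows)
  zero_fp <- curve$threshold[curve$fp_rate == 0]
  min_fn <- curve$threshold[curve$fn_rate <= fn_tolerance_pct]
  structure(curve,
            zero_fp_threshold = if (length(zero_fp)) min(zero_fp) else NA_real_,
            max_accuracy_threshold = curve$threshold[which.max(curve$accuracy)],
            min_fn_threshold = if (length(min_fn)) max(min_fn) else NA_real_,
            class = c("threshold_curve", "data.frame"))
}
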