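# Submodel B: PCA-prescaled neural-network salt-form classifier with
# probability gating, plus two per-form bagged regression-tree
# concentration models, and grouped cross-validation utilities.

#' Grouped cross-validation folds
#'
#' Randomly partitions samples (not scans) into near-equal folds so that all
#' replicate scans of one sample are held out together, preventing replicate
#' leakage between training and validation.
#'
#' @param sample_ids Character vector of distinct sample identifiers.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return Named integer vector: fold index in `1..n_folds` per sample.
#' @export
grouped_cv_folds <- function(sample_ids, n_folds = 10, seed = 1) {
  sample_ids <- unique(as.character(sample_ids))
  n <- length(sample_ids)
  if (n_folds > n) {
    stop(sprintf("n_folds (%d) exceeds number of samples (%d)", n_folds, n),
         call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  perm <- sample(sample_ids)
  folds <- rep(seq_len(n_folds), length.out = n)
  stats::setNames(folds[match(sample_ids, perm)], sample_ids)
}

# Save/restore the global RNG state so seeded fits do not perturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Salt-form classifier configuration
#'
#' Settings for the PCA-prescaled neural network that scores the probability
#' that a scan is cocaine base (versus cocaine HCl), and for the probability
#' gates that turn the score into a class call. Scores of at most `prob_low`
#' are called HCl, scores of at least `prob_high` are called base, and
#' anything in between is left unassigned.
#'
#' @param variance_retained Fraction of spectral variance the PCA prescaling
#'   must retain (default 0.99); the smallest number of components reaching
#'   it is used.
#' @param prob_low,prob_high Gating bounds (defaults 0.05 and 0.95,
#'   inclusive).
#' @param hidden_units Hidden-layer size of the network (default 8).
#' @param max_epochs Maximum training iterations (default 300).
#' @param decay Weight decay of the network (default 1e-4).
#' @param seed Integer seed for weight initialisation; training is
#'   reproducible given (data, config, seed).
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(variance_retained = 0.99, prob_low = 0.05,
                       prob_high = 0.95, hidden_units = 8, max_epochs = 300,
                       decay = 1e-4, seed = 1) {
  if (!(prob_low > 0 && prob_low < prob_high && prob_high < 1)) {
    stop("need 0 < prob_low < prob_high < 1", call. = FALSE)
  }
  if (variance_retained <= 0 || variance_retained > 1) {
    stop("variance_retained must be in (0, 1]", call. = FALSE)
  }
  structure(list(variance_retained = variance_retained, prob_low = prob_low,
                 prob_high = prob_high, hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs), decay = decay,
                 seed = as.integer(seed)),
            class = "ann_config")
}

# Smallest number of leading components whose cumulative explained
# variance reaches the target fraction.
n_components_for_variance <- function(sdev, variance_retained) {
  frac <- cumsum(sdev^2) / sum(sdev^2)
  which(frac >= variance_retained - 1e-12)[1]
}

#' Fit the salt-form classifier
#'
#' Fits a PCA (mean-centred, unscaled) on the training matrix, keeps the
#' smallest number of components retaining `variance_retained` of the
#' variance, and trains a single-hidden-layer neural network
#' (logistic output, cross-entropy loss) on the scores with targets
#' HCl = 0, base = 1. Train only on cocaine-containing scans of known form,
#' with outlier-flagged scans already removed.
#'
#' @param x Preprocessed scans-by-wavelength matrix of cocaine scans.
#' @param form Character vector (`"hcl"` / `"base"`) per row of `x`.
#' @param config An [ann_config()].
#' @param preprocess_tag Tag of the preprocessing applied to `x`; stored and
#'   checked at prediction time.
#' @return An object of class `form_classifier`.
#' @export
fit_form_classifier <- function(x, form, config = ann_config(),
                                preprocess_tag = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(form))
  form <- as.character(form)
  if (!all(form %in% c("hcl", "base"))) {
    stop("form must be 'hcl' or 'base'", call. = FALSE)
  }
  if (length(unique(form)) < 2) {
    stop("training set contains a single form; need both hcl and base",
         call. = FALSE)
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components_for_variance(pca$sdev, config$variance_retained)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  y <- as.numeric(form == "base")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  net <- nnet::nnet(scores, y, size = config$hidden_units, decay = config$decay,
                    maxit = config$max_epochs, entropy = TRUE, trace = FALSE)
  structure(list(center = pca$center,
                 rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 n_components_used = k,
                 sdev = pca$sdev,
                 network = net,
                 config = config,
                 preprocess_tag = preprocess_tag),
            class = "form_classifier")
}

#' @export
print.form_classifier <- function(x, ...) {
  cat(sprintf("<form_classifier> %d PCs (>= %.0f%% variance), %d hidden units\n",
              x$n_components_used, 100 * x$config$variance_retained,
              x$config$hidden_units))
  invisible(x)
}

#' Score the probability of the base form
#'
#' @param classifier A `form_classifier`.
#' @param x Preprocessed spectrum (vector) or matrix of spectra.
#' @param preprocess_tag Optional tag of the preprocessing applied to `x`;
#'   if both tags are non-`NULL` they must match.
#' @return Numeric vector of probabilities in \[0, 1\] that each scan is
#'   cocaine base.
#' @export
predict_form_probability <- function(classifier, x, preprocess_tag = NULL) {
  stopifnot(inherits(classifier, "form_classifier"))
  check_preprocess_tag(classifier$preprocess_tag, preprocess_tag)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(classifier$center)) {
    stop("scan width does not match the classifier's training width",
         call. = FALSE)
  }
  scores <- sweep(x, 2, classifier$center) %*% classifier$rotation
  p <- as.numeric(stats::predict(classifier$network, scores))
  pmin(pmax(p, 0), 1)
}

check_preprocess_tag <- function(model_tag, data_tag) {
  if (!is.null(model_tag) && !is.null(data_tag) &&
      !identical(model_tag, data_tag)) {
    stop(sprintf("preprocessing mismatch: model trained on '%s', data is '%s'",
                 model_tag, data_tag), call. = FALSE)
  }
  invisible(NULL)
}

#' Gate a form probability into a class call
#'
#' @param probability Probability (or vector of probabilities) of the base
#'   form, in \[0, 1\].
#' @param config An [ann_config()] supplying the gates.
#' @return Character vector: `"hcl"` for probabilities at or below
#'   `prob_low`, `"base"` at or above `prob_high`, `"unassigned"` otherwise.
#' @examples
#' assign_form(c(0.02, 0.5, 0.97)) # hcl unassigned base
#' @export
assign_form <- function(probability, config = ann_config()) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop("probability must be in [0, 1]", call. = FALSE)
  }
  out <- rep("unassigned", length(probability))
  out[probability <= config$prob_low] <- "hcl"
  out[probability >= config$prob_high] <- "base"
  out[is.na(probability)] <- NA_character_
  out
}

#' Fit a bagged-tree concentration regressor
#'
#' Trains an ensemble of `B` regression trees, each on a bootstrap resample
#' (n draws with replacement) of the training scans of one cocaine form; the
#' ensemble prediction is the mean of the tree predictions, clipped to
#' \[0, 100\] wt%.
#'
#' @param x Preprocessed scans-by-wavelength matrix (one form only).
#' @param conc Known cocaine concentrations (wt%) per row.
#' @param form `"hcl"` or `"base"`; recorded for bookkeeping.
#' @param B Number of bootstrap trees (default 25).
#' @param min_leaf Minimum observations in a terminal node (default 5).
#' @param seed Integer seed for the bootstrap resampling.
#' @param preprocess_tag Tag of the preprocessing applied to `x`.
#' @return An object of class `concentration_regressor`.
#' @export
fit_concentration_regressor <- function(x, conc, form = c("hcl", "base"),
                                        B = 25, min_leaf = 5, seed = 1,
                                        preprocess_tag = NULL) {
  form <- match.arg(form)
  stopifnot(is.matrix(x), nrow(x) == length(conc))
  if (nrow(x) == 0) stop("empty training set for form ", form, call. = FALSE)
  df <- as.data.frame(x)
  names(df) <- paste0("v", seq_len(ncol(x)))
  df$.conc <- conc
  ctrl <- rpart::rpart.control(minsplit = max(2L, 2L * min_leaf),
                               minbucket = min_leaf, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- nrow(df)
  trees <- lapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.conc ~ ., data = df[idx, , drop = FALSE], method = "anova",
                 control = ctrl)
  })
  structure(list(form = form, trees = trees, B = B, min_leaf = min_leaf,
                 seed = seed, n_features = ncol(x),
                 preprocess_tag = preprocess_tag),
            class = "concentration_regressor")
}

#' Predict concentration from a bagged-tree regressor
#'
#' @param object A `concentration_regressor`.
#' @param x Preprocessed spectrum (vector) or matrix of spectra.
#' @param ... Unused.
#' @return Numeric vector of predicted cocaine concentrations (wt%),
#'   clipped to \[0, 100\].
#' @export
predict.concentration_regressor <- function(object, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$n_features) {
    stop("scan width does not match the regressor's training width",
         call. = FALSE)
  }
  df <- as.data.frame(x)
  names(df) <- paste0("v", seq_len(ncol(x)))
  preds <- vapply(object$trees, function(tr) as.numeric(stats::predict(tr, df)),
                  numeric(nrow(df)))
  if (nrow(df) == 1) preds <- matrix(preds, nrow = 1)
  out <- rowMeans(preds)
  pmin(pmax(out, 0), 100)
}

#' @export
print.concentration_regressor <- function(x, ...) {
  cat(sprintf("<concentration_regressor> form %s, %d bagged trees (min leaf %d)\n",
              x$form, x$B, x$min_leaf))
  invisible(x)
}

#' Run submodel B on scans
#'
#' Composes the gated form classifier with the per-form concentration
#' regressors: each scan's base-form probability is gated via
#' [assign_form()]; scans assigned a form get a concentration from that
#' form's regressor, unassigned scans get none.
#'
#' @param x Preprocessed spectrum (vector) or matrix of spectra.
#' @param classifier A `form_classifier`.
#' @param regressors Named list with elements `hcl` and `base`, each a
#'   `concentration_regressor`.
#' @param config The [ann_config()] supplying the probability gates.
#' @param preprocess_tag Optional tag of the preprocessing applied to `x`.
#' @return Data frame with columns `probability`, `form`
#'   (`hcl`/`base`/`unassigned`) and `predicted_conc` (`NA` when unassigned).
#' @export
predict_submodel_b <- function(x, classifier, regressors,
                               config = classifier$config,
                               preprocess_tag = NULL) {
  stopifnot(all(c("hcl", "base") %in% names(regressors)))
  check_preprocess_tag(classifier$preprocess_tag, preprocess_tag)
  for (f in c("hcl", "base")) {
    check_preprocess_tag(regressors[[f]]$preprocess_tag, preprocess_tag)
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  p <- predict_form_probability(classifier, x)
  form <- assign_form(p, config)
  conc <- rep(NA_real_, nrow(x))
  for (f in c("hcl", "base")) {
    rows <- which(form == f)
    if (length(rows) > 0) {
      conc[rows] <- predict(regressors[[f]], x[rows, , drop = FALSE])
    }
  }
  data.frame(probability = p, form = form, predicted_conc = conc,
             stringsAsFactors = FALSE)
}
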