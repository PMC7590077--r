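# Grouped folds, PCA-prescaled form classifier with gating, bagged trees.

test_that("grouped folds co-assign samples, balance sizes and are seeded", {
  ids <- sprintf("s%02d", 1:20)
  f1 <- grouped_cv_folds(ids, n_folds = 10, seed = 1)
  expect_equal(sort(unname(table(f1))), rep(2L, 10), ignore_attr = TRUE)
  f2 <- grouped_cv_folds(ids, n_folds = 10, seed = 1)
  expect_identical(f1, f2)
  f3 <- grouped_cv_folds(ids, n_folds = 10, seed = 2)
  expect_false(identical(f1, f3))
  expect_error(grouped_cv_folds(ids[1:5], n_folds = 10), "exceeds")
})

make_form_library <- function(noise_sd = 0.001, seed = 31) {
  sigs <- benchmark_signatures()
  wt <- c(95, 80, 65, 50)
  samples <- data.frame(
    sample_id = c(sprintf("h%d", 1:4), sprintf("b%d", 1:4)),
    identity = rep(c("cocaine HCl in caffeine", "cocaine base in caffeine"), each = 4),
    cocaine_form = rep(c("hcl", "base"), each = 4),
    cocaine_wt_pct = rep(wt, 2), set_tag = "A", stringsAsFactors = FALSE)
  compositions <- c(
    lapply(wt / 100, function(f) stats::setNames(c(f, 1 - f), c("cocaine_hcl", "caffeine"))),
    lapply(wt / 100, function(f) stats::setNames(c(f, 1 - f), c("cocaine_base", "caffeine"))))
  names(compositions) <- samples$sample_id
  mm <- measurement_model(scatter_sd = 0.05, offset_sd = 0.03,
                          scanner_offset_sd = 0.03, noise_sd = noise_sd)
  gen <- generate_library(library_design(sigs, samples, compositions,
                                         n_scanners = 2, replicates = 3,
                                         model = mm, seed = seed))
  build_library(gen$scans, gen$sample_meta)
}

test_that("form classifier separates clean HCl/base spectra through the gates", {
  lib <- make_form_library()
  prep <- preprocess_library(lib, preprocess_config(1))
  truth <- nirscreen:::library_scan_truth(prep)
  cfg <- ann_config(seed = 5)
  clf <- fit_form_classifier(prep$matrix, truth$cocaine_form, cfg,
                             preprocess_tag = prep$preprocess_tag)
  p <- predict_form_probability(clf, prep$matrix)
  expect_true(all(p[truth$cocaine_form == "hcl"] < 0.05))
  expect_true(all(p[truth$cocaine_form == "base"] > 0.95))

  # refitting with the same data/config/seed reproduces the probabilities
  clf2 <- fit_form_classifier(prep$matrix, truth$cocaine_form, cfg,
                              preprocess_tag = prep$preprocess_tag)
  expect_identical(p, predict_form_probability(clf2, prep$matrix))

  # single-class training is refused
  hcl_rows <- truth$cocaine_form == "hcl"
  expect_error(fit_form_classifier(prep$matrix[hcl_rows, ],
                                   truth$cocaine_form[hcl_rows], cfg),
               "single form")
})

test_that("PCA component count matches a cumulative-eigenvalue oracle", {
  set.seed(12)
  # anisotropic data with a known spectrum of variances
  x <- matrix(stats::rnorm(400 * 20), 400, 20) %*% diag(seq(3, 0.1, length.out = 20))
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (vr in c(0.8, 0.95, 0.99)) {
    got <- nirscreen:::n_components_for_variance(pca$sdev, vr)
    # oracle: eigenvalues of the covariance matrix, summed until the target
    ev <- sort(eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    want <- which(cumsum(ev) / sum(ev) >= vr)[1]
    expect_identical(got, want)
  }
})

test_that("probability gates assign forms with inclusive bounds", {
  cfg <- ann_config()
  expect_identical(assign_form(c(0.02, 0.5, 0.97), cfg),
                   c("hcl", "unassigned", "base"))
  expect_identical(assign_form(c(0.05, 0.95), cfg), c("hcl", "base"))
  expect_identical(assign_form(c(0.050001, 0.949999), cfg),
                   c("unassigned", "unassigned"))
  expect_error(assign_form(1.2, cfg), "probability")
})

test_that("bagged trees memorise degenerate training sets and beat the mean baseline", {
  set.seed(21)
  x <- matrix(stats::rnorm(60 * 10), 60, 10)
  # constant-concentration training set predicts the constant
  reg_const <- fit_concentration_regressor(x, rep(70, 60), form = "hcl",
                                           B = 5, seed = 1)
  expect_equal(unname(predict(reg_const, x[1:5, ])), rep(70, 5))

  # single tree with min-leaf 1 memorises a unique training point
  y <- stats::runif(60, 0, 100)
  reg1 <- fit_concentration_regressor(x, y, form = "hcl", B = 1, min_leaf = 1,
                                      seed = 7)
  # the bootstrap resample may not contain every point; check one that is in it
  set.seed(7)
  idx <- sample.int(60, 60, replace = TRUE)
  probe <- idx[1]
  expect_equal(unname(predict(reg1, x[probe, , drop = FALSE])), y[probe])

  # on a smooth dilution response, the ensemble beats predict-the-mean
  lib <- small_benchmark_library(n_samples = 8, n_scanners = 3,
                                 replicates = 3, seed = 23)
  prep <- preprocess_library(lib, preprocess_config(1))
  truth <- nirscreen:::library_scan_truth(prep)
  hold <- truth$sample_id %in% c("s03", "s06")
  reg <- fit_concentration_regressor(prep$matrix[!hold, ],
                                     truth$cocaine_wt_pct[!hold],
                                     form = "hcl", B = 25, seed = 2)
  pred <- predict(reg, prep$matrix[hold, ])
  rmse <- sqrt(mean((pred - truth$cocaine_wt_pct[hold])^2))
  baseline <- sqrt(mean((mean(truth$cocaine_wt_pct[!hold]) -
                           truth$cocaine_wt_pct[hold])^2))
  expect_lt(rmse, baseline)
})

test_that("ensemble averaging shrinks prediction spread across reseeded refits", {
  lib <- small_benchmark_library(n_samples = 6, n_scanners = 2,
                                 replicates = 3, seed = 29)
  prep <- preprocess_library(lib, preprocess_config(1))
  truth <- nirscreen:::library_scan_truth(prep)
  hold <- truth$sample_id == "s04"
  pred_for <- function(B, seed) {
    reg <- fit_concentration_regressor(prep$matrix[!hold, ],
                                       truth$cocaine_wt_pct[!hold],
                                       form = "hcl", B = B, seed = seed)
    mean(predict(reg, prep$matrix[hold, ]))
  }
  single <- vapply(1:8, function(s) pred_for(1, s), numeric(1))
  bagged <- vapply(1:8, function(s) pred_for(25, s), numeric(1))
  expect_lt(stats::sd(bagged), stats::sd(single))
})

test_that("submodel B composes gating and per-form regression", {
  lib <- make_form_library()
  prep <- preprocess_library(lib, preprocess_config(1))
  truth <- nirscreen:::library_scan_truth(prep)
  cfg <- ann_config(seed = 5)
  clf <- fit_form_classifier(prep$matrix, truth$cocaine_form, cfg,
                             preprocess_tag = prep$preprocess_tag)
  regs <- list(
    hcl = fit_concentration_regressor(prep$matrix[truth$cocaine_form == "hcl", ],
                                      truth$cocaine_wt_pct[truth$cocaine_form == "hcl"],
                                      form = "hcl", seed = 1,
                                      preprocess_tag = prep$preprocess_tag),
    base = fit_concentration_regressor(prep$matrix[truth$cocaine_form == "base", ],
                                       truth$cocaine_wt_pct[truth$cocaine_form == "base"],
                                       form = "base", seed = 1,
                                       preprocess_tag = prep$preprocess_tag))
  out <- predict_submodel_b(prep$matrix, clf, regs, config = cfg,
                            preprocess_tag = prep$preprocess_tag)
  expect_identical(out$form, truth$cocaine_form)
  expect_true(all(!is.na(out$predicted_conc)))
  # zero-noise base scans recover roughly the true concentration
  base_rows <- truth$cocaine_form == "base"
  expect_lt(mean(abs(out$predicted_conc[base_rows] -
                       truth$cocaine_wt_pct[base_rows])), 10)
  # preprocess fingerprint mismatch is refused
  expect_error(predict_submodel_b(prep$matrix, clf, regs, config = cfg,
                                  preprocess_tag = "snv-d2-w19-p3"),
               "mismatch")
})
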