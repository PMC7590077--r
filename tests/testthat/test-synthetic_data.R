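# Synthetic signatures, measurement model, library generation.

test_that("a single-band signature is a Gaussian bump peaking at its centre", {
  g <- wavelength_grid()
  sig <- component_signature("bump", band_centers = 880, band_widths = 30,
                             band_amplitudes = 1, baseline_slope = 0,
                             baseline_level = 1)
  v <- signature_values(sig, g)
  expect_equal(g$wavelengths[which.max(v)], 880)
  expect_equal(max(v), 2)
  expect_equal(v[g$wavelengths == 880 + 30], 1 + exp(-0.5), tolerance = 1e-12)
  expect_error(signature_values(
    component_signature("off", 2000, 30, 1), g), "outside")
})

test_that("seeded random signatures are reproducible", {
  s1 <- make_component_signature("a", seed = 11)
  s2 <- make_component_signature("a", seed = 11)
  expect_identical(s1, s2)
  s3 <- make_component_signature("a", seed = 12)
  expect_false(identical(s1$band_centers, s3$band_centers))
  v <- signature_values(s1)
  expect_true(all(v > 0))
})

test_that("frozen benchmark signatures are mutually distinguishable after preprocessing", {
  sigs <- benchmark_signatures()
  g <- wavelength_grid()
  cfg <- preprocess_config(1)
  pp <- t(vapply(sigs, function(s) {
    savgol_derivative(snv(signature_values(s, g)), cfg)
  }, numeric(313)))
  d <- as.matrix(stats::dist(pp))
  expect_gt(min(d[upper.tri(d)]), 0.1)
  r <- stats::cor(t(pp))
  expect_lt(max(r[upper.tri(r)]), 0.98)
  # the two cocaine forms differ inside the 839-939 nm region of interest
  wl <- g$wavelengths[10:322]
  roi <- wl >= 839 & wl <= 939
  expect_gt(sqrt(sum((pp["cocaine_hcl", roi] - pp["cocaine_base", roi])^2)), 0.1)
})

test_that("the identity measurement model returns the exact mixture", {
  sigs <- benchmark_signatures()
  quiet <- measurement_model(scatter_sd = 0, offset_sd = 0,
                             scanner_offset_sd = 0, noise_sd = 0)
  fr <- stats::setNames(c(0.3, 0.7), c("cocaine_hcl", "lactose"))
  v <- simulate_scan(fr, sigs, quiet)
  want <- 0.3 * signature_values(sigs$cocaine_hcl) +
    0.7 * signature_values(sigs$lactose)
  expect_equal(v, want)
  # pure component equals its signature
  expect_equal(simulate_scan(c(caffeine = 1), sigs, quiet),
               signature_values(sigs$caffeine))
  expect_error(simulate_scan(c(caffeine = 0.6), sigs, quiet), "sum to 1")
})

test_that("the preprocessed replicate mean converges to the noise-free scan", {
  sigs <- benchmark_signatures()
  cfg <- preprocess_config(1)
  fr <- stats::setNames(c(0.42, 0.58), c("cocaine_hcl", "caffeine"))
  quiet <- measurement_model(scatter_sd = 0, offset_sd = 0,
                             scanner_offset_sd = 0, noise_sd = 0)
  truth_pp <- savgol_derivative(snv(simulate_scan(fr, sigs, quiet)), cfg)
  set.seed(99)
  reps <- t(vapply(1:200, function(i) {
    savgol_derivative(snv(simulate_scan(fr, sigs, measurement_model())), cfg)
  }, numeric(313)))
  d_single <- mean(sqrt(rowSums(sweep(reps, 2, truth_pp)^2)))
  d_mean <- sqrt(sum((colMeans(reps) - truth_pp)^2))
  expect_lt(d_mean, d_single / 5)
})

test_that("library generation is deterministic, correctly sized and truth-labelled", {
  design <- benchmark_design(seed = 20)
  gen <- generate_library(design)
  expect_equal(nrow(gen$scans$meta), 72 * 5 * 5)
  expect_equal(nrow(gen$sample_meta), 72)
  # REF caffeine ladder truth values are present
  caf <- gen$sample_meta[grepl("^hc_caf", gen$sample_meta$sample_id), ]
  expect_setequal(caf$cocaine_wt_pct, c(42, 34, 30, 25, 20, 19, 10, 5, 0))
  expect_true(all(caf$cocaine_form[caf$cocaine_wt_pct > 0] == "hcl"))
  expect_true(all(caf$cocaine_form[caf$cocaine_wt_pct == 0] == "none"))

  # byte-identical CSVs for identical design/seed
  gen2 <- generate_library(benchmark_design(seed = 20))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_scans(gen$scans, f1)
  write_scans(gen2$scans, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the values
  gen3 <- generate_library(benchmark_design(seed = 21))
  expect_false(identical(gen$scans$values, gen3$scans$values))
})

test_that("spike corruption is recorded and roughly binomial in count", {
  design <- benchmark_design(seed = 20, outlier_rate = 0.01)
  gen <- generate_library(design)
  n <- nrow(gen$scans$meta)
  expect_true(all(gen$corrupted %in% gen$scans$meta$scan_id))
  # within 4 binomial standard deviations of the expected count
  expect_lt(abs(length(gen$corrupted) - 0.01 * n),
            4 * sqrt(n * 0.01 * 0.99) + 1)
  # corrupted scans really deviate from their uncorrupted counterparts
  clean <- generate_library(benchmark_design(seed = 20))
  idx <- match(gen$corrupted, gen$scans$meta$scan_id)
  diffs <- abs(gen$scans$values[idx, , drop = FALSE] -
                 clean$scans$values[idx, , drop = FALSE])
  expect_true(all(apply(diffs, 1, max) >= design$model$spike_magnitude * 0.99))
})

test_that("inconsistent designs are rejected", {
  sigs <- benchmark_signatures()
  samples <- data.frame(sample_id = "bad", identity = "cocaine HCl in caffeine",
                        cocaine_form = "hcl", cocaine_wt_pct = 50, set_tag = "A",
                        stringsAsFactors = FALSE)
  # fraction says 40%, metadata says 50%
  comp <- list(bad = stats::setNames(c(0.4, 0.6), c("cocaine_hcl", "caffeine")))
  expect_error(library_design(sigs, samples, comp), "inconsistent")
  comp2 <- list(bad = stats::setNames(c(0.5, 0.6), c("cocaine_hcl", "caffeine")))
  expect_error(library_design(sigs, samples, comp2), "sum to 1")
  expect_error(library_design(sigs, samples, list()), "no composition")
})
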