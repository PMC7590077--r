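# Shared fixtures. Heavy benchmark runs are computed once per session and
# cached; everything is seeded and generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Full cross-validated benchmark run (frozen design seed 20, pipeline seed 1).
benchmark_run <- function() cached("benchmark", run_benchmark(seed = 1))

# Benchmark library with 1% spike-corrupted scans, plus its outlier flags.
outlier_run <- function() {
  cached("outlier", {
    design <- benchmark_design(seed = 20, outlier_rate = 0.01)
    gen <- generate_library(design)
    lib <- build_library(gen$scans, gen$sample_meta)
    prep <- preprocess_library(lib)
    flags <- flag_outliers(prep)
    list(library = lib, prep = prep, flags = flags,
         corrupted = lib$scan_meta$scan_id %in% gen$corrupted)
  })
}

# Screening model fitted on the clean benchmark library (deployment path).
benchmark_model <- function() {
  cached("model", {
    gen <- generate_library(benchmark_design())
    lib <- build_library(gen$scans, gen$sample_meta)
    fit_screening_model(lib, seed = 1)
  })
}

# A small raw library: n_samples samples x n_scanners x replicates scans of
# distinct mixtures, simulated from the frozen signatures.
small_benchmark_library <- function(n_samples = 6, n_scanners = 2,
                                    replicates = 3, seed = 42,
                                    model = measurement_model()) {
  sigs <- benchmark_signatures()
  wt <- seq(80, 30, length.out = n_samples)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    identity = "cocaine HCl in caffeine",
    cocaine_form = "hcl",
    cocaine_wt_pct = wt,
    set_tag = "REF", stringsAsFactors = FALSE)
  compositions <- lapply(wt / 100, function(f) {
    stats::setNames(c(f, 1 - f), c("cocaine_hcl", "caffeine"))
  })
  names(compositions) <- samples$sample_id
  design <- library_design(sigs, samples, compositions,
                           n_scanners = n_scanners, replicates = replicates,
                           model = model, seed = seed)
  gen <- generate_library(design)
  build_library(gen$scans, gen$sample_meta)
}

# A random (non-spectral) preprocessed library for kNN ranking tests: values
# scaled so that some pairs pass and some fail the 0.1/0.98 thresholds.
random_preprocessed_library <- function(n_scans, n_vars = 12, n_samples = 4,
                                        seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n_samples * n_vars), n_samples, n_vars)
  sample_of <- sample(seq_len(n_samples), n_scans, replace = TRUE)
  mat <- base[sample_of, , drop = FALSE] * 0.05 +
    matrix(stats::rnorm(n_scans * n_vars, sd = 0.03), n_scans, n_vars)
  meta <- data.frame(scan_id = sprintf("q%03d", seq_len(n_scans)),
                     sample_id = sprintf("s%d", sample_of),
                     scanner_id = "sc1", replicate = 1L,
                     stringsAsFactors = FALSE)
  smeta <- data.frame(sample_id = sprintf("s%d", seq_len(n_samples)),
                      identity = sprintf("compound%d", seq_len(n_samples)),
                      cocaine_form = "none", cocaine_wt_pct = 0,
                      set_tag = "B", stringsAsFactors = FALSE)
  structure(list(matrix = mat, wavelengths = seq_len(n_vars),
                 scan_meta = meta, sample_meta = smeta,
                 preprocess_tag = "test"),
            class = "nir_library")
}

# Independent brute-force oracle for the dual kNN ranking: plain loops and
# sorts over every candidate scan, kept free of the package's vectorised
# ranking code.
brute_force_neighbors <- function(query, library, config,
                                  exclude_samples = character()) {
  mat <- library$matrix
  keep <- !(library$scan_meta$sample_id %in% exclude_samples)
  rows <- which(keep)
  d <- numeric(length(rows))
  r <- numeric(length(rows))
  for (i in seq_along(rows)) {
    v <- mat[rows[i], ]
    d[i] <- sqrt(sum((v - query)^2))
    r[i] <- suppressWarnings(stats::cor(v, query))
  }
  pass_d <- which(d <= config$max_distance)
  pass_d <- pass_d[order(d[pass_d], rows[pass_d])]
  pass_d <- utils::head(pass_d, config$k_distance)
  pass_r <- which(!is.na(r) & r >= config$min_correlation)
  pass_r <- pass_r[order(-r[pass_r], rows[pass_r])]
  pass_r <- utils::head(pass_r, config$k_correlation)
  list(distance_rows = rows[pass_d], distances = d[pass_d],
       correlation_rows = rows[pass_r], correlations = r[pass_r])
}
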