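# Seeded generator of synthetic component signatures, powder-mixture
# spectra and multi-scanner replicate designs. The measurement model
# reproduces the artifact structure of handheld diffuse-reflectance NIR
# scanning: per-scan multiplicative scatter, additive per-scan and
# per-scanner baseline offsets, and per-wavelength noise. Signatures are
# synthetic stand-ins for real pure-compound spectra (smooth Gaussian band
# sets); no claim of spectral realism is made.

#' Synthetic pure-component signature
#'
#' A smooth, strictly positive reflectance signature on the wavelength grid:
#' a baseline level plus slope and a set of Gaussian bands.
#'
#' @param name Component label.
#' @param band_centers Band centres in nm; must lie inside the grid.
#' @param band_widths Gaussian standard deviations in nm (one per band).
#' @param band_amplitudes Band amplitudes in reflectance units.
#' @param baseline_slope Baseline slope in units per nm (default 0).
#' @param baseline_level Baseline level (default 1).
#' @return An object of class `component_signature`.
#' @export
component_signature <- function(name, band_centers, band_widths,
                                band_amplitudes, baseline_slope = 0,
                                baseline_level = 1) {
  stopifnot(length(band_centers) == length(band_widths),
            length(band_centers) == length(band_amplitudes))
  structure(list(name = name, band_centers = band_centers,
                 band_widths = band_widths,
                 band_amplitudes = band_amplitudes,
                 baseline_slope = baseline_slope,
                 baseline_level = baseline_level),
            class = "component_signature")
}

#' Evaluate a component signature on a wavelength grid
#'
#' @param signature A [component_signature()].
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of strictly positive reflectance values on the
#'   grid. Errors if a band centre lies outside the grid or the signature is
#'   not positive everywhere.
#' @export
signature_values <- function(signature, grid = wavelength_grid()) {
  w <- grid$wavelengths
  if (any(signature$band_centers < grid$start_nm |
            signature$band_centers > grid$end_nm)) {
    stop("band centre(s) outside the wavelength grid for component ",
         signature$name, call. = FALSE)
  }
  v <- signature$baseline_level +
    signature$baseline_slope * (w - grid$start_nm)
  for (i in seq_along(signature$band_centers)) {
    v <- v + signature$band_amplitudes[i] *
      exp(-0.5 * ((w - signature$band_centers[i]) / signature$band_widths[i])^2)
  }
  if (any(v <= 0)) {
    stop("signature not strictly positive on the grid for component ",
         signature$name, call. = FALSE)
  }
  v
}

#' Random component signature
#'
#' Draws a smooth synthetic signature with 3-8 Gaussian bands (widths
#' 10-60 nm) inside the grid; deterministic given the seed.
#'
#' @param name Component label.
#' @param seed Integer seed.
#' @param grid A [wavelength_grid()].
#' @return A [component_signature()].
#' @export
make_component_signature <- function(name, seed, grid = wavelength_grid()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n_bands <- sample(3:8, 1)
  component_signature(
    name = name,
    band_centers = stats::runif(n_bands, grid$start_nm + 15, grid$end_nm - 15),
    band_widths = stats::runif(n_bands, 10, 60),
    band_amplitudes = stats::runif(n_bands, 0.15, 0.6),
    baseline_slope = stats::runif(1, -0.001, 0),
    baseline_level = stats::runif(1, 1, 1.4)
  )
}

#' Measurement-artifact model
#'
#' Parameters of the synthetic scan model
#' `a * mix + b_scanner + b_scan + noise`: the multiplicative scatter factor
#' `a` is log-normal (`exp(N(0, scatter_sd^2))`, always positive), the
#' additive offsets are Gaussian per scanner and per scan, and noise is
#' i.i.d. Gaussian per wavelength. Spike corruption (used to exercise
#' outlier flagging) adds `spike_magnitude` to a random `spike_width`-point
#' window.
#'
#' @param scatter_sd Log-scale SD of the multiplicative factor
#'   (default 0.08).
#' @param offset_sd SD of the per-scan additive offset (default 0.04).
#' @param scanner_offset_sd SD of the per-scanner systematic offset
#'   (default 0.06).
#' @param noise_sd SD of the per-wavelength additive noise (default 0.002).
#' @param spike_magnitude Offset added inside a corrupted window
#'   (default 1).
#' @param spike_width Width of the corrupted window in points (default 20).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(scatter_sd = 0.08, offset_sd = 0.04,
                              scanner_offset_sd = 0.06, noise_sd = 0.002,
                              spike_magnitude = 1, spike_width = 20) {
  stopifnot(scatter_sd >= 0, offset_sd >= 0, scanner_offset_sd >= 0,
            noise_sd >= 0)
  structure(list(scatter_sd = scatter_sd, offset_sd = offset_sd,
                 scanner_offset_sd = scanner_offset_sd, noise_sd = noise_sd,
                 spike_magnitude = spike_magnitude,
                 spike_width = as.integer(spike_width)),
            class = "measurement_model")
}

#' Simulate one scan of a powder mixture
#'
#' Evaluates the linear (Beer-Lambert-like) mixture of component signatures
#' and applies the measurement artifacts. Uses the current RNG state; seed
#' upstream for reproducibility.
#'
#' @param fractions Named numeric vector of weight fractions (must sum
#'   to 1); names index into `signatures`.
#' @param signatures Named list of [component_signature()] objects.
#' @param model A [measurement_model()].
#' @param scanner_offset Systematic additive offset of the scanner used
#'   (default 0; drawn per scanner by [generate_library()]).
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of simulated reflectance values on the grid.
#' @export
simulate_scan <- function(fractions, signatures, model = measurement_model(),
                          scanner_offset = 0, grid = wavelength_grid()) {
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop("mixture fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(fractions) %in% names(signatures))) {
    stop("unknown component(s): ",
         paste(setdiff(names(fractions), names(signatures)), collapse = ", "),
         call. = FALSE)
  }
  mix <- numeric(grid$n_points)
  for (nm in names(fractions)) {
    mix <- mix + fractions[[nm]] * signature_values(signatures[[nm]], grid)
  }
  a <- exp(stats::rnorm(1, 0, model$scatter_sd))
  b <- stats::rnorm(1, 0, model$offset_sd)
  noise <- if (model$noise_sd > 0) stats::rnorm(grid$n_points, 0, model$noise_sd) else 0
  a * mix + scanner_offset + b + noise
}

#' Library design
#'
#' Describes a full synthetic data set: the component signatures, the sample
#' plan (composition, form, cocaine wt%, set tag), the scanner/replicate
#' layout, the measurement model and the seed.
#'
#' @param signatures Named list of [component_signature()] objects.
#' @param samples Data frame with columns `sample_id`, `identity`,
#'   `cocaine_form`, `cocaine_wt_pct`, `set_tag`.
#' @param compositions Named list (keyed by `sample_id`) of named weight-
#'   fraction vectors, each summing to 1. For cocaine-containing samples the
#'   cocaine component's fraction must equal `cocaine_wt_pct / 100`.
#' @param n_scanners Number of scanners (default 5).
#' @param replicates Replicate scans per scanner (default 5).
#' @param model A [measurement_model()].
#' @param outlier_rate Probability that a scan is spike-corrupted
#'   (default 0).
#' @param seed Integer seed for the whole generation.
#' @return An object of class `library_design`.
#' @export
library_design <- function(signatures, samples, compositions,
                           n_scanners = 5, replicates = 5,
                           model = measurement_model(), outlier_rate = 0,
                           seed = 1) {
  samples <- sample_metadata(samples)
  missing_comp <- setdiff(samples$sample_id, names(compositions))
  if (length(missing_comp) > 0) {
    stop("no composition for sample(s): ",
         paste(missing_comp, collapse = ", "), call. = FALSE)
  }
  coc_names <- c(hcl = "cocaine_hcl", base = "cocaine_base")
  for (i in seq_len(nrow(samples))) {
    fr <- compositions[[samples$sample_id[i]]]
    if (abs(sum(fr) - 1) > 1e-12) {
      stop("fractions of sample ", samples$sample_id[i], " do not sum to 1",
           call. = FALSE)
    }
    form <- samples$cocaine_form[i]
    coc_fr <- if (form == "none") 0 else {
      if (!coc_names[[form]] %in% names(fr)) 0 else fr[[coc_names[[form]]]]
    }
    if (abs(coc_fr * 100 - samples$cocaine_wt_pct[i]) > 1e-9) {
      stop("cocaine fraction inconsistent with cocaine_wt_pct for sample ",
           samples$sample_id[i], call. = FALSE)
    }
  }
  structure(list(signatures = signatures, samples = samples,
                 compositions = compositions,
                 n_scanners = as.integer(n_scanners),
                 replicates = as.integer(replicates),
                 model = model, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "library_design")
}

#' Generate a synthetic scan set from a design
#'
#' Simulates `n_samples x n_scanners x replicates` scans with full truth
#' metadata. Per-scanner offsets are drawn once; scans are simulated in a
#' fixed order so the output is byte-identical for identical designs and
#' seeds. When `outlier_rate > 0`, each scan is independently
#' spike-corrupted with that probability and the corrupted scan ids are
#' returned.
#'
#' @param design A [library_design()].
#' @param grid A [wavelength_grid()].
#' @return List with `scans` (a `nir_scans` object), `sample_meta`,
#'   and `corrupted` (character vector of corrupted scan ids).
#' @export
generate_library <- function(design, grid = wavelength_grid()) {
  stopifnot(inherits(design, "library_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(design$seed)
  scanner_ids <- sprintf("scanner%02d", seq_len(design$n_scanners))
  scanner_offsets <- stats::rnorm(design$n_scanners, 0,
                                  design$model$scanner_offset_sd)
  n_scans <- nrow(design$samples) * design$n_scanners * design$replicates
  values <- matrix(NA_real_, n_scans, grid$n_points)
  meta <- data.frame(scan_id = character(n_scans), sample_id = character(n_scans),
                     scanner_id = character(n_scans), replicate = integer(n_scans),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(nrow(design$samples))) {
    sid <- design$samples$sample_id[i]
    fr <- design$compositions[[sid]]
    for (sc in seq_len(design$n_scanners)) {
      for (rep_i in seq_len(design$replicates)) {
        row <- row + 1L
        values[row, ] <- simulate_scan(fr, design$signatures, design$model,
                                       scanner_offset = scanner_offsets[sc],
                                       grid = grid)
        meta$scan_id[row] <- sprintf("%s_%s_r%d", sid, scanner_ids[sc], rep_i)
        meta$sample_id[row] <- sid
        meta$scanner_id[row] <- scanner_ids[sc]
        meta$replicate[row] <- rep_i
      }
    }
  }
  # spike corruption is a post-pass on its own random draws, so the clean
  # scan values of a design are identical whether or not injection is on
  corrupted <- character(0)
  if (design$outlier_rate > 0) {
    hit <- which(stats::runif(n_scans) < design$outlier_rate)
    for (row in hit) {
      start <- sample.int(grid$n_points - design$model$spike_width + 1L, 1)
      win <- start:(start + design$model$spike_width - 1L)
      values[row, win] <- values[row, win] + design$model$spike_magnitude
    }
    corrupted <- meta$scan_id[hit]
  }
  colnames(values) <- wavelength_colnames(grid)
  list(scans = new_nir_scans(meta, values, grid),
       sample_meta = design$samples,
       corrupted = corrupted)
}

# ---------------------------------------------------------------------------
# Frozen benchmark: signatures and design used throughout the test suite.

#' Frozen synthetic component signatures
#'
#' The fixed set of synthetic pure-component signatures used by the
#' benchmark design: the two cocaine forms (spectrally distinct inside the
#' 839-939 nm region) and eight adulterant/diluent stand-ins. Band
#' parameters are frozen constants chosen so that, after SNV +
#' first-derivative preprocessing, all pairwise component distances clear
#' the kNN acceptance threshold while mixtures differing by one ladder step
#' remain matchable.
#'
#' @return Named list of [component_signature()] objects.
#' @export
benchmark_signatures <- function() {
  sig <- function(...) component_signature(...)
  list(
    cocaine_hcl = sig("cocaine_hcl",
                      band_centers = c(795, 875, 905, 990, 1035),
                      band_widths = c(30, 22, 26, 35, 40),
                      band_amplitudes = c(0.35, 0.55, 0.40, 0.30, 0.25),
                      baseline_slope = -0.0008, baseline_level = 1.20),
    cocaine_base = sig("cocaine_base",
                       band_centers = c(760, 845, 880, 920, 1010),
                       band_widths = c(28, 24, 30, 26, 45),
                       band_amplitudes = c(0.30, 0.50, 0.35, 0.45, 0.20),
                       baseline_slope = -0.0006, baseline_level = 1.10),
    caffeine = sig("caffeine",
                   band_centers = c(780, 855, 960, 1040),
                   band_widths = c(35, 40, 30, 38),
                   band_amplitudes = c(0.45, 0.30, 0.50, 0.30),
                   baseline_slope = -0.0010, baseline_level = 1.30),
    lactose = sig("lactose",
                  band_centers = c(770, 910, 975, 1050),
                  band_widths = c(40, 45, 28, 35),
                  band_amplitudes = c(0.35, 0.40, 0.45, 0.30),
                  baseline_slope = -0.0005, baseline_level = 1.15),
    acetaminophen = sig("acetaminophen",
                        band_centers = c(800, 865, 935, 1005),
                        band_widths = c(30, 35, 32, 40),
                        band_amplitudes = c(0.50, 0.35, 0.45, 0.30),
                        baseline_slope = -0.0012, baseline_level = 1.25),
    levamisole = sig("levamisole",
                     band_centers = c(765, 830, 895, 970, 1045),
                     band_widths = c(30, 28, 38, 33, 30),
                     band_amplitudes = c(0.30, 0.45, 0.35, 0.40, 0.25),
                     baseline_slope = -0.0007, baseline_level = 1.20),
    phenacetin = sig("phenacetin",
                     band_centers = c(785, 850, 925, 1000),
                     band_widths = c(26, 34, 30, 36),
                     band_amplitudes = c(0.40, 0.50, 0.30, 0.35),
                     baseline_slope = -0.0009, baseline_level = 1.10),
    lidocaine = sig("lidocaine",
                    band_centers = c(775, 840, 915, 985, 1055),
                    band_widths = c(32, 30, 28, 35, 30),
                    band_amplitudes = c(0.35, 0.30, 0.50, 0.30, 0.20),
                    baseline_slope = -0.0006, baseline_level = 1.20),
    inositol = sig("inositol",
                   band_centers = c(790, 870, 950, 1025),
                   band_widths = c(38, 32, 36, 30),
                   band_amplitudes = c(0.30, 0.45, 0.35, 0.40),
                   baseline_slope = -0.0008, baseline_level = 1.15),
    mannitol = sig("mannitol",
                   band_centers = c(760, 885, 945, 1015, 1060),
                   band_widths = c(30, 36, 30, 32, 25),
                   band_amplitudes = c(0.25, 0.40, 0.45, 0.30, 0.20),
                   baseline_slope = -0.0010, baseline_level = 1.25)
  )
}

#' Signature of a compound absent from the benchmark library
#'
#' A synthetic stand-in for a novel compound (e.g. a new psychoactive
#' substance) that the screening model has never seen; used to exercise the
#' kNN abstention behaviour.
#'
#' @return A [component_signature()].
#' @export
novel_signature <- function() {
  component_signature("novel_compound",
                      band_centers = c(810, 860, 940, 995, 1050),
                      band_widths = c(25, 30, 34, 28, 32),
                      band_amplitudes = c(0.45, 0.25, 0.40, 0.50, 0.30),
                      baseline_slope = -0.0011, baseline_level = 1.20)
}

# One dilution-ladder sample row + composition.
ladder_samples <- function(coc_comp, diluent, wt_vec, form, tag, prefix) {
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", prefix, seq_along(wt_vec)),
    identity = ifelse(wt_vec > 0,
                      paste0(if (form == "hcl") "cocaine HCl" else "cocaine base",
                             " in ", diluent),
                      diluent),
    cocaine_form = ifelse(wt_vec > 0, form, "none"),
    cocaine_wt_pct = wt_vec,
    set_tag = tag,
    stringsAsFactors = FALSE
  )
  compositions <- lapply(wt_vec, function(wt) {
    f <- wt / 100
    if (f == 0) stats::setNames(1, diluent)
    else if (f == 1) stats::setNames(1, coc_comp)
    else stats::setNames(c(f, 1 - f), c(coc_comp, diluent))
  })
  names(compositions) <- samples$sample_id
  list(samples = samples, compositions = compositions)
}

#' Frozen benchmark design
#'
#' The documented benchmark data set used by the test suite and the
#' acceptance script: 72 samples scanned on 5 scanners with 5 replicates
#' each (1800 scans). The sample plan echoes the structure of a reference
#' dilution-ladder study: cocaine HCl ladders in caffeine
#' (42/34/30/25/20/19/10/5/0 wt%), lactose (81/76/44/33/17/9/0),
#' acetaminophen (48/26/17/10/6/0) and inositol (100 down to 0 in 10 wt%
#' steps); cocaine base ladders in caffeine (95/85/70/55/40/31) and lactose
#' (99/90/75/60/45); the eight pure negative components; and eight
#' equal-weight negative mixtures. Negative compositions each occur in two
#' independent samples (cutting agents recur across seizures), so the
#' abstaining kNN submodel only falls back to the neural-network path for
#' compositions genuinely absent from the library.
#'
#' @param seed Integer seed (default 20, the frozen benchmark seed).
#' @param outlier_rate Spike-corruption probability per scan (default 0).
#' @param model A [measurement_model()] (defaults are the calibrated
#'   benchmark noise levels).
#' @return A [library_design()].
#' @export
benchmark_design <- function(seed = 20, outlier_rate = 0,
                             model = measurement_model()) {
  sigs <- benchmark_signatures()
  parts <- list(
    ladder_samples("cocaine_hcl", "caffeine",
                   c(42, 34, 30, 25, 20, 19, 10, 5, 0), "hcl", "REF", "hc_caf"),
    ladder_samples("cocaine_hcl", "lactose",
                   c(81, 76, 44, 33, 17, 9, 0), "hcl", "REF", "hc_lac"),
    ladder_samples("cocaine_hcl", "acetaminophen",
                   c(48, 26, 17, 10, 6, 0), "hcl", "REF", "hc_ace"),
    ladder_samples("cocaine_hcl", "inositol",
                   seq(100, 0, by = -10), "hcl", "VAL", "hc_ino"),
    ladder_samples("cocaine_base", "caffeine",
                   c(95, 85, 70, 55, 40, 31), "base", "A", "cb_caf"),
    ladder_samples("cocaine_base", "lactose",
                   c(99, 90, 75, 60, 45), "base", "A", "cb_lac")
  )
  pure_negatives <- c("levamisole", "phenacetin", "lidocaine", "mannitol",
                      "caffeine", "lactose", "acetaminophen", "inositol")
  # the first four adulterants have no 0 wt% ladder twin, so a second
  # independently seized sample of each keeps every library composition
  # represented by more than one sample (common cutting agents recur)
  neg_ids <- c(sprintf("neg_%s", pure_negatives),
               sprintf("neg2_%s", pure_negatives[1:4]))
  neg_components <- c(pure_negatives, pure_negatives[1:4])
  neg_samples <- data.frame(
    sample_id = neg_ids,
    identity = neg_components,
    cocaine_form = "none", cocaine_wt_pct = 0, set_tag = "B",
    stringsAsFactors = FALSE
  )
  neg_comp <- lapply(neg_components, function(nm) stats::setNames(1, nm))
  names(neg_comp) <- neg_samples$sample_id
  mixtures <- list(
    c("acetaminophen", "caffeine"), c("acetaminophen", "phenacetin"),
    c("levamisole", "lidocaine"), c("levamisole", "phenacetin"),
    c("phenacetin", "lidocaine"),
    c("levamisole", "acetaminophen", "lidocaine"),
    c("mannitol", "inositol"), c("caffeine", "lactose")
  )
  # every prepared mixture also occurs twice, for the same reason
  mixtures <- c(mixtures, mixtures)
  mix_samples <- data.frame(
    sample_id = c(sprintf("mix_%02d", 1:8), sprintf("mix2_%02d", 1:8)),
    identity = vapply(mixtures, paste, character(1), collapse = ":"),
    cocaine_form = "none", cocaine_wt_pct = 0, set_tag = "B",
    stringsAsFactors = FALSE
  )
  mix_comp <- lapply(mixtures, function(m) {
    stats::setNames(rep(1 / length(m), length(m)), m)
  })
  names(mix_comp) <- mix_samples$sample_id
  samples <- rbind(do.call(rbind, lapply(parts, `[[`, "samples")),
                   neg_samples, mix_samples)
  compositions <- c(do.call(c, lapply(parts, `[[`, "compositions")),
                    neg_comp, mix_comp)
  names(compositions) <- samples$sample_id
  library_design(sigs, samples, compositions, n_scanners = 5, replicates = 5,
                 model = model, outlier_rate = outlier_rate, seed = seed)
}
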