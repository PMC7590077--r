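# Scan-wise preprocessing: SNV normalisation, fused Savitzky-Golay
# smoothing + derivative, and region-of-interest selection.
#
# Order of operations for the screening models is always
# snv() -> savgol_derivative() -> select_roi(), applied per scan.

#' Preprocessing configuration
#'
#' Bundles the preprocessing choices shared by all models: derivative order,
#' Savitzky-Golay window and polynomial order, and whether to restrict to the
#' cocaine-selective region of interest (ROI). The ROI bounds are tied to the
#' derivative order: 839-939 nm for first-derivative spectra and 839-914 nm
#' for second-derivative spectra.
#'
#' @param derivative_order 1 or 2.
#' @param sg_window Savitzky-Golay window length in data points; odd,
#'   default 19.
#' @param sg_polyorder Degree of the local polynomial fit; must be at least
#'   `derivative_order` and less than `sg_window`. Default 3.
#' @param roi Logical; restrict to the region of interest?
#' @param roi_bounds_nm Length-2 numeric ROI bounds; derived from
#'   `derivative_order` when `NULL`.
#' @param snv_sd `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(derivative_order = 1, sg_window = 19,
                              sg_polyorder = 3, roi = FALSE,
                              roi_bounds_nm = NULL,
                              snv_sd = c("sample", "population")) {
  snv_sd <- match.arg(snv_sd)
  if (!derivative_order %in% c(1, 2)) {
    stop("derivative_order must be 1 or 2", call. = FALSE)
  }
  if (sg_window %% 2 != 1 || sg_window < sg_polyorder + 2) {
    stop("sg_window must be odd and > sg_polyorder + 1", call. = FALSE)
  }
  if (sg_polyorder < derivative_order) {
    stop("sg_polyorder must be >= derivative_order", call. = FALSE)
  }
  if (is.null(roi_bounds_nm)) {
    roi_bounds_nm <- if (derivative_order == 1) c(839, 939) else c(839, 914)
  }
  if (length(roi_bounds_nm) != 2 || roi_bounds_nm[1] >= roi_bounds_nm[2]) {
    stop("roi_bounds_nm must be an increasing interval", call. = FALSE)
  }
  structure(
    list(derivative_order = as.integer(derivative_order),
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         roi = isTRUE(roi),
         roi_bounds_nm = roi_bounds_nm,
         snv_sd = snv_sd),
    class = "preprocess_config"
  )
}

preprocess_tag <- function(config) {
  sprintf("snv-d%d-w%d-p%d%s", config$derivative_order, config$sg_window,
          config$sg_polyorder, if (config$roi) "-roi" else "")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("<preprocess_config> %s (ROI %g-%g nm %s)\n", preprocess_tag(x),
              x$roi_bounds_nm[1], x$roi_bounds_nm[2],
              if (x$roi) "on" else "off"))
  invisible(x)
}

#' Standard normal variate normalisation
#'
#' Centers each spectrum to mean 0 and scales it to unit standard deviation,
#' removing additive baseline offsets and multiplicative scatter effects:
#' `snv(a * x + b)` equals `snv(x)` for any `a > 0`.
#'
#' @param x Numeric vector (one spectrum) or a scans-by-wavelength matrix
#'   (normalised row-wise).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Normalised vector or matrix of the same shape.
#' @examples
#' snv(c(1, 2, 3)) # -1 0 1
#' @export
snv <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, snv_vector, sd_type = sd_type))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  snv_vector(x, sd_type)
}

snv_vector <- function(x, sd_type) {
  if (length(x) < 2) stop("SNV needs at least 2 points", call. = FALSE)
  if (any(!is.finite(x))) stop("SNV input must be finite", call. = FALSE)
  centered <- x - mean(x)
  denom <- if (sd_type == "sample") length(x) - 1 else length(x)
  s <- sqrt(sum(centered^2) / denom)
  if (s == 0) {
    stop("degenerate spectrum: zero variance, cannot SNV-normalise", call. = FALSE)
  }
  centered / s
}

# Central Savitzky-Golay convolution coefficients for the fused
# smoothing + derivative filter (local polynomial fit, evaluated at the
# window centre). Taken from the filter matrix of signal::sgolay; the
# middle row applied to a centred window estimates the m-th derivative
# per unit grid step.
savgol_coefficients <- function(window, polyorder, deriv) {
  fm <- signal::sgolay(p = polyorder, n = window, m = deriv)
  coefs <- fm[(window + 1) / 2, ]
  as.numeric(coefs)
}

#' Savitzky-Golay derivative
#'
#' Fused smoothing and differentiation: fits a local polynomial of degree
#' `sg_polyorder` in a `sg_window`-point window around each interior grid
#' point and returns the derivative of that fit, in units per nm. The
#' `(sg_window - 1) / 2` edge points on each side are dropped rather than
#' extrapolated, so a 331-point spectrum with the default 19-point window
#' yields 313 interior values (749-1061 nm on the standard grid).
#'
#' @param x Numeric vector (one spectrum) or scans-by-wavelength matrix.
#' @param config A [preprocess_config()].
#' @param step_nm Grid spacing in nm (default 1).
#' @return Derivative values at the interior points; same class as `x`.
#' @export
savgol_derivative <- function(x, config = preprocess_config(), step_nm = 1) {
  w <- config$sg_window
  half <- (w - 1L) / 2L
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < w) {
    stop(sprintf("spectrum has %d points, shorter than the %d-point window", n, w),
         call. = FALSE)
  }
  h <- savgol_coefficients(w, config$sg_polyorder, config$derivative_order) /
    step_nm^config$derivative_order
  n_out <- n - 2L * half
  if (is.matrix(x)) {
    out <- matrix(0, nrow(x), n_out)
    for (k in seq_len(w)) {
      out <- out + h[k] * x[, k:(k + n_out - 1L), drop = FALSE]
    }
    rownames(out) <- rownames(x)
    return(out)
  }
  out <- numeric(n_out)
  for (k in seq_len(w)) out <- out + h[k] * x[k:(k + n_out - 1L)]
  out
}

# Wavelengths remaining after edge trimming by the derivative filter.
interior_wavelengths <- function(wavelengths, config) {
  half <- (config$sg_window - 1L) / 2L
  wavelengths[(half + 1L):(length(wavelengths) - half)]
}

#' Region-of-interest selection
#'
#' Restricts a (derivative) spectrum to the wavelengths inside the configured
#' ROI, inclusive on both bounds. With `roi = FALSE` in the config the input
#' is returned unchanged.
#'
#' @param x Numeric vector or matrix of values aligned with `wavelengths`.
#' @param wavelengths Wavelengths (nm) of the columns/elements of `x`.
#' @param config A [preprocess_config()].
#' @return The values inside the ROI, with attribute `"wavelengths"` updated;
#'   matrices are subset column-wise.
#' @export
select_roi <- function(x, wavelengths, config) {
  if (!config$roi) return(x)
  keep <- wavelengths >= config$roi_bounds_nm[1] &
    wavelengths <= config$roi_bounds_nm[2]
  if (!any(keep)) {
    stop("ROI does not intersect the available wavelengths", call. = FALSE)
  }
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
}

#' Preprocess a spectral library
#'
#' Applies SNV, the Savitzky-Golay derivative and (optionally) ROI selection
#' scan-wise to a raw library, preserving row and metadata alignment. The
#' resulting library's `preprocess_tag` records the configuration; models
#' refuse to mix artifacts with different tags.
#'
#' @param library A raw `nir_library` from [build_library()].
#' @param config A [preprocess_config()].
#' @return A preprocessed `nir_library` whose `wavelengths` reflect edge
#'   trimming and ROI selection.
#' @export
preprocess_library <- function(library, config = preprocess_config()) {
  stopifnot(inherits(library, "nir_library"))
  x <- library$matrix
  snv_mat <- withCallingHandlers(
    tryCatch(snv(x, sd_type = config$snv_sd), error = function(e) {
      # re-raise degenerate-spectrum errors with scan context
      bad <- which(apply(x, 1, stats::sd) == 0)
      if (length(bad) > 0) {
        stop("degenerate (flat-line) scan(s): ",
             paste(library$scan_meta$scan_id[bad], collapse = ", "),
             call. = FALSE)
      }
      stop(e)
    }),
    warning = function(w) w
  )
  step <- library$wavelengths[2] - library$wavelengths[1]
  deriv <- savgol_derivative(snv_mat, config, step_nm = step)
  wl <- interior_wavelengths(library$wavelengths, config)
  out <- select_roi(deriv, wl, config)
  wl_out <- select_roi(wl, wl, config)
  colnames(out) <- wavelength_colnames(list(wavelengths = wl_out))
  res <- library
  res$matrix <- out
  res$wavelengths <- wl_out
  res$grid <- NULL
  res$preprocess_tag <- preprocess_tag(config)
  res
}
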