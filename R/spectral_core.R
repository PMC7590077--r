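# Data model for scans, sample metadata and spectral libraries.
#
# A scan is one diffuse-reflectance measurement: 331 reflectance values on
# the fixed 740-1070 nm / 1 nm grid of the handheld sensor, plus scan,
# sample and scanner identifiers. A library is the aligned scans-by-
# wavelength matrix joined to per-sample metadata (identity, cocaine form,
# cocaine weight percentage).

#' Wavelength grid of a spectral library
#'
#' Constructs the regular wavelength grid that all spectra in one library
#' must share. The default is the 740-1070 nm range at 1 nm resolution
#' (331 points) of the handheld short-range NIR sensor the package targets.
#'
#' @param start_nm First wavelength in nm.
#' @param end_nm Last wavelength in nm.
#' @param step_nm Grid spacing in nm; must divide `end_nm - start_nm`.
#' @return An object of class `wavelength_grid`: a list with `start_nm`,
#'   `end_nm`, `step_nm`, `n_points` and the `wavelengths` vector.
#' @examples
#' g <- wavelength_grid()
#' g$n_points # 331
#' @export
wavelength_grid <- function(start_nm = 740, end_nm = 1070, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(step_nm) ||
      length(start_nm) != 1L || length(end_nm) != 1L || length(step_nm) != 1L) {
    stop("grid parameters must be single numbers", call. = FALSE)
  }
  if (step_nm <= 0 || end_nm <= start_nm) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  n <- (end_nm - start_nm) / step_nm + 1
  if (abs(n - round(n)) > 1e-8) {
    stop("step_nm does not evenly divide the wavelength range", call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         n_points = n,
         wavelengths = seq(start_nm, end_nm, by = step_nm)),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d points\n",
              x$start_nm, x$end_nm, x$step_nm, x$n_points))
  invisible(x)
}

grid_from_wavelengths <- function(w) {
  if (length(w) < 2L) stop("grid needs at least two wavelengths", call. = FALSE)
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
  steps <- diff(w)
  if (max(steps) - min(steps) > 1e-6) {
    stop("wavelength columns are not on a regular grid", call. = FALSE)
  }
  wavelength_grid(w[1L], w[length(w)], steps[1L])
}

wavelength_colnames <- function(grid) paste0("w", format(grid$wavelengths, trim = TRUE, scientific = FALSE))

scan_id_cols <- c("scan_id", "sample_id", "scanner_id", "replicate")

new_nir_scans <- function(meta, values, grid) {
  stopifnot(nrow(meta) == nrow(values))
  rownames(values) <- meta$scan_id
  structure(list(meta = meta, values = values, grid = grid), class = "nir_scans")
}

#' Read a wide-format scan table
#'
#' Reads a CSV with one row per scan: the identifier columns `scan_id`,
#' `sample_id`, `scanner_id`, `replicate` followed by one reflectance column
#' per wavelength, named `w<nm>` (e.g. `w740` ... `w1070`). The grid is
#' inferred from the column headers and validated: it must be regular and,
#' when `grid` is supplied, identical to it.
#'
#' @param path Path to the CSV file.
#' @param grid Optional `wavelength_grid` the file must match; by default the
#'   grid is inferred from the header and only checked for regularity against
#'   the standard 740-1070/1 nm grid if it has 331 columns.
#' @return An object of class `nir_scans`: list with `meta` (data frame of
#'   identifiers), `values` (scans x wavelengths matrix) and `grid`.
#' @seealso [write_scans()], [build_library()]
#' @export
read_scans <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_ids <- setdiff(scan_id_cols, names(df))
  if (length(missing_ids) > 0) {
    stop("scan table lacks identifier column(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  wcols <- grep("^w[0-9]+(\\.[0-9]+)?$", names(df), value = TRUE)
  if (length(wcols) == 0) stop("no wavelength columns (named 'w<nm>') found", call. = FALSE)
  w <- as.numeric(sub("^w", "", wcols))
  ord <- order(w)
  wcols <- wcols[ord]
  file_grid <- grid_from_wavelengths(w[ord])
  if (!is.null(grid)) {
    if (!identical(grid$wavelengths, file_grid$wavelengths)) {
      stop(sprintf("grid mismatch: file has %d points %g-%g nm, expected %d points %g-%g nm",
                   file_grid$n_points, file_grid$start_nm, file_grid$end_nm,
                   grid$n_points, grid$start_nm, grid$end_nm), call. = FALSE)
    }
    file_grid <- grid
  }
  meta <- df[, scan_id_cols, drop = FALSE]
  meta$scan_id <- as.character(meta$scan_id)
  meta$sample_id <- as.character(meta$sample_id)
  meta$scanner_id <- as.character(meta$scanner_id)
  meta$replicate <- as.integer(meta$replicate)
  dup <- meta$scan_id[duplicated(meta$scan_id)]
  if (length(dup) > 0) {
    stop("duplicated scan_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, wcols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[wcols], is.numeric, logical(1)))
    stop("non-numeric reflectance in column(s): ",
         paste(wcols[bad], collapse = ", "), call. = FALSE)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-finite reflectance at row %d (scan_id %s), column %s",
                 idx[1], meta$scan_id[idx[1]], wcols[idx[2]]), call. = FALSE)
  }
  colnames(vals) <- wavelength_colnames(file_grid)
  new_nir_scans(meta, vals, file_grid)
}

#' Write scans to a wide-format CSV
#'
#' Inverse of [read_scans()]: writes one row per scan with identifier columns
#' followed by `w<nm>` reflectance columns. Values round-trip exactly
#' (written with full precision).
#'
#' @param scans A `nir_scans` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  stopifnot(inherits(scans, "nir_scans"))
  chr <- matrix(sprintf("%.17g", scans$values), nrow = nrow(scans$values))
  df <- cbind(scans$meta, as.data.frame(chr, stringsAsFactors = FALSE))
  names(df) <- c(names(scans$meta), colnames(scans$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.nir_scans <- function(x, ...) {
  cat(sprintf("<nir_scans> %d scans, %d samples, grid %g-%g nm (%d points)\n",
              nrow(x$meta), length(unique(x$meta$sample_id)),
              x$grid$start_nm, x$grid$end_nm, x$grid$n_points))
  invisible(x)
}

cocaine_forms <- c("hcl", "base", "none")

#' Validate a sample-metadata table
#'
#' Checks the per-sample ground-truth table used to label a library:
#' one row per sample with its qualitative identity, cocaine form
#' (`"hcl"`, `"base"` or `"none"`) and cocaine content in weight percent.
#' A sample with `cocaine_form == "none"` must have 0 wt% and vice versa.
#'
#' @param df Data frame with columns `sample_id`, `identity`, `cocaine_form`,
#'   `cocaine_wt_pct`, `set_tag`.
#' @return The validated data frame (character/numeric types coerced).
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "identity", "cocaine_form", "cocaine_wt_pct", "set_tag")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("sample metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, req, drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$identity <- as.character(df$identity)
  df$cocaine_form <- as.character(df$cocaine_form)
  df$set_tag <- as.character(df$set_tag)
  df$cocaine_wt_pct <- as.numeric(df$cocaine_wt_pct)
  if (nrow(df) == 0) return(df)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_form <- !df$cocaine_form %in% cocaine_forms
  if (any(bad_form)) {
    stop("invalid cocaine_form for sample(s): ",
         paste(df$sample_id[bad_form], collapse = ", "),
         " (must be one of hcl/base/none)", call. = FALSE)
  }
  out_of_range <- is.na(df$cocaine_wt_pct) | df$cocaine_wt_pct < 0 | df$cocaine_wt_pct > 100
  if (any(out_of_range)) {
    stop("cocaine_wt_pct outside [0, 100] for sample(s): ",
         paste(df$sample_id[out_of_range], collapse = ", "), call. = FALSE)
  }
  inconsistent <- (df$cocaine_form == "none") != (df$cocaine_wt_pct == 0)
  if (any(inconsistent)) {
    stop("cocaine_form/cocaine_wt_pct inconsistent (none <=> 0 wt%) for sample(s): ",
         paste(df$sample_id[inconsistent], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a sample-metadata CSV
#'
#' @param path Path to a CSV with columns `sample_id`, `identity`,
#'   `cocaine_form`, `cocaine_wt_pct`, `set_tag`.
#' @return Validated sample-metadata data frame (see [sample_metadata()]).
#'   An empty file yields an empty data frame with a warning.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) warning("sample metadata file is empty: ", path, call. = FALSE)
  sample_metadata(df)
}

#' Write a sample-metadata CSV
#'
#' @param meta Validated sample-metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a labelled spectral library
#'
#' Joins scans to their sample metadata into the container all models in the
#' package consume: an aligned scans-by-wavelength matrix, per-scan
#' identifiers, keyed per-sample metadata and a `preprocess_tag` recording
#' what has been applied to the matrix (`"raw"` on assembly).
#'
#' @param scans A `nir_scans` object.
#' @param meta Sample-metadata data frame (validated by [sample_metadata()]).
#' @return An object of class `nir_library`.
#' @export
build_library <- function(scans, meta) {
  stopifnot(inherits(scans, "nir_scans"))
  meta <- sample_metadata(meta)
  orphans <- setdiff(scans$meta$sample_id, meta$sample_id)
  if (length(orphans) > 0) {
    bad <- scans$meta$scan_id[scans$meta$sample_id %in% orphans]
    stop("scans reference unknown sample_id(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "",
         call. = FALSE)
  }
  structure(
    list(matrix = scans$values,
         wavelengths = scans$grid$wavelengths,
         grid = scans$grid,
         scan_meta = scans$meta,
         sample_meta = meta,
         preprocess_tag = "raw"),
    class = "nir_library"
  )
}

#' @export
print.nir_library <- function(x, ...) {
  cat(sprintf("<nir_library> %d scans x %d variables, %d samples, preprocess: %s\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$sample_meta), x$preprocess_tag))
  invisible(x)
}

# Lookup of per-scan sample metadata aligned to the library rows.
library_scan_truth <- function(library) {
  idx <- match(library$scan_meta$sample_id, library$sample_meta$sample_id)
  cbind(library$scan_meta, library$sample_meta[idx, -1, drop = FALSE],
        row.names = NULL)
}
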