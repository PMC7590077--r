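# Submodel A: PCA score-distance outlier flagging and the dual
# Euclidean-distance / Pearson-correlation k-nearest-neighbour matcher
# with abstention thresholds, identity voting and neighbour-averaged
# concentration.

#' Outlier-flagging configuration
#'
#' Controls PCA score-distance outlier flagging of replicate scans. A PCA is
#' fitted on the whole preprocessed library (mean-centred, unscaled); each
#' scan's mean Euclidean distance to the other scans of the same sample is
#' computed in the space of the first `n_components` scores, and scans whose
#' mean distance lies strictly above the `quantile` empirical quantile are
#' flagged.
#'
#' @param n_components Number of leading principal components (default 3).
#' @param quantile Flagging quantile (default 0.99).
#' @param scope `"pooled"` (default): the quantile is taken over the per-scan
#'   mean distances of the whole library; `"per_sample"`: over each sample's
#'   own scans only. The pooled rule flags only scans that are extreme
#'   relative to the library-wide replicate spread rather than one scan per
#'   sample regardless of spread.
#' @return An object of class `outlier_config`.
#' @export
outlier_config <- function(n_components = 3, quantile = 0.99,
                           scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)", call. = FALSE)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  structure(list(n_components = as.integer(n_components), quantile = quantile,
                 scope = scope),
            class = "outlier_config")
}

#' Flag outlying replicate scans
#'
#' @param library A preprocessed `nir_library`.
#' @param config An [outlier_config()].
#' @return Logical vector (one element per library row, named by scan_id)
#'   with attribute `"mean_distance"` holding the per-scan mean within-sample
#'   score distances. Samples with a single scan are never flagged.
#' @export
flag_outliers <- function(library, config = outlier_config()) {
  stopifnot(inherits(library, "nir_library"))
  x <- library$matrix
  k <- min(config$n_components, ncol(x), nrow(x) - 1L)
  if (k < config$n_components) {
    warning(sprintf("PCA rank limited to %d components", k), call. = FALSE)
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  sample_id <- library$scan_meta$sample_id
  mean_dist <- rep(NA_real_, nrow(x))
  for (sid in unique(sample_id)) {
    rows <- which(sample_id == sid)
    if (length(rows) < 2) next
    d <- as.matrix(stats::dist(scores[rows, , drop = FALSE]))
    mean_dist[rows] <- rowSums(d) / (length(rows) - 1L)
  }
  flagged <- rep(FALSE, nrow(x))
  if (config$scope == "pooled") {
    q <- stats::quantile(mean_dist, config$quantile, na.rm = TRUE, names = FALSE)
    flagged <- !is.na(mean_dist) & mean_dist > q
  } else {
    for (sid in unique(sample_id)) {
      rows <- which(sample_id == sid)
      if (length(rows) < 2) next
      q <- stats::quantile(mean_dist[rows], config$quantile, names = FALSE)
      flagged[rows] <- mean_dist[rows] > q
    }
  }
  names(flagged) <- library$scan_meta$scan_id
  attr(flagged, "mean_distance") <- mean_dist
  flagged
}

#' kNN matcher configuration
#'
#' @param k_distance Neighbours kept by smallest Euclidean distance
#'   (default 9).
#' @param k_correlation Neighbours kept by highest Pearson correlation
#'   (default 9).
#' @param max_distance Acceptance threshold: neighbours must have distance
#'   `<= max_distance` (default 0.1; tuned for SNV + first-derivative full
#'   spectra).
#' @param min_correlation Acceptance threshold: neighbours must have
#'   correlation `>= min_correlation` (default 0.98).
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(k_distance = 9, k_correlation = 9,
                       max_distance = 0.1, min_correlation = 0.98) {
  if (k_distance < 1 || k_correlation < 1) stop("k must be >= 1", call. = FALSE)
  if (max_distance <= 0) stop("max_distance must be positive", call. = FALSE)
  if (min_correlation < -1 || min_correlation > 1) {
    stop("min_correlation must be in [-1, 1]", call. = FALSE)
  }
  structure(list(k_distance = as.integer(k_distance),
                 k_correlation = as.integer(k_correlation),
                 max_distance = max_distance,
                 min_correlation = min_correlation),
            class = "knn_config")
}

# Rows of `m` standardised for Pearson correlation: centred, unit norm.
pearson_standardize <- function(m) {
  c_m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(c_m^2))
  nrm[nrm == 0] <- NA_real_
  c_m / nrm
}

#' Query the dual kNN matcher
#'
#' Ranks library scans against a query spectrum by Euclidean distance and by
#' Pearson correlation, keeping up to `k_distance` / `k_correlation`
#' neighbours that pass the acceptance thresholds. Scans of excluded samples
#' (e.g. the query's own sample during leave-one-sample-out cross-validation)
#' never enter the ranking. Ties are broken by library row order.
#'
#' @param query Preprocessed spectrum (numeric vector matching the library
#'   width).
#' @param library Preprocessed `nir_library`.
#' @param config A [knn_config()].
#' @param exclude_samples Character vector of sample_ids to remove before
#'   ranking.
#' @param exclude_rows Logical mask of library rows to remove (e.g. outliers).
#' @return An object of class `neighbor_set`: list with data frames
#'   `by_distance` (columns `row`, `scan_id`, `sample_id`, `distance`) sorted
#'   ascending and `by_correlation` (with `correlation`) sorted descending;
#'   both may have zero rows.
#' @export
query_neighbors <- function(query, library, config = knn_config(),
                            exclude_samples = character(),
                            exclude_rows = NULL) {
  stopifnot(inherits(library, "nir_library"))
  if (length(query) != ncol(library$matrix)) {
    stop("query width does not match library width", call. = FALSE)
  }
  keep <- !(library$scan_meta$sample_id %in% exclude_samples)
  if (!is.null(exclude_rows)) keep <- keep & !exclude_rows
  rows <- which(keep)
  empty <- data.frame(row = integer(), scan_id = character(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (length(rows) == 0) {
    return(structure(list(
      by_distance = cbind(empty, distance = numeric()),
      by_correlation = cbind(empty, correlation = numeric())
    ), class = "neighbor_set"))
  }
  lib <- library$matrix[rows, , drop = FALSE]
  diffs <- sweep(lib, 2, query)
  d <- sqrt(rowSums(diffs^2))
  qz <- query - mean(query)
  qn <- sqrt(sum(qz^2))
  lz <- pearson_standardize(lib)
  r <- if (qn == 0) rep(NA_real_, nrow(lib)) else as.numeric(lz %*% (qz / qn))
  sel_d <- which(d <= config$max_distance)
  sel_d <- sel_d[order(d[sel_d], sel_d)]
  sel_d <- utils::head(sel_d, config$k_distance)
  sel_r <- which(!is.na(r) & r >= config$min_correlation)
  sel_r <- sel_r[order(-r[sel_r], sel_r)]
  sel_r <- utils::head(sel_r, config$k_correlation)
  mk <- function(sel, extra) {
    df <- data.frame(row = rows[sel],
                     scan_id = library$scan_meta$scan_id[rows[sel]],
                     sample_id = library$scan_meta$sample_id[rows[sel]],
                     stringsAsFactors = FALSE)
    cbind(df, extra)
  }
  structure(list(
    by_distance = mk(sel_d, data.frame(distance = d[sel_d])),
    by_correlation = mk(sel_r, data.frame(correlation = r[sel_r],
                                          distance = d[sel_r]))
  ), class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("<neighbor_set> %d by distance, %d by correlation\n",
              nrow(x$by_distance), nrow(x$by_correlation)))
  invisible(x)
}

#' Predict identity and concentration from accepted neighbours
#'
#' Combines the distance- and correlation-accepted neighbours into one
#' multiset (a scan accepted by both metrics counts twice, so at most
#' `k_distance + k_correlation` votes), predicts the modal identity (ties
#' broken by the smallest mean neighbour distance among tied identities) and
#' the arithmetic-mean cocaine concentration of the multiset. An empty
#' multiset yields an abstaining `no_match` result.
#'
#' @param neighbors A `neighbor_set` from [query_neighbors()].
#' @param sample_meta Sample-metadata data frame resolving the neighbours'
#'   `sample_id`s.
#' @return An object of class `knn_result`: list with `status` (`"ok"` or
#'   `"no_match"`), `predicted_identity`, `predicted_conc` (both `NA` on
#'   `no_match`), `n_neighbors` and the `neighbor_set`.
#' @export
knn_predict <- function(neighbors, sample_meta) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  combined <- rbind(
    neighbors$by_distance[, c("row", "scan_id", "sample_id", "distance")],
    neighbors$by_correlation[, c("row", "scan_id", "sample_id", "distance")]
  )
  if (nrow(combined) == 0) {
    return(structure(list(status = "no_match", predicted_identity = NA_character_,
                          predicted_conc = NA_real_, n_neighbors = 0L,
                          neighbor_set = neighbors),
                     class = "knn_result"))
  }
  idx <- match(combined$sample_id, sample_meta$sample_id)
  if (anyNA(idx)) {
    stop("neighbour sample_id(s) not in metadata: ",
         paste(unique(combined$sample_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  identity <- sample_meta$identity[idx]
  conc <- sample_meta$cocaine_wt_pct[idx]
  votes <- table(identity)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    mean_d <- vapply(top, function(id) mean(combined$distance[identity == id]),
                     numeric(1))
    top <- top[which.min(mean_d)]
  }
  structure(list(status = "ok", predicted_identity = top,
                 predicted_conc = mean(conc),
                 n_neighbors = nrow(combined),
                 neighbor_set = neighbors),
            class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  if (x$status == "no_match") {
    cat("<knn_result> no_match (no neighbours within thresholds)\n")
  } else {
    cat(sprintf("<knn_result> %s, %.1f wt%% (%d neighbours)\n",
                x$predicted_identity, x$predicted_conc, x$n_neighbors))
  }
  invisible(x)
}

# Vectorised leave-one-sample-out kNN over a whole library: computes the
# full pairwise distance and correlation matrices once and, for each scan,
# ranks all non-outlier scans of other samples. Returns one row per scan
# (including outliers, which are queried but never serve as neighbours).
knn_loso <- function(library, config = knn_config(), outlier_mask = NULL) {
  x <- library$matrix
  n <- nrow(x)
  if (is.null(outlier_mask)) outlier_mask <- rep(FALSE, n)
  sq <- rowSums(x^2)
  g <- x %*% t(x)
  d2 <- outer(sq, sq, `+`) - 2 * g
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  z <- pearson_standardize(x)
  rmat <- z %*% t(z)
  sample_id <- library$scan_meta$sample_id
  meta_idx <- match(sample_id, library$sample_meta$sample_id)
  identity <- library$sample_meta$identity[meta_idx]
  conc <- library$sample_meta$cocaine_wt_pct[meta_idx]
  res <- data.frame(scan_id = library$scan_meta$scan_id,
                    sample_id = sample_id,
                    status = character(n), predicted_identity = NA_character_,
                    predicted_conc = NA_real_, n_neighbors = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cand <- which(sample_id != sample_id[i] & !outlier_mask)
    d <- dmat[i, cand]
    r <- rmat[i, cand]
    sel_d <- cand[d <= config$max_distance]
    sel_d <- sel_d[order(dmat[i, sel_d], sel_d)]
    sel_d <- utils::head(sel_d, config$k_distance)
    sel_r <- cand[!is.na(r) & r >= config$min_correlation]
    sel_r <- sel_r[order(-rmat[i, sel_r], sel_r)]
    sel_r <- utils::head(sel_r, config$k_correlation)
    combined <- c(sel_d, sel_r)
    if (length(combined) == 0) {
      res$status[i] <- "no_match"
      next
    }
    ids <- identity[combined]
    votes <- table(ids)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(id) mean(dmat[i, combined[ids == id]]),
                       numeric(1))
      top <- top[which.min(mean_d)]
    }
    res$status[i] <- "ok"
    res$predicted_identity[i] <- top
    res$predicted_conc[i] <- mean(conc[combined])
    res$n_neighbors[i] <- length(combined)
  }
  res
}
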