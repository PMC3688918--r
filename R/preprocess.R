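#' Collapse replicate injections to per-sample medians
#'
#' Each biological sample is measured as several replicate injections; the
#' per-sample value of every feature is the median over its replicates,
#' with zeros (not detected) participating in the median. Blank injections
#' are excluded. This is the X0 -> X1 reduction of the pipeline.
#'
#' @param table an [injection_table].
#' @return A [feature_matrix] with provenance "X1": one row per biological
#'   sample, same features as the input.
#' @export
collapse_replicates <- function(table) {
  stopifnot(inherits(table, "injection_table"))
  inj <- table$injections
  samp <- inj[inj$role == "sample", , drop = FALSE]
  if (nrow(samp) == 0L) stop("no sample injections present")
  sample_ids <- unique(samp$sample_id)
  vals <- matrix(0, length(sample_ids), nrow(table$features))
  labels <- character(length(sample_ids))
  for (k in seq_along(sample_ids)) {
    cols <- which(inj$role == "sample" & inj$sample_id == sample_ids[k])
    if (length(cols) == 0L) stop("sample with zero injections: ", sample_ids[k])
    sub <- table$intensity[, cols, drop = FALSE]
    vals[k, ] <- apply(sub, 1L, stats::median)
    labels[k] <- samp$class_label[match(sample_ids[k], samp$sample_id)]
  }
  feature_matrix(sample_ids, labels, table$features, vals, provenance = "X1")
}

#' Remove background features detected in blank injections
#'
#' Features detected (intensity above `intensity_floor`) in at least
#' `min_blank_detections` blank injections are treated as background
#' (solvent contamination, carry-over) and removed. This is the X1 -> X2
#' reduction.
#'
#' @param matrix a [feature_matrix] (typically provenance "X1").
#' @param table the [injection_table] the matrix was collapsed from; its
#'   blank injections define the background.
#' @param min_blank_detections minimum number of blank injections a feature
#'   must be detected in to be removed (default 1).
#' @param intensity_floor detection threshold; intensities strictly above
#'   it count as detected (default 0).
#' @return A list with `matrix` (a [feature_matrix], provenance "X2") and
#'   `removed_ids` (character vector of removed feature ids).
#' @export
remove_blank_features <- function(matrix, table, min_blank_detections = 1L,
                                  intensity_floor = 0) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(table, "injection_table"))
  blank_cols <- which(table$injections$role == "blank")
  if (length(blank_cols) == 0L)
    stop("no blank injections present; cannot identify background features")
  ids <- matrix$features$feature_id
  blank_counts <- rowSums(table$intensity[, blank_cols, drop = FALSE] >
                            intensity_floor)
  blank_counts <- blank_counts[match(ids, table$features$feature_id)]
  drop <- !is.na(blank_counts) & blank_counts >= min_blank_detections
  keep <- which(!drop)
  out <- feature_matrix(matrix$sample_ids, matrix$class_labels,
                        matrix$features[keep, , drop = FALSE],
                        matrix$values[, keep, drop = FALSE],
                        provenance = "X2")
  list(matrix = out, removed_ids = ids[drop])
}

#' Remove low-detection-frequency features
#'
#' Features detected in fewer than `min_samples` biological samples (after
#' replicate collapsing) are unreliable markers and are removed. This is
#' the X2 -> X3 reduction.
#'
#' @param matrix a [feature_matrix] (typically provenance "X2").
#' @param min_samples minimum number of samples a feature must be detected
#'   in to be retained (default 3).
#' @return A list with `matrix` (a [feature_matrix], provenance "X3") and
#'   `removed_ids`.
#' @export
frequency_filter <- function(matrix, min_samples = 3L) {
  stopifnot(inherits(matrix, "feature_matrix"), min_samples >= 1L)
  n_det <- colSums(matrix$values > 0)
  drop <- n_det < min_samples
  keep <- which(!drop)
  out <- feature_matrix(matrix$sample_ids, matrix$class_labels,
                        matrix$features[keep, , drop = FALSE],
                        matrix$values[, keep, drop = FALSE],
                        provenance = "X3")
  list(matrix = out, removed_ids = matrix$features$feature_id[drop])
}

#' Run the full feature-table preprocessing chain
#'
#' Applies, in fixed order, replicate collapsing (X1), blank-feature
#' removal (X2) and the detection-frequency filter (X3), and reports the
#' feature counts and missing-value fractions at each stage.
#'
#' @inheritParams remove_blank_features
#' @inheritParams frequency_filter
#' @param table an [injection_table].
#' @return A list with elements `x1`, `x2`, `x3` (feature matrices) and
#'   `report`, a `preprocess_report` with fields `n_features_in`,
#'   `n_removed_blank`, `n_removed_lowfreq`, `n_features_out`,
#'   `missing_fraction_before` (zeros in X1), `missing_fraction_x2`,
#'   `missing_fraction_after` (zeros in X3) and
#'   `per_sample_detected_counts` (detected features per sample in X3).
#' @export
preprocess <- function(table, min_blank_detections = 1L, min_samples = 3L,
                       intensity_floor = 0) {
  x1 <- collapse_replicates(table)
  st2 <- remove_blank_features(x1, table, min_blank_detections,
                               intensity_floor)
  st3 <- frequency_filter(st2$matrix, min_samples)
  report <- structure(list(
    n_features_in = ncol(x1$values),
    n_removed_blank = length(st2$removed_ids),
    n_removed_lowfreq = length(st3$removed_ids),
    n_features_out = ncol(st3$matrix$values),
    missing_fraction_before = mean(x1$values == 0),
    missing_fraction_x2 = mean(st2$matrix$values == 0),
    missing_fraction_after = mean(st3$matrix$values == 0),
    per_sample_detected_counts = as.integer(rowSums(st3$matrix$values > 0))),
    class = "preprocess_report")
  stopifnot(report$n_features_out ==
              report$n_features_in - report$n_removed_blank -
              report$n_removed_lowfreq)
  list(x1 = x1, x2 = st2$matrix, x3 = st3$matrix, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocessing: ", x$n_features_in, " features -> ",
      x$n_features_in - x$n_removed_blank, " (blank removal) -> ",
      x$n_features_out, " (frequency filter)\n",
      "missing fraction: ", round(100 * x$missing_fraction_before, 1),
      "% -> ", round(100 * x$missing_fraction_after, 1), "%\n", sep = "")
  invisible(x)
}

# column means and sample (n-1) standard deviations
.scale_fit <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sds <- sqrt(colSums(xc * xc) / (n - 1L))
  list(center = ctr, scale = sds)
}

.scale_apply <- function(x, center, scale) {
  s <- ifelse(scale > 0, scale, 1)  # constant columns map to all-zero
  sweep(sweep(x, 2L, center), 2L, s, "/")
}

#' Autoscale a data matrix
#'
#' Mean-centers every column and divides it by its sample (n-1) standard
#' deviation, the pretreatment used before both PCA and PLS-DA. The
#' returned means and SDs allow applying the identical transform to
#' held-out rows.
#'
#' @param x numeric matrix or [feature_matrix].
#' @return A list with `values` (the scaled matrix), `center` and `scale`.
#'   A zero-variance column is an error naming the offending feature; drop
#'   it (see [frequency_filter()]) or jitter it first.
#' @export
autoscale <- function(x) {
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  sf <- .scale_fit(values)
  if (any(sf$scale == 0)) {
    bad <- colnames(values)[sf$scale == 0]
    if (is.null(bad)) bad <- which(sf$scale == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  list(values = .scale_apply(values, sf$center, sf$scale),
       center = sf$center, scale = sf$scale)
}

#' Quality-control metrics for an injection batch
#'
#' Computes the batch QC metrics used to accept the data: relative
#' standard deviation of the internal-standard peak area across
#' injections, per-injection signed mass error of the internal standard in
#' ppm, Pearson correlations between replicate intensity profiles of the
#' same sample, and the per-feature percent RSD across replicates.
#'
#' @param table an [injection_table]; IS metrics require its `is_channel`.
#' @param is_reference_mz theoretical m/z of the internal standard
#'   (default 609.2812, reserpine `[M+H]+`).
#' @return A `qc_report` list with `is_area_rsd` (percent, NA when no IS
#'   channel is present), `is_ppm_errors`, `replicate_correlations`
#'   (data.frame sample_id, rep_a, rep_b, r) and `feature_rsd` (per-feature
#'   percent RSD across replicates, averaged over samples where detected in
#'   all replicates).
#' @export
qc_metrics <- function(table, is_reference_mz = 609.2812) {
  stopifnot(inherits(table, "injection_table"))
  is_area_rsd <- NA_real_
  is_ppm_errors <- NULL
  if (!is.null(table$is_channel)) {
    a <- table$is_channel$area
    is_area_rsd <- 100 * stats::sd(a) / mean(a)
    is_ppm_errors <- 1e6 * (table$is_channel$mz_measured - is_reference_mz) /
      is_reference_mz
  }
  inj <- table$injections
  samp_ids <- unique(inj$sample_id[inj$role == "sample"])
  cors <- list()
  for (sid in samp_ids) {
    cols <- which(inj$role == "sample" & inj$sample_id == sid)
    if (length(cols) < 2L) next
    prs <- utils::combn(cols, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; j <- prs[2L, k]
      cors[[length(cors) + 1L]] <- data.frame(
        sample_id = sid,
        rep_a = inj$injection_id[i], rep_b = inj$injection_id[j],
        r = stats::cor(table$intensity[, i], table$intensity[, j]))
    }
  }
  cors <- if (length(cors)) do.call(rbind, cors) else NULL
  # per-feature %RSD across replicates, averaged over fully detected samples
  feat_rsd <- rep(NA_real_, nrow(table$features))
  for (f in seq_len(nrow(table$features))) {
    rsds <- c()
    for (sid in samp_ids) {
      cols <- which(inj$role == "sample" & inj$sample_id == sid)
      v <- table$intensity[f, cols]
      if (all(v > 0) && length(v) >= 2L)
        rsds <- c(rsds, 100 * stats::sd(v) / mean(v))
    }
    if (length(rsds)) feat_rsd[f] <- mean(rsds)
  }
  structure(list(is_area_rsd = is_area_rsd, is_ppm_errors = is_ppm_errors,
                 replicate_correlations = cors, feature_rsd = feat_rsd),
            class = "qc_report")
}
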