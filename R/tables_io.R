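#' @title Injection-level feature table
#'
#' @description An `injection_table` holds an aligned LC-MS marker table at
#' the injection level: one row per detected feature (retention time, m/z),
#' one column per injection (biological sample replicates and solvent
#' blanks), with zero encoding "not detected". This is the raw matrix a
#' peak-alignment tool exports, before any replicate collapsing or
#' filtering.
#'
#' @param features data.frame with columns `feature_id`, `rt` (minutes,
#'   >= 0) and `mz` (50-950 for profiling features).
#' @param injections data.frame with columns `injection_id`, `sample_id`
#'   (NA for blanks), `replicate_index`, `role` ("sample" or "blank"),
#'   `class_label` (NA for blanks) and `run_order`.
#' @param intensity numeric matrix `n_features x n_injections` of
#'   non-negative intensities; 0 means not detected.
#' @param is_channel optional data.frame with columns `injection_id`,
#'   `area` and `mz_measured` describing the internal-standard channel.
#'
#' @return An object of class `injection_table`.
#' @export
injection_table <- function(features, injections, intensity, is_channel = NULL) {
  features <- as.data.frame(features)
  injections <- as.data.frame(injections)
  intensity <- as.matrix(intensity)
  req_f <- c("feature_id", "rt", "mz")
  req_i <- c("injection_id", "sample_id", "replicate_index", "role",
             "class_label", "run_order")
  if (!all(req_f %in% names(features)))
    stop("features must have columns: ", paste(req_f, collapse = ", "))
  if (!all(req_i %in% names(injections)))
    stop("injections must have columns: ", paste(req_i, collapse = ", "))
  if (anyDuplicated(features$feature_id))
    stop("feature_id values must be unique")
  if (anyDuplicated(injections$run_order))
    stop("run_order values must be unique")
  if (nrow(intensity) != nrow(features) || ncol(intensity) != nrow(injections))
    stop("intensity must be n_features x n_injections (got ",
         nrow(intensity), "x", ncol(intensity), ")")
  if (any(intensity < 0))
    stop("intensities must be non-negative (0 = not detected)")
  if (any(features$rt < 0)) stop("retention times must be >= 0")
  bad_blank <- injections$role == "blank" &
    (!is.na(injections$sample_id) | !is.na(injections$class_label))
  if (any(bad_blank))
    stop("blank injections must have NA sample_id and class_label: ",
         paste(injections$injection_id[bad_blank], collapse = ", "))
  dimnames(intensity) <- list(features$feature_id, injections$injection_id)
  structure(list(features = features, injections = injections,
                 intensity = intensity, is_channel = is_channel),
            class = "injection_table")
}

#' @export
print.injection_table <- function(x, ...) {
  ns <- sum(x$injections$role == "sample")
  nb <- sum(x$injections$role == "blank")
  cat("injection_table: ", nrow(x$features), " features x ",
      ncol(x$intensity), " injections (", ns, " sample, ", nb, " blank)\n",
      sep = "")
  invisible(x)
}

#' Collapsed samples-by-features matrix
#'
#' A `feature_matrix` is the per-sample view of the data: one row per
#' biological sample (replicates already collapsed), one column per
#' feature, zeros encoding "not detected". `provenance` records which
#' preprocessing stage produced it: `X1` after replicate collapsing,
#' `X2` after blank-feature removal, `X3` after the detection-frequency
#' filter.
#'
#' @param sample_ids character vector of biological sample ids.
#' @param class_labels per-sample class labels (e.g. "hypoxia"/"normoxia").
#' @param features data.frame with columns `feature_id`, `rt`, `mz`.
#' @param values numeric matrix `n_samples x n_features`, 0 = not detected.
#' @param provenance one of "X1", "X2", "X3", "custom".
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(sample_ids, class_labels, features, values,
                           provenance = c("custom", "X1", "X2", "X3")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  features <- as.data.frame(features)
  if (nrow(values) != length(sample_ids))
    stop("values must have one row per sample")
  if (ncol(values) != nrow(features))
    stop("values must have one column per feature")
  if (length(class_labels) != length(sample_ids))
    stop("class_labels must match sample_ids")
  dimnames(values) <- list(sample_ids, features$feature_id)
  structure(list(sample_ids = sample_ids, class_labels = class_labels,
                 features = features, values = values,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix [", x$provenance, "]: ", nrow(x$values),
      " samples x ", ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Canonical feature id from retention time and m/z
#'
#' Renders the (rt, m/z) pair identifying an aligned feature to the fixed
#' "RT_MZ" string convention (2 decimals for rt in minutes, 4 for m/z), so
#' that literature-style references such as "0.69, 489.1157" are
#' addressable.
#'
#' @param rt retention time in minutes.
#' @param mz mass-to-charge ratio.
#' @return character vector of canonical feature ids.
#' @export
#' @examples
#' feature_id(0.69, 489.1157)
feature_id <- function(rt, mz) {
  sprintf("%.2f_%.4f", rt, mz)
}

#' Read an injection-level feature table from CSV/TSV files
#'
#' The intensity file is feature-per-row (peak-alignment export
#' convention): columns `feature_id`, `rt`, `mz`, then one column per
#' injection id. The metadata file has one row per injection with columns
#' `injection_id`, `sample_id`, `replicate_index`, `role`, `class_label`,
#' `run_order`. Injection columns are matched to metadata rows by id and
#' both sets must agree exactly.
#'
#' @param path_intensities path to the intensity CSV/TSV.
#' @param path_metadata path to the injection metadata CSV/TSV.
#' @param sep field separator, inferred from the file extension
#'   (".tsv"/".txt" = tab) when NULL.
#' @return An [injection_table].
#' @export
read_injection_table <- function(path_intensities, path_metadata, sep = NULL) {
  read1 <- function(path) {
    s <- sep
    if (is.null(s))
      s <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = s, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = c("NA", ""))
  }
  intens <- read1(path_intensities)
  meta <- read1(path_metadata)
  fixed <- c("feature_id", "rt", "mz")
  if (!all(fixed %in% names(intens)[1:3]))
    stop("intensity file must start with columns feature_id, rt, mz")
  inj_cols <- setdiff(names(intens), fixed)
  missing_meta <- setdiff(inj_cols, meta$injection_id)
  missing_cols <- setdiff(meta$injection_id, inj_cols)
  if (length(missing_meta) || length(missing_cols))
    stop("intensity columns and metadata rows disagree; ",
         "columns without metadata: [",
         paste(missing_meta, collapse = ", "),
         "]; metadata without columns: [",
         paste(missing_cols, collapse = ", "), "]")
  meta <- meta[match(inj_cols, meta$injection_id), , drop = FALSE]
  rownames(meta) <- NULL
  m <- as.matrix(intens[, inj_cols, drop = FALSE])
  storage.mode(m) <- "double"
  is_channel <- NULL
  is_rows <- grepl("^IS_", intens$feature_id)
  if (any(is_rows)) {
    # internal-standard channel stored as a pseudo-feature row IS_<mz>
    is_channel <- data.frame(
      injection_id = inj_cols,
      area = as.numeric(m[which(is_rows)[1], ]),
      mz_measured = rep(intens$mz[which(is_rows)[1]], length(inj_cols)))
    m <- m[!is_rows, , drop = FALSE]
    intens <- intens[!is_rows, , drop = FALSE]
  }
  injection_table(features = intens[, fixed], injections = meta,
                  intensity = m, is_channel = is_channel)
}

#' Write an injection-level feature table to CSV files
#'
#' Inverse of [read_injection_table()]: the intensity file keeps the
#' feature-per-row orientation verbatim, so a read/write round trip is
#' lossless for values and ordering. The internal-standard channel, when
#' present, is written to a third file.
#'
#' @param table an [injection_table].
#' @param path_intensities,path_metadata output CSV paths.
#' @param path_is_channel optional output path for the IS channel.
#' @return Invisibly, the paths written.
#' @export
write_injection_table <- function(table, path_intensities, path_metadata,
                                  path_is_channel = NULL) {
  stopifnot(inherits(table, "injection_table"))
  out <- cbind(table$features[, c("feature_id", "rt", "mz")],
               as.data.frame(table$intensity, check.names = FALSE))
  utils::write.csv(out, path_intensities, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$injections, path_metadata, row.names = FALSE,
                   quote = FALSE)
  paths <- c(path_intensities, path_metadata)
  if (!is.null(table$is_channel) && !is.null(path_is_channel)) {
    utils::write.csv(table$is_channel, path_is_channel, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, path_is_channel)
  }
  invisible(paths)
}

#' Write a pipeline result object to versioned JSON
#'
#' Serializes any pipeline result (preprocessing reports, PCA/PLS models,
#' double-cross-validation and permutation results, calibration curves) to
#' a self-describing JSON document with a schema version and the object's
#' class, with full float precision and deterministic key order.
#'
#' @param object a pipeline result (list-like S3 object).
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(object, path) {
  strip <- function(x) {
    if (is.object(x) && !is.data.frame(x) && !is.factor(x)) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) x[] <- lapply(x, strip)
    x
  }
  payload <- strip(object)
  doc <- list(schema = "hypoxmet/1",
              class = paste(class(object), collapse = ","),
              payload = payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a pipeline result written by [write_results()]
#'
#' @param path path to a JSON document produced by [write_results()].
#' @return The stored payload with its original S3 class restored.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !identical(doc$schema, "hypoxmet/1"))
    stop("not a hypoxmet results document: ", path)
  out <- doc$payload
  class(out) <- strsplit(doc$class, ",", fixed = TRUE)[[1]]
  out
}
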