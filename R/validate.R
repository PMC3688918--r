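#' Leave-one-out double cross-validation of a PLS-DA model
#'
#' Nested cross-validation giving out-of-fold figures of merit: the outer
#' loop leaves each sample out in turn; the inner loop (a second
#' leave-one-out on the remaining samples, via [select_n_lv()]) chooses
#' the number of latent variables; the model refit on the outer training
#' set then predicts the held-out sample. The aggregated out-of-fold
#' predictions yield dQ2 and NMC, and the mean of the outer-fold
#' regression vectors is the statistic used for variable selection.
#'
#' @param x matrix or [feature_matrix], original units.
#' @param y class labels (taken from `x` when it is a [feature_matrix]
#'   and `y` is missing).
#' @param lv_max ceiling on latent variables (default 3).
#' @param autoscale refit autoscaling inside every fold (default TRUE).
#' @return A `dcv_result` with `folds` (data.frame: held-out sample id,
#'   chosen `n_lv`, out-of-fold `prediction` on the 0/1 scale, true
#'   `y`), `dq2`, `nmc`, `b_mean` (mean outer-fold regression vector),
#'   `b_folds` (n x p matrix of per-fold vectors) and `class_levels`.
#' @export
double_cv <- function(x, y = NULL, lv_max = 3L, autoscale = TRUE) {
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (inherits(x, "feature_matrix") && is.null(y)) y <- x$class_labels
  y01 <- class_code(y)
  n <- nrow(values)
  if (n < 4L) stop("need at least 4 samples for double cross-validation")
  if (min(table(y01)) < 2L) stop("each class needs at least 2 members")
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  core <- .dcv_core(values, as.numeric(y01), lv_max, autoscale)
  structure(list(
    folds = data.frame(sample_id = ids, n_lv = core$n_lv,
                       prediction = core$preds, y = as.numeric(y01)),
    dq2 = dq2(as.numeric(y01), core$preds),
    nmc = nmc(as.numeric(y01), core$preds),
    b_mean = colMeans(core$b_folds),
    b_folds = core$b_folds,
    class_levels = attr(y01, "levels")),
    class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  cat("double cross-validation: dQ2 = ", round(x$dq2, 3), ", NMC = ",
      x$nmc, " of ", nrow(x$folds), "\n", sep = "")
  invisible(x)
}

#' Enumerate non-complementary balanced label permutations
#'
#' All distinct relabelings of a two-class vector preserving the class
#' sizes, excluding the true labeling, and - when the classes are of
#' equal size, so that swapping the two class names maps one relabeling
#' onto another - keeping exactly one representative of each
#' complement pair. For 5 vs 5 this gives 125 permutations
#' (choose(10,5) = 252 assignments, 126 complement classes, minus the
#' true one).
#'
#' @param y two-class label vector.
#' @return List of label vectors (same type and levels as `y`), each a
#'   relabeling of the samples; deterministic order.
#' @export
enumerate_balanced_permutations <- function(y) {
  y01 <- class_code(y)
  lv <- attr(y01, "levels")
  n <- length(y01)
  n1 <- sum(y01 == 1)
  if (min(n1, n - n1) < 2L)
    stop("classes too small to permute (need >= 2 per class)")
  sets <- utils::combn(n, n1)
  true_set <- which(as.numeric(y01) == 1)
  keep <- logical(ncol(sets))
  for (k in seq_len(ncol(sets))) {
    s <- sets[, k]
    if (2L * n1 == n && !(1L %in% s)) next  # complement representative
    if (length(s) == n1 && all(s == true_set)) next
    if (2L * n1 == n && all(sort(setdiff(seq_len(n), s)) == true_set)) next
    keep[k] <- TRUE
  }
  out <- vector("list", sum(keep))
  j <- 0L
  for (k in which(keep)) {
    lab <- rep(lv[1], n)
    lab[sets[, k]] <- lv[2]
    j <- j + 1L
    out[[j]] <- lab
  }
  out
}

#' Permutation test of the PLS-DA model and variable selection
#'
#' Runs [double_cv()] under every relabeling from
#' [enumerate_balanced_permutations()], building null distributions of the
#' figures of merit and of the mean regression vector. The model p-values
#' are the fraction of permuted statistics at least as extreme as the
#' real-label statistic (larger dQ2, smaller NMC; equality counts). Each
#' feature's p-value is the smaller of the two one-tailed fractions of
#' null regression coefficients at least as extreme as the real one, and
#' features with p below `alpha` (default 0.025, i.e. 2.5% per tail) are
#' selected as differentiating.
#'
#' @inheritParams double_cv
#' @param alpha per-tail selection threshold (default 0.025).
#' @param plus_one use the add-one convention for empirical p-values
#'   (default FALSE: plain fraction of permuted statistics).
#' @param extremeness compare signed coefficients per tail (default
#'   "signed") or absolute values ("absolute").
#' @return A `permutation_result` with `n_permutations`, `null_dq2`,
#'   `null_nmc`, `b_random` (permutations x features), `real` (the
#'   real-label `dcv_result`), `p_dq2`, `p_nmc`, `per_feature_p`,
#'   `selected_features` (feature ids, or column indices when `x` has
#'   none) and `alpha`.
#' @export
permutation_test <- function(x, y = NULL, lv_max = 3L, alpha = 0.025,
                             autoscale = TRUE, plus_one = FALSE,
                             extremeness = c("signed", "absolute")) {
  extremeness <- match.arg(extremeness)
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (inherits(x, "feature_matrix") && is.null(y)) y <- x$class_labels
  y01 <- class_code(y)
  real <- double_cv(values, as.numeric(y01), lv_max = lv_max,
                    autoscale = autoscale)
  perms <- enumerate_balanced_permutations(as.numeric(y01))
  n_perm <- length(perms)
  null_dq2 <- rep(NA_real_, n_perm)
  null_nmc <- rep(NA_integer_, n_perm)
  b_random <- matrix(NA_real_, n_perm, ncol(values))
  failed <- integer(0)
  for (k in seq_len(n_perm)) {
    res <- tryCatch(
      double_cv(values, as.numeric(perms[[k]]), lv_max = lv_max,
                autoscale = autoscale),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, k)
      next
    }
    null_dq2[k] <- res$dq2
    null_nmc[k] <- res$nmc
    b_random[k, ] <- res$b_mean
  }
  if (length(failed)) {
    warning(length(failed), " permutation(s) dropped due to fold errors: ",
            paste(utils::head(failed, 5L), collapse = ", "))
    null_dq2 <- null_dq2[-failed]
    null_nmc <- null_nmc[-failed]
    b_random <- b_random[-failed, , drop = FALSE]
  }
  n_eff <- length(null_dq2)
  add <- as.integer(plus_one)
  p_dq2 <- (sum(null_dq2 >= real$dq2) + add) / (n_eff + add)
  p_nmc <- (sum(null_nmc <= real$nmc) + add) / (n_eff + add)
  b_real <- real$b_mean
  if (extremeness == "absolute") {
    per_p <- (colSums(abs(b_random) >=
                        matrix(abs(b_real), n_eff, length(b_real),
                               byrow = TRUE)) + add) / (n_eff + add)
  } else {
    bm <- matrix(b_real, n_eff, length(b_real), byrow = TRUE)
    upper <- (colSums(b_random >= bm) + add) / (n_eff + add)
    lower <- (colSums(b_random <= bm) + add) / (n_eff + add)
    per_p <- pmin(upper, lower)
  }
  ids <- colnames(values)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(values)))
  structure(list(n_permutations = n_eff, null_dq2 = null_dq2,
                 null_nmc = null_nmc, b_random = b_random, real = real,
                 p_dq2 = p_dq2, p_nmc = p_nmc, per_feature_p = per_p,
                 selected_features = ids[per_p < alpha], alpha = alpha),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation test (", x$n_permutations, " relabelings): p(dQ2) = ",
      signif(x$p_dq2, 3), ", p(NMC) = ", signif(x$p_nmc, 3), "; ",
      length(x$selected_features), " feature(s) selected at p < ",
      x$alpha, "\n", sep = "")
  invisible(x)
}
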