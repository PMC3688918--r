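#' Principal component analysis with outlier statistics
#'
#' Fits a PCA model (by singular value decomposition, equivalent to
#' NIPALS-PCA at convergence) to an optionally autoscaled data matrix, for
#' unsupervised exploration and outlier screening of the preprocessed
#' feature matrix. The number of components can be fixed or chosen by
#' leave-one-out cross-validation minimizing the element-wise prediction
#' residual sum of squares (each coordinate of the held-out row predicted
#' from its other coordinates through the fold's loadings), with scaling
#' refit inside each fold.
#'
#' @param x numeric matrix or [feature_matrix] (samples in rows).
#' @param ncomp number of principal components, or `"loo-cv"` to choose it
#'   by leave-one-out cross-validation.
#' @param ncomp_max largest number of components considered under
#'   `"loo-cv"`; defaults to `min(n - 2, 6)`.
#' @param autoscale logical; mean-center and unit-variance scale columns
#'   before decomposition (default TRUE). With FALSE columns are only
#'   mean-centered.
#' @return A `pca_model` with `loadings` (features x A, orthonormal),
#'   `scores` (samples x A), `eigenvalues` (score variances, n-1
#'   convention), `explained_variance` (per-PC proportion of total
#'   variance over all PCs), `ncomp`, stored `center`/`scale`, the
#'   training row count `n`, and 95% control limits `q_limit_95` /
#'   `t2_limit_95` (see [pca_limits()]).
#' @export
fit_pca <- function(x, ncomp = "loo-cv", ncomp_max = NULL, autoscale = TRUE) {
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  n <- nrow(values)
  rank_max <- min(n - 1L, ncol(values))
  if (is.null(ncomp_max)) ncomp_max <- max(1L, min(n - 2L, 6L))
  ncomp_max <- min(ncomp_max, rank_max)
  if (identical(ncomp, "loo-cv")) {
    press <- .pca_loo_press(values, ncomp_max, autoscale)
    ncomp <- which.min(press)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > rank_max)
    stop("ncomp must be in 1..", rank_max)
  sf <- .scale_fit(values)
  sc <- if (autoscale) sf$scale else rep(1, ncol(values))
  if (autoscale && any(sf$scale == 0))
    stop("zero-variance column(s): ",
         paste(colnames(values)[sf$scale == 0], collapse = ", "))
  xs <- .scale_apply(values, sf$center, sc)
  dec <- svd(xs)
  eig_all <- dec$d^2 / (n - 1L)
  keep <- seq_len(ncomp)
  model <- structure(list(
    loadings = dec$v[, keep, drop = FALSE],
    scores = xs %*% dec$v[, keep, drop = FALSE],
    eigenvalues = eig_all[keep],
    eigenvalues_all = eig_all,
    explained_variance = eig_all[keep] / sum(eig_all),
    ncomp = ncomp, center = sf$center, scale = sc, n = n),
    class = "pca_model")
  lim <- pca_limits(model)
  model$q_limit_95 <- lim$q_limit
  model$t2_limit_95 <- lim$t2_limit
  model
}

# LOO PRESS: refit scaling and PCA without row i, then predict each
# coordinate of the left-out scaled row from its other coordinates
# (missing-coordinate projection). Plain projection PRESS decreases
# monotonically with the component count and cannot select a model;
# element-wise prediction penalizes overfitted loadings.
.pca_loo_press <- function(values, ncomp_max, autoscale) {
  n <- nrow(values)
  p <- ncol(values)
  press <- numeric(ncomp_max)
  for (i in seq_len(n)) {
    tr <- values[-i, , drop = FALSE]
    sf <- .scale_fit(tr)
    sc <- if (autoscale) ifelse(sf$scale > 0, sf$scale, 1) else
      rep(1, ncol(tr))
    xs <- .scale_apply(tr, sf$center, sc)
    v <- svd(xs, nu = 0, nv = min(ncomp_max, nrow(tr) - 1L))$v
    x0 <- as.numeric(.scale_apply(values[i, , drop = FALSE], sf$center, sc))
    for (a in seq_len(ncomp_max)) {
      va <- v[, seq_len(min(a, ncol(v))), drop = FALSE]
      g <- crossprod(va)            # a x a
      vx <- crossprod(va, x0)       # a x 1
      for (j in seq_len(p)) {
        vj <- va[j, ]
        # scores from all coordinates but j
        tj <- tryCatch(solve(g - tcrossprod(vj), vx - vj * x0[j]),
                       error = function(e) NULL)
        xhat <- if (is.null(tj)) 0 else sum(vj * tj)
        press[a] <- press[a] + (x0[j] - xhat)^2
      }
    }
  }
  press
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", x$ncomp, " PC(s), explaining ",
      round(100 * sum(x$explained_variance), 1), "% of total variance\n",
      sep = "")
  invisible(x)
}

#' Q residual statistic (squared distance to the model plane)
#'
#' The Q statistic of a sample is the squared Euclidean distance between
#' the (autoscaled) sample and its projection onto the PCA subspace; large
#' values flag samples with variation the model does not describe.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param rows matrix of rows in original units (or a single row vector).
#' @return Numeric vector of Q values, one per row.
#' @export
q_statistic <- function(model, rows) {
  xs <- .rows_to_scaled(model, rows)
  resid <- xs - xs %*% model$loadings %*% t(model$loadings)
  rowSums(resid^2)
}

#' Hotelling's T-squared statistic (sum of normalized squared scores)
#'
#' T-squared of a sample is the sum over retained components of its
#' squared score divided by that component's score variance; it measures
#' how far the sample sits from the data centroid within the model plane.
#'
#' @inheritParams q_statistic
#' @return Numeric vector of T-squared values, one per row.
#' @export
t2_statistic <- function(model, rows) {
  if (any(model$eigenvalues <= 0))
    stop("zero eigenvalue among retained components")
  xs <- .rows_to_scaled(model, rows)
  t_scores <- xs %*% model$loadings
  rowSums(sweep(t_scores^2, 2L, model$eigenvalues, "/"))
}

.rows_to_scaled <- function(model, rows) {
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1L) else as.matrix(rows)
  if (ncol(rows) != length(model$center))
    stop("row length does not match the model's feature space")
  .scale_apply(rows, model$center, model$scale)
}

#' 95% control limits for the Q and T-squared statistics
#'
#' T-squared limit from the F-distribution form
#' `A(n-1)(n+1)/(n(n-A)) * F(0.95; A, n-A)`; Q limit from the
#' Jackson-Mudholkar approximation based on the residual eigenvalues,
#' falling back to the Box chi-squared moment approximation (with a
#' warning) when the Jackson-Mudholkar form is unusable.
#'
#' @param model a `pca_model`.
#' @param n number of training samples (defaults to the model's).
#' @param alpha significance level (default 0.05 for 95% limits).
#' @return List with `q_limit` and `t2_limit`. `q_limit` is NA when no
#'   residual variance remains (full-rank model).
#' @export
pca_limits <- function(model, n = model$n, alpha = 0.05) {
  a <- model$ncomp
  if (n <= a) stop("need n > ncomp for the T-squared limit")
  t2_limit <- a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha, a, n - a)
  resid_eig <- model$eigenvalues_all[-seq_len(a)]
  resid_eig <- resid_eig[resid_eig > .Machine$double.eps * resid_eig[1]]
  q_limit <- NA_real_
  if (length(resid_eig) >= 1L && sum(resid_eig) > 0) {
    th1 <- sum(resid_eig); th2 <- sum(resid_eig^2); th3 <- sum(resid_eig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    z <- stats::qnorm(1 - alpha)
    if (is.finite(h0) && h0 > 0) {
      q_limit <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 +
                          th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
    }
    if (!is.finite(q_limit) || q_limit <= 0) {
      warning("Jackson-Mudholkar form unusable; using Box chi-squared ",
              "approximation for the Q limit")
      g <- th2 / th1; h <- th1^2 / th2
      q_limit <- g * stats::qchisq(1 - alpha, h)
    }
  }
  list(q_limit = q_limit, t2_limit = t2_limit)
}

#' Ward hierarchical clustering of PCA scores
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion on Euclidean distances, used to explore sample grouping in
#' the PCA score space: at each step the two clusters whose merger least
#' increases the pooled within-cluster variance are joined.
#'
#' @param x a `pca_model` (clusters its score matrix), a [feature_matrix],
#'   or a numeric matrix of rows to cluster.
#' @return An object of class `hclust` (Ward linkage, Euclidean distance);
#'   merge heights are non-decreasing.
#' @export
ward_hca <- function(x) {
  m <- if (inherits(x, "pca_model")) x$scores
  else if (inherits(x, "feature_matrix")) x$values
  else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(m), method = "ward.D2")
}
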