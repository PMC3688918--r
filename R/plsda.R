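#' Coerce class labels to the 0/1 code of the discriminant response
#'
#' Two-class labels are coded 0 for the first level and 1 for the second
#' ("hypoxia" = 0, "normoxia" = 1 when those labels are present), then
#' mean-centered inside the model fit.
#'
#' @param labels factor, character or numeric 0/1 vector.
#' @param levels optional explicit two-level ordering.
#' @return Numeric 0/1 vector with a `"levels"` attribute.
#' @export
class_code <- function(labels, levels = NULL) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    lv <- if (is.null(levels)) c("0", "1") else levels
    y <- as.numeric(labels)
  } else {
    lv <- if (!is.null(levels)) levels
    else if (all(c("hypoxia", "normoxia") %in% unique(as.character(labels))))
      c("hypoxia", "normoxia")
    else sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("need exactly two classes, got: ",
                               paste(lv, collapse = ", "))
    y <- as.numeric(match(as.character(labels), lv) - 1L)
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  attr(y, "levels") <- lv
  y
}

# PLS1 by NIPALS on a scaled X and centered y. For a single response the
# weight update has a closed fixed point, reached in one pass; the
# iteration guard is kept for form. Returns per-LV weights W, x-loadings
# P, y-loadings q, scores T, and the cumulative regression vectors
# B[, a] = W_a (P_a' W_a)^{-1} q_a for a = 1..ncomp.
.pls1_nipals <- function(xs, yc, ncomp, tol = 1e-12, max_iter = 500L) {
  p <- ncol(xs)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(xs), ncomp)
  qv <- numeric(ncomp)
  xd <- xs; yd <- yc
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-14) break  # X deflated to noise: no further direction
    w <- w / nw
    for (it in seq_len(max_iter)) {
      t_sc <- xd %*% w
      w_new <- crossprod(xd, yd)
      w_new <- w_new / sqrt(sum(w_new * w_new))
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    t_sc <- xd %*% w
    tt <- sum(t_sc * t_sc)
    if (tt < 1e-28) break
    p_a <- crossprod(xd, t_sc) / tt
    q_a <- sum(yd * t_sc) / tt
    xd <- xd - tcrossprod(t_sc, p_a)
    yd <- yd - q_a * t_sc
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a; Tm[, a] <- t_sc
    a_done <- a
  }
  if (a_done == 0L) stop("NIPALS found no latent variable (X'y is zero)")
  B <- matrix(0, p, a_done)
  for (a in seq_len(a_done)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
  }
  list(W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       q = qv[seq_len(a_done)],
       scores = Tm[, seq_len(a_done), drop = FALSE],
       B = B, ncomp = a_done)
}

#' Fit a PLS1 discriminant model by NIPALS
#'
#' Partial least squares regression of the mean-centered 0/1 class code on
#' the autoscaled feature matrix, computed with the nonlinear iterative
#' partial least squares (NIPALS) algorithm with deflation. The default
#' ceiling of 3 latent variables guards against overfitting at small n.
#'
#' @param x numeric matrix or [feature_matrix] (samples in rows), original
#'   units.
#' @param y class labels (see [class_code()]).
#' @param ncomp number of latent variables (1..`lv_max`).
#' @param lv_max ceiling on latent variables (default 3).
#' @param autoscale autoscale columns of `x` (default TRUE); the scaling
#'   is stored in the model and reapplied by [predict.plsda_model()].
#' @return A `plsda_model` with per-LV `weights`, `x_loadings`,
#'   `y_loadings`, `scores`, the regression vector `b` (for `ncomp` LVs,
#'   on the scaled-X / centered-y scale), `b_by_ncomp` (cumulative
#'   regression vectors for 1..ncomp LVs), `ncomp`, stored
#'   `center`/`scale`/`y_mean`, and `class_levels`.
#' @export
fit_plsda <- function(x, y, ncomp = 1L, lv_max = 3L, autoscale = TRUE) {
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (inherits(x, "feature_matrix") && (missing(y) || is.null(y)))
    y <- x$class_labels
  y01 <- class_code(y)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > lv_max)
    stop("ncomp must be in 1..lv_max (= ", lv_max, ")")
  sf <- .scale_fit(values)
  sc <- if (autoscale) sf$scale else rep(1, ncol(values))
  if (autoscale && any(sf$scale == 0))
    stop("zero-variance column(s): ",
         paste(colnames(values)[sf$scale == 0], collapse = ", "))
  xs <- .scale_apply(values, sf$center, sc)
  y_mean <- mean(y01)
  fit <- .pls1_nipals(xs, as.numeric(y01) - y_mean, ncomp)
  structure(list(weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
                 scores = fit$scores, b = fit$B[, fit$ncomp],
                 b_by_ncomp = fit$B, ncomp = fit$ncomp,
                 center = sf$center, scale = sc, y_mean = y_mean,
                 class_levels = attr(y01, "levels")),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("plsda_model: ", x$ncomp, " latent variable(s), ",
      length(x$b), " features; classes ",
      paste(x$class_levels, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' Predict class response values from a PLS-DA model
#'
#' Applies the model's stored autoscaling to the new rows and evaluates
#' `y_hat = X b + y_mean`, returning predictions on the original 0/1
#' label scale (0 = first class level, 1 = second).
#'
#' @param object a `plsda_model`.
#' @param newdata matrix of rows in original units, or a [feature_matrix].
#' @param ncomp number of latent variables to use (default: the model's).
#' @param ... unused.
#' @return Numeric vector of predicted responses on the 0/1 scale.
#' @export
predict.plsda_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  values <- if (inherits(newdata, "feature_matrix")) newdata$values
  else if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
  else as.matrix(newdata)
  if (ncol(values) != length(object$center))
    stop("newdata has ", ncol(values), " columns; model expects ",
         length(object$center))
  ncomp <- min(as.integer(ncomp), object$ncomp)
  xs <- .scale_apply(values, object$center, object$scale)
  as.numeric(xs %*% object$b_by_ncomp[, ncomp] + object$y_mean)
}

#' Discriminant Q-squared (dQ2)
#'
#' Cross-validated explained variance of the class response in which
#' predictions that overshoot their own class code in the correct
#' direction carry no penalty: for a class-1 sample predicted at or above
#' 1 (or a class-0 sample at or below 0) the residual is set to zero,
#' otherwise it is `y_hat - y`. `dQ2 = 1 - sum(e^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true 0/1 class codes (or labels coercible via [class_code()]).
#' @param y_pred predicted responses on the same 0/1 scale.
#' @param codes the two class codes, default `c(0, 1)`.
#' @return Scalar dQ2 (at most 1; 1 means every prediction at or beyond
#'   its class code on the correct side).
#' @export
dq2 <- function(y_true, y_pred, codes = c(0, 1)) {
  y <- if (is.numeric(y_true) && all(y_true %in% codes)) as.numeric(y_true)
  else codes[1] + (codes[2] - codes[1]) * class_code(y_true)
  if (length(y) != length(y_pred)) stop("length mismatch")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero total sum of squares: single class")
  hi <- max(codes); lo <- min(codes)
  e <- y_pred - y
  e[y == hi & y_pred >= hi] <- 0
  e[y == lo & y_pred <= lo] <- 0
  1 - sum(e^2) / tss
}

#' Number of misclassified samples (NMC)
#'
#' Counts predictions on the wrong side of the midpoint between the two
#' class codes; a prediction exactly at the midpoint counts as
#' misclassified.
#'
#' @inheritParams dq2
#' @return Integer count of misclassifications.
#' @export
nmc <- function(y_true, y_pred, codes = c(0, 1)) {
  y <- if (is.numeric(y_true) && all(y_true %in% codes)) as.numeric(y_true)
  else codes[1] + (codes[2] - codes[1]) * class_code(y_true)
  if (length(y) != length(y_pred)) stop("length mismatch")
  mid <- mean(codes)
  hi <- max(codes); lo <- min(codes)
  sum((y == hi & y_pred <= mid) | (y == lo & y_pred >= mid))
}

# Lean internal kernels used by the cross-validation loops; they follow
# exactly the same NIPALS deflation as .pls1_nipals but skip the S3
# plumbing (for PLS1 the weight update has an exact one-pass fixed
# point). .pls1_b returns the cumulative regression vectors for
# 1..ncomp latent variables; columns past the extractable rank repeat
# the last valid vector.
.pls1_b <- function(xs, yc, ncomp) {
  p <- ncol(xs)
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  xd <- xs; yd <- yc
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-14) break
    w <- w / nw
    t_sc <- xd %*% w
    tt <- sum(t_sc * t_sc)
    if (tt < 1e-28) break
    p_a <- crossprod(xd, t_sc) / tt
    q_a <- sum(yd * t_sc) / tt
    xd <- xd - t_sc %*% t(p_a)
    yd <- yd - q_a * t_sc
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) stop("NIPALS found no latent variable (X'y is zero)")
  B <- matrix(0, p, ncomp)
  for (a in seq_len(a_done)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
  }
  if (a_done < ncomp)
    for (a in seq.int(a_done + 1L, ncomp)) B[, a] <- B[, a_done]
  B
}

.autoscale_train <- function(x, autoscale = TRUE) {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- x - rep(ctr, each = n)
  if (autoscale) {
    sdv <- sqrt(colSums(xc * xc) / (n - 1L))
    sdv[sdv == 0] <- 1  # constant training column contributes zeros
  } else sdv <- rep(1, ncol(x))
  list(xs = xc / rep(sdv, each = n), center = ctr, sd = sdv)
}

# leave-one-out predictions (0/1 scale) for every dimensionality 1..lv_max
.loo_preds <- function(values, y01, lv_max, autoscale = TRUE) {
  n <- nrow(values)
  preds <- matrix(NA_real_, n, lv_max)
  for (i in seq_len(n)) {
    yt <- y01[-i]
    if (length(unique(yt)) < 2L)
      stop("leave-one-out fold lost a class entirely")
    sc <- .autoscale_train(values[-i, , drop = FALSE], autoscale)
    ym <- mean(yt)
    B <- .pls1_b(sc$xs, yt - ym, lv_max)
    x0 <- (values[i, ] - sc$center) / sc$sd
    preds[i, ] <- as.numeric(crossprod(B, x0)) + ym
  }
  preds
}

.dq2_num <- function(y, yhat) {
  e <- yhat - y
  e[y == 1 & yhat >= 1] <- 0
  e[y == 0 & yhat <= 0] <- 0
  1 - sum(e * e) / sum((y - mean(y))^2)
}

# nested leave-one-out: inner LV choice, outer out-of-fold prediction
.dcv_core <- function(values, y01, lv_max, autoscale = TRUE) {
  n <- nrow(values)
  n_lv <- integer(n)
  preds <- numeric(n)
  b_folds <- matrix(0, n, ncol(values))
  for (i in seq_len(n)) {
    xt <- values[-i, , drop = FALSE]
    yt <- y01[-i]
    inner <- .loo_preds(xt, yt, lv_max, autoscale)
    dq2s <- vapply(seq_len(lv_max), function(a) .dq2_num(yt, inner[, a]),
                   numeric(1))
    a <- which(dq2s >= max(dq2s) - 1e-12)[1]
    sc <- .autoscale_train(xt, autoscale)
    ym <- mean(yt)
    B <- .pls1_b(sc$xs, yt - ym, a)
    x0 <- (values[i, ] - sc$center) / sc$sd
    preds[i] <- sum(B[, a] * x0) + ym
    n_lv[i] <- a
    b_folds[i, ] <- B[, a]
  }
  list(n_lv = n_lv, preds = preds, b_folds = b_folds)
}

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' For each candidate dimensionality `a = 1..lv_max`, computes
#' leave-one-out predictions (autoscaling and response centering refit
#' within each fold) and the resulting dQ2; returns the smallest `a`
#' attaining the maximum dQ2.
#'
#' @param x matrix or [feature_matrix], original units.
#' @param y class labels.
#' @param lv_max ceiling on latent variables (default 3).
#' @param autoscale refit autoscaling inside each fold (default TRUE).
#' @return Integer in `1..lv_max`, with attribute `"dq2"` holding the
#'   per-dimensionality cross-validated dQ2 values.
#' @export
select_n_lv <- function(x, y, lv_max = 3L, autoscale = TRUE) {
  values <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  y01 <- as.numeric(class_code(y))
  if (nrow(values) < 3L) stop("need at least 3 samples")
  lv_max <- as.integer(lv_max)
  preds <- .loo_preds(values, y01, lv_max, autoscale)
  dq2s <- vapply(seq_len(lv_max), function(a) .dq2_num(y01, preds[, a]),
                 numeric(1))
  best <- which(dq2s >= max(dq2s) - 1e-12)[1]  # smallest a at the maximum
  structure(as.integer(best), dq2 = dq2s)
}
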