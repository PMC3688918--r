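# Independent oracles, deliberately implemented by routes different from
# the package's own algorithms.

# PLS1 regression vector via its Krylov-subspace characterisation:
# b_a minimises ||y - X b|| over b in span{s, Ms, M^2 s, ...} with
# M = X'X, s = X'y. Algebraically equivalent to NIPALS-PLS1 at every
# dimensionality, computed here by explicit orthogonalisation.
oracle_pls1_b <- function(xs, yc, a) {
  m <- crossprod(xs)
  s <- crossprod(xs, yc)
  K <- matrix(0, ncol(xs), a)
  v <- s
  for (k in seq_len(a)) {
    K[, k] <- v
    v <- m %*% v
  }
  V <- qr.Q(qr(K))
  V %*% solve(crossprod(V, m %*% V), crossprod(V, s))
}

# Ward agglomeration by the Lance-Williams update on squared Euclidean
# distances; returns merge heights (sqrt scale, matching ward.D2).
oracle_ward_heights <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA
    for (i in which(active)) for (j in which(active)) {
      if (j <= i) next
      if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
    }
    heights[step] <- sqrt(best)
    for (k in which(active)) {
      if (k == bi || k == bj) next
      ni <- size[bi]; nj <- size[bj]; nk <- size[k]
      d2[bi, k] <- d2[k, bi] <-
        ((ni + nk) * d2[bi, k] + (nj + nk) * d2[bj, k] -
           nk * d2[bi, bj]) / (ni + nj + nk)
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  heights
}

# Brute-force count of distinct balanced relabelings: every subset of the
# right size, collapsing complement pairs for equal class sizes,
# excluding the true labeling.
oracle_n_permutations <- function(y01) {
  n <- length(y01)
  n1 <- sum(y01 == 1)
  sets <- utils::combn(n, n1, simplify = FALSE)
  key <- function(s) paste(sort(s), collapse = ",")
  true_key <- key(which(y01 == 1))
  seen <- character(0)
  count <- 0L
  for (s in sets) {
    k <- key(s)
    kc <- key(setdiff(seq_len(n), s))
    canon <- if (2L * n1 == n) min(k, kc) else k
    if (canon %in% seen) next
    seen <- c(seen, canon)
    if (canon == true_key || (2L * n1 == n && canon == min(true_key, key(
      setdiff(seq_len(n), which(y01 == 1)))))) next
    count <- count + 1L
  }
  count
}

# standard (unclipped) cross-validated Q2
oracle_q2 <- function(y, yhat) 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
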