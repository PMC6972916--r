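# Non-negative matrix factorization core: NNDSVD initialization + HALS
# (hierarchical alternating least squares) updates for the Frobenius
# objective. HALS solves each factor column/row exactly under the
# non-negativity constraint, so the objective is non-increasing per sweep.

# Non-negative double SVD initialization (Boutsidis & Gallopoulos).
# Zero entries are replaced by small seeded uniform draws so multiplicative
# structure cannot lock them at zero ("ar" variant).
.nndsvdInit <- function(X, k, seed) {
  sv <- svd(X, nu = k, nv = k)
  n <- nrow(X); m <- ncol(X)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (k >= 2L) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      sig <- nup * nvp
      if (sig > 0) {
        W[, j] <- sqrt(sv$d[j] * sig) * up / nup
        H[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
      }
    } else {
      sig <- nun * nvn
      W[, j] <- sqrt(sv$d[j] * sig) * un / nun
      H[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
    }
  }
  eps <- mean(X) * 1e-4
  withr::with_seed(seed, {
    W[W == 0] <- stats::runif(sum(W == 0), 0, eps)
    H[H == 0] <- stats::runif(sum(H == 0), 0, eps)
  })
  list(W = W, H = H)
}

# One HALS fit with objective-guarded extrapolation (momentum steps are
# only accepted when they decrease the objective, so the trace stays
# monotone). Returns W, H, the objective trace (squared Frobenius residual
# per iteration) and a convergence flag. The objective is computed from the
# residual directly: the expanded Gram form loses all precision once the
# fit approaches machine zero.
.halsFit <- function(X, W, H, maxIter, tol, relTol = 1e-7, betaMax = 2) {
  normX2 <- sum(X^2)
  obj <- numeric(maxIter)
  prev <- Inf
  converged <- FALSE
  beta <- 0.5
  nIt <- 0L
  for (it in seq_len(maxIter)) {
    Wold <- W; Hold <- H
    A <- X %*% t(H); B <- tcrossprod(H)
    for (j in seq_len(ncol(W))) {
      if (B[j, j] > 0)
        W[, j] <- pmax(0, W[, j] + (A[, j] - W %*% B[, j]) / B[j, j])
    }
    C <- crossprod(W, X); D <- crossprod(W)
    for (j in seq_len(nrow(H))) {
      if (D[j, j] > 0)
        H[j, ] <- pmax(0, H[j, ] + (C[j, ] - D[j, ] %*% H) / D[j, j])
    }
    o <- sum((X - W %*% H)^2)
    We <- pmax(W + beta * (W - Wold), 0)
    He <- pmax(H + beta * (H - Hold), 0)
    oe <- sum((X - We %*% He)^2)
    if (oe < o) {
      W <- We; H <- He; o <- oe
      beta <- min(betaMax, beta * 1.1)
    } else {
      beta <- max(0.1, beta * 0.5)
    }
    nIt <- it
    obj[it] <- o
    if (o <= relTol^2 * normX2 ||
        (is.finite(prev) && (prev - o) <= tol * max(prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev <- o
  }
  list(W = W, H = H, objective = obj[seq_len(nIt)], converged = converged)
}

# Masked multiplicative-update NMF used only for held-out rank selection.
# M is a 0/1 mask of observed entries.
.maskedMuFit <- function(X, M, k, seed, maxIter = 300L) {
  eps <- .Machine$double.eps
  withr::with_seed(seed, {
    W <- matrix(stats::runif(nrow(X) * k, 0, mean(X)), ncol = k)
    H <- matrix(stats::runif(k * ncol(X), 0, 1), nrow = k)
  })
  MX <- M * X
  for (it in seq_len(maxIter)) {
    WH <- W %*% H
    W <- W * (MX %*% t(H)) / ((M * WH) %*% t(H) + eps)
    WH <- W %*% H
    H <- H * crossprod(W, MX) / (crossprod(W, M * WH) + eps)
  }
  list(W = W, H = H)
}
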