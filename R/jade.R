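#' @include AllClasses.R
NULL

#' JADE independent component analysis
#'
#' Blind source separation by Joint Approximate Diagonalization of
#' Eigenmatrices: the observations are whitened via the eigendecomposition
#' of their covariance, the parallel set of fourth-order cumulant matrices
#' is estimated, and an orthogonal joint diagonalizer is found by Jacobi
#' rotation sweeps. Entirely deterministic (no random initialization).
#' Sources are recovered up to permutation and sign, as is inherent to
#' ICA.
#'
#' @param X m x N matrix, one observed mixture per row.
#' @param maxSweeps maximum Jacobi sweep count.
#' @return List with `S` (m x N source estimates) and `B` (unmixing
#'   matrix, `S = B %*% scale(X)`).
#' @examples
#' t <- (0:599) / 30
#' src <- rbind(sin(2 * pi * 1.2 * t), sign(sin(2 * pi * 0.31 * t)))
#' X <- matrix(c(0.6, 0.4, 0.35, 0.65), 2) %*% src
#' fit <- jadeIca(X)
#' @export
jadeIca <- function(X, maxSweeps = 100) {
  m <- nrow(X); N <- ncol(X)
  stopifnot(m >= 2L, N > 10L * m)
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / N
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[1L] <= 0 || eg$values[m] / eg$values[1L] < 1e-12)
    stop("rank-deficient input: mixtures are not separable")
  Wh <- diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
  Z <- Wh %*% X

  # parallel set of m(m+1)/2 fourth-order cumulant matrices
  R <- diag(m)
  CM <- vector("list", m * (m + 1) / 2)
  k <- 1L
  for (i in seq_len(m)) {
    Zi <- Z[i, ]
    CM[[k]] <- (Z * rep(Zi * Zi, each = m)) %*% t(Z) / N - R -
      2 * tcrossprod(R[, i])
    k <- k + 1L
    if (i > 1L) for (j in seq_len(i - 1L)) {
      Zj <- Z[j, ]
      CM[[k]] <- sqrt(2) * ((Z * rep(Zi * Zj, each = m)) %*% t(Z) / N -
        tcrossprod(R[, i], R[, j]) - tcrossprod(R[, j], R[, i]))
      k <- k + 1L
    }
  }

  # joint diagonalization by Jacobi rotations
  V <- diag(m)
  thresh <- 1e-6 / sqrt(N)
  for (sweep in seq_len(maxSweeps)) {
    rotated <- FALSE
    for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
      ton <- vapply(CM, function(M) M[p, p] - M[q, q], numeric(1L))
      toff <- vapply(CM, function(M) M[p, q] + M[q, p], numeric(1L))
      g11 <- sum(ton * ton); g22 <- sum(toff * toff)
      g12 <- sum(ton * toff)
      theta <- 0.5 * atan2(2 * g12,
                           g11 - g22 + sqrt((g11 - g22)^2 + 4 * g12^2))
      if (abs(sin(theta)) > thresh) {
        rotated <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        G <- matrix(c(cs, sn, -sn, cs), 2L, 2L)
        pair <- c(p, q)
        for (kk in seq_along(CM)) {
          M <- CM[[kk]]
          M[pair, ] <- t(G) %*% M[pair, ]
          M[, pair] <- M[, pair] %*% G
          CM[[kk]] <- M
        }
        V[, pair] <- V[, pair] %*% G
      }
    }
    if (!rotated) break
  }
  B <- t(V) %*% Wh
  list(S = B %*% X, B = B)
}
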