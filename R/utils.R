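# Internal numerical helpers.

# Row-wise log-sum-exp of a matrix, guarding -Inf rows.
.rowLogSumExp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

# Orthonormal basis (Q) of the column space of X plus its rank/df.
.projector <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank deficient (rank ", qx$rank,
         " < ", ncol(X), " columns)")
  }
  list(Q = qr.Q(qx), df = qx$rank)
}

# Fitted values of every row of Y under the column space spanned by Q.
.projectRows <- function(Y, Q) {
  tcrossprod(Y %*% Q, Q)
}

# Squared-distance matrix between rows of A (m x N) and rows of B (K x N).
.sqDistMatrix <- function(A, B) {
  D <- -2 * tcrossprod(A, B)
  D <- sweep(D, 1L, rowSums(A^2), "+")
  D <- sweep(D, 2L, rowSums(B^2), "+")
  pmax(D, 0)
}

# Derive independent sub-stream seeds from one user seed.
.spawnSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}
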