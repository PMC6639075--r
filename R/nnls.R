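#' Non-negative least squares via the active-set method on normal equations
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` given the precomputed
#' Gram matrix `AtA = t(A) %*% A` and `Atb = t(A) %*% b` (Bro & de Jong's
#' fast NNLS). Working on the normal equations lets one factorization
#' design be shared across thousands of right-hand sides, which is how the
#' consensus usage and TPM-spectra refits use it.
#'
#' @param AtA k x k Gram matrix.
#' @param Atb length-k vector.
#' @param tol Convergence tolerance on the residual gradient (default 1e-8).
#' @return Non-negative coefficient vector of length k.
#' @export
nnls_gram <- function(AtA, Atb, tol = 1e-8) {
  k <- length(Atb)
  x <- numeric(k)
  passive <- logical(k)
  w <- Atb                       # negative gradient at x = 0
  it <- 0L
  max_it <- 30L * k
  while (any(!passive) && max(w[!passive]) > tol && it < max_it) {
    it <- it + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(k)
      sol <- tryCatch(solve(AtA[passive, passive, drop = FALSE], Atb[passive]),
                      error = function(e) NULL)
      if (is.null(sol)) {        # singular passive set: minimum-norm inner solve
        sv <- svd(AtA[passive, passive, drop = FALSE])
        d <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
        sol <- sv$v %*% (d * crossprod(sv$u, Atb[passive]))
      }
      s[passive] <- sol
      if (all(s[passive] > 0)) break
      q <- passive & (s <= 0)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
    }
    x <- s
    w <- Atb - drop(AtA %*% x)
  }
  pmax(x, 0)
}

#' Non-negative least squares for many right-hand sides
#'
#' Solves `min ||A X - B||_F` column-wise subject to `X >= 0`, sharing one
#' Gram matrix across all columns of `B`.
#'
#' @param A n x k design matrix.
#' @param B n x m matrix of right-hand sides.
#' @param tol Passed to [nnls_gram()].
#' @return k x m non-negative coefficient matrix.
#' @export
nnls_multi <- function(A, B, tol = 1e-8) {
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  out <- matrix(0, ncol(A), ncol(B))
  for (j in seq_len(ncol(B))) {
    out[, j] <- nnls_gram(AtA, AtB[, j], tol = tol)
  }
  dimnames(out) <- list(colnames(A), colnames(B))
  out
}
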