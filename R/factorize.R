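#' Run one seeded NMF replicate
#'
#' Factorizes the non-negative matrix `X ~ U %*% G` (cells x genes into
#' cells x k and k x genes) under the Frobenius objective with a
#' hierarchical-ALS coordinate-descent solver: each column of `U` and each
#' row of `G` is updated to its exact non-negative block minimizer in turn,
#' so the loss is non-increasing at every update. Initialization is random
#' uniform scaled by `sqrt(mean(X)/k)`; convergence is declared when the
#' drop in loss over 10 iterations falls below `tol` times the initial
#' loss, or after `max_iter` iterations (the method's settings are
#' `tol = 1e-4`, `max_iter = 400`).
#'
#' Components that collapse to all-zero are kept as zero rows (they carry a
#' `zero_components` flag and are removed later by consensus outlier
#' filtering) rather than silently changing the factorization rank.
#'
#' @param x Non-negative cells x genes matrix.
#' @param k Number of components (>= 1).
#' @param seed Integer seed for the random initialization.
#' @param tol Relative stopping tolerance (default 1e-4).
#' @param max_iter Maximum iterations (default 400).
#' @param trace Record the loss at every iteration (for diagnostics).
#' @return A list with `u` (cells x k), `g` (k x genes), `loss` (final
#'   Frobenius norm of the residual), `iterations`, `zero_components`, and
#'   (if `trace`) `loss_trace`.
#' @export
run_nmf_replicate <- function(x, k, seed, tol = 1e-4, max_iter = 400,
                              trace = FALSE) {
  stopifnot(k >= 1)
  if (anyNA(x)) stop("input matrix contains NA/NaN")
  if (min(x) < 0) stop("input matrix must be non-negative")
  n <- nrow(x); m <- ncol(x)
  set.seed(seed)
  scale0 <- sqrt(mean(x) / k)
  u <- matrix(stats::runif(n * k), n, k) * scale0
  g <- matrix(stats::runif(k * m), k, m) * scale0
  norm_x2 <- sum(x^2)
  loss2 <- function(utu, gtg_ux) norm_x2 - 2 * gtg_ux$cross + gtg_ux$quad
  loss_trace <- if (trace) numeric(max_iter) else NULL
  err_init <- NA_real_
  err_prev <- NA_real_
  it_done <- max_iter
  for (it in seq_len(max_iter)) {
    # update U columns given G
    ggt <- tcrossprod(g)
    xgt <- x %*% t(g)
    for (j in seq_len(k)) {
      den <- ggt[j, j]
      if (den <= 0) next
      u[, j] <- pmax(0, u[, j] + (xgt[, j] - u %*% ggt[, j]) / den)
    }
    # update G rows given U
    utu <- crossprod(u)
    utx <- crossprod(u, x)
    for (j in seq_len(k)) {
      den <- utu[j, j]
      if (den <= 0) next
      g[j, ] <- pmax(0, g[j, ] + (utx[j, ] - utu[j, ] %*% g) / den)
    }
    check <- trace || it %% 10 == 0 || it == max_iter
    if (check) {
      err2 <- norm_x2 - 2 * sum(utx * g) + sum(crossprod(u) * tcrossprod(g))
      err2 <- max(err2, 0)
      if (trace) loss_trace[it] <- sqrt(err2)
      if (is.na(err_init)) {
        err_init <- err2
      } else if (it %% 10 == 0 && !is.na(err_prev) &&
                 (err_prev - err2) < tol * err_init) {
        it_done <- it
        break
      }
      if (it %% 10 == 0) err_prev <- err2
    }
  }
  utx <- crossprod(u, x)
  final2 <- max(norm_x2 - 2 * sum(utx * g) + sum(crossprod(u) * tcrossprod(g)), 0)
  zero <- rowSums(g) == 0 | colSums(u) == 0
  res <- list(u = u, g = g, loss = sqrt(final2), iterations = it_done,
              zero_components = zero)
  if (trace) res$loss_trace <- loss_trace[seq_len(it_done)]
  res
}

#' Run R independently seeded NMF replicates and stack their components
#'
#' Each replicate r uses seed `base_seed + r`, so results are independent
#' of execution order. Every component row is l2-normalized (zero rows are
#' kept as zeros and flagged) and the normalized rows of all replicates are
#' concatenated vertically into the `(R*K) x H` component stack that the
#' consensus step consumes.
#'
#' @param x Non-negative cells x genes matrix (the variance-scaled input).
#' @param k Number of components per replicate.
#' @param r Number of replicates (the benchmark default is 200 at full
#'   scale; this package's reduced benchmark uses 50).
#' @param base_seed Base seed; replicate r gets `base_seed + r`.
#' @param tol,max_iter Passed to [run_nmf_replicate()].
#' @param keep_usages Keep the per-replicate usage matrices (default TRUE).
#' @return An object of class `replicate_stack`: `components` ((R*K) x H
#'   matrix of l2-normalized rows), `usages` (list of cells x K matrices or
#'   NULL), `seeds`, `losses`, `iterations`, `k`, `r`, `zero_rows`.
#' @export
run_replicates <- function(x, k, r, base_seed = 0, tol = 1e-4,
                           max_iter = 400, keep_usages = TRUE) {
  stopifnot(r >= 1)
  seeds <- base_seed + seq_len(r)
  comp <- matrix(0, r * k, ncol(x))
  colnames(comp) <- colnames(x)
  rownames(comp) <- paste0("rep", rep(seq_len(r), each = k), "_k",
                           rep(seq_len(k), r))
  usages <- if (keep_usages) vector("list", r) else NULL
  losses <- numeric(r)
  iters <- integer(r)
  zero_rows <- logical(r * k)
  for (i in seq_len(r)) {
    fit <- run_nmf_replicate(x, k, seed = seeds[i], tol = tol,
                             max_iter = max_iter)
    g <- fit$g
    nrm <- sqrt(rowSums(g^2))
    gn <- g
    gn[nrm > 0, ] <- g[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
    rows <- (i - 1) * k + seq_len(k)
    comp[rows, ] <- gn
    zero_rows[rows] <- nrm == 0
    if (keep_usages) usages[[i]] <- fit$u
    losses[i] <- fit$loss
    iters[i] <- fit$iterations
  }
  structure(list(components = comp, usages = usages, seeds = seeds,
                 losses = losses, iterations = iters, k = k, r = r,
                 zero_rows = zero_rows),
            class = "replicate_stack")
}
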