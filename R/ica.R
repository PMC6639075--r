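#' @title Consensus independent component analysis (cICA) baseline
#' @description
#' The benchmark's strongest published competitor reuses the whole
#' consensus machinery with ICA as the base factorization. Because no ICA
#' implementation is available in the package's dependency set, a compact
#' symmetric FastICA (logcosh contrast, PCA whitening) is included here.
#' ICA is sign-ambiguous, so before stacking, every component whose median
#' usage across cells is positive is flipped (component and usage scaled
#' by -1), making orientation deterministic across replicates.
#' @name cica
NULL

# symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% w
}

#' PCA whitening for FastICA
#'
#' Centers the columns of `x` and projects onto the top `k` principal
#' directions, scaled to unit variance.
#'
#' @param x Cells x genes matrix.
#' @param k Number of components.
#' @return A list with `scores` (cells x k, whitened), `center`, and
#'   `xc` (the centered matrix, kept for the mixing-matrix fit).
#' @keywords internal
whiten_pca <- function(x, k) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  e <- eigen(tcrossprod(xc), symmetric = TRUE)
  u <- e$vectors[, seq_len(k), drop = FALSE]
  list(scores = u * sqrt(nrow(x) - 1), center = ctr, xc = xc)
}

#' One seeded FastICA replicate on whitened scores
#'
#' Symmetric FastICA with the logcosh (tanh) contrast on pre-whitened
#' scores; random orthogonal initialization from `seed`. Sources and the
#' gene-space mixing rows are sign-aligned by the median-usage rule:
#' any component with positive median source value is multiplied by -1
#' together with its mixing row.
#'
#' @param wh Whitening object from [whiten_pca()].
#' @param seed Integer seed.
#' @param tol Convergence tolerance (default 1e-4).
#' @param max_iter Maximum FastICA iterations (default 200).
#' @return A list with `usage` (cells x k sources) and `spectra`
#'   (k x genes mixing rows).
#' @export
run_ica_replicate <- function(wh, seed, tol = 1e-4, max_iter = 200) {
  z <- wh$scores
  n <- nrow(z)
  k <- ncol(z)
  set.seed(seed)
  w <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    s <- z %*% t(w)
    gs <- tanh(s)
    w_new <- crossprod(gs, z) / n - diag(colMeans(1 - gs^2)) %*% w
    w_new <- sym_decorrelate(w_new)
    lim <- max(abs(abs(diag(tcrossprod(w_new, w))) - 1))
    w <- w_new
    if (lim < tol) break
  }
  s <- z %*% t(w)
  spectra <- crossprod(s, wh$xc) / (n - 1)
  flip <- apply(s, 2, stats::median) > 0
  s[, flip] <- -s[, flip, drop = FALSE]
  spectra[flip, ] <- -spectra[flip, , drop = FALSE]
  list(usage = s, spectra = spectra)
}

#' Consensus ICA
#'
#' Runs `r` FastICA replicates (whitening computed once; only the random
#' rotation initialization differs), sign-aligns and l2-normalizes the
#' components, then applies the identical consensus machinery as cNMF --
#' KNN outlier filter, KMeans, per-gene median, l1 normalization -- and
#' refits usages by unconstrained least squares (spectra may be negative,
#' so NNLS does not apply).
#'
#' @param norm Cells x H variance-scaled matrix.
#' @param k Number of components.
#' @param r Number of replicates.
#' @param rho,tau Outlier-filter parameters (see [knn_outlier_filter()]).
#' @param base_seed Base seed; replicate i uses `base_seed + i`.
#' @return An object of class `cnmf_consensus` (spectra and usages signed;
#'   `usage_norm` is NULL).
#' @export
consensus_ica <- function(norm, k, r, rho = 0.3, tau = "auto",
                          base_seed = 0) {
  wh <- whiten_pca(norm, k)
  comp <- matrix(0, r * k, ncol(norm))
  colnames(comp) <- colnames(norm)
  rownames(comp) <- paste0("rep", rep(seq_len(r), each = k), "_k",
                           rep(seq_len(k), r))
  for (i in seq_len(r)) {
    fit <- run_ica_replicate(wh, seed = base_seed + i)
    g <- fit$spectra
    nrm <- sqrt(rowSums(g^2))
    comp[(i - 1) * k + seq_len(k), ] <- g / nrm
  }
  stack <- structure(list(components = comp, usages = NULL,
                          seeds = base_seed + seq_len(r), k = k, r = r),
                     class = "replicate_stack")
  flt <- knn_outlier_filter(stack, rho = rho, tau = tau)
  mrg <- cluster_and_merge(flt$components, k, seed = base_seed)
  usg <- refit_usage(norm, mrg$spectra_l1, nonneg = FALSE)
  structure(list(spectra_l1 = mrg$spectra_l1,
                 usage = usg$usage,
                 usage_norm = NULL,
                 spectra_tpm = NULL,
                 knn_distances = flt$distances,
                 kept = flt$kept,
                 cluster = mrg$cluster,
                 params = list(rho = rho, tau = flt$tau, k = k, r = r)),
            class = "cnmf_consensus")
}
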