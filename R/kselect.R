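#' Stability / reconstruction-error diagnostic over a range of K
#'
#' For each candidate K, runs `r` NMF replicates, clusters the full stacked
#' component set with KMeans (no outlier filtering -- both diagnostics
#' deliberately see every component), and reports (1) the mean silhouette
#' width of the stacked l2-normalized components under their cluster labels
#' (Euclidean metric) as a stability score, and (2) the Frobenius
#' reconstruction error `||norm - U G||_F` of the unfiltered consensus
#' solution after the NNLS usage refit. The diagnostics are advisory: high
#' stability with low error suggests a good K, but the maximum-stability
#' solution can hide true signal, so no K is auto-selected.
#'
#' @param norm Cells x H variance-scaled matrix.
#' @param k_values Integer vector of candidate K (each >= 2).
#' @param r Replicates per K (a smaller value than the final run, default
#'   20, keeps the sweep cheap).
#' @param base_seed Base seed for the replicates at each K.
#' @return An object of class `k_diagnostics`: a data frame with columns
#'   `k`, `silhouette`, `frobenius_error`.
#' @export
stability_error_curve <- function(norm, k_values, r = 20, base_seed = 0) {
  stopifnot(all(k_values >= 2), r >= 2)
  sil <- numeric(length(k_values))
  err <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    stack <- run_replicates(norm, k = k, r = r, base_seed = base_seed,
                            keep_usages = FALSE)
    cons <- consensus(stack, norm, filter = FALSE, seed = base_seed)
    d <- stats::dist(stack$components)
    sil[i] <- mean(cluster::silhouette(cons$cluster, d)[, "sil_width"])
    recon <- cons$usage %*% cons$spectra_l1
    err[i] <- sqrt(sum((norm - recon)^2))
  }
  structure(data.frame(k = k_values, silhouette = sil,
                       frobenius_error = err),
            class = c("k_diagnostics", "data.frame"))
}

#' PCA scree: proportion of variance explained per principal component
#'
#' A second aid for choosing K: since K principal components always span at
#' least as large a subspace as K NMF components, the scree elbow bounds
#' the number of programs from below. Centering is applied for the PCA only
#' and never touches the NMF input.
#'
#' @param norm Cells x H matrix.
#' @param n_components Number of leading PCs to return (default all).
#' @return Numeric vector of variance fractions, non-increasing, summing
#'   to 1 over all PCs.
#' @export
pca_scree <- function(norm, n_components = NULL) {
  pc <- stats::prcomp(norm, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_components)) frac <- frac[seq_len(n_components)]
  frac
}
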