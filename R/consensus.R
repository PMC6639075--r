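#' @title Consensus step: outlier filtering, clustering, median merge and
#'   refits
#' @description
#' Components from many NMF replicates are merged into K consensus gene
#' expression programs: rows with a high mean Euclidean distance to their
#' nearest neighbours are dropped (they tend to be splits/merges of true
#' programs found in only a few replicates), the survivors are clustered
#' with KMeans into K groups, each group is collapsed to its per-gene
#' median and l1-normalized, per-cell usages are refit by non-negative
#' least squares against the fixed consensus spectra, and finally spectra
#' are re-expressed in TPM units over all genes by per-gene NNLS against
#' the normalized usages.
#' @name consensus
NULL

# squared Euclidean distances between rows of a and rows of b
row_dist <- function(a, b = a) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Filter outlier components by mean distance to nearest neighbours
#'
#' For each of the stacked components, computes the mean Euclidean distance
#' to its `L = round(rho * R)` nearest other components (self excluded).
#' Components whose mean distance is below `tau` (strictly) are kept. `rho`
#' is the fraction of replicates that must have found an approximately
#' matching component for it to survive; `tau` defines "approximately
#' matching" in l2-normalized component space.
#'
#' @param stack A `replicate_stack` from [run_replicates()], or a plain
#'   matrix of stacked components (then `r` must be given).
#' @param rho Neighbour fraction in (0, 1] (default 0.3).
#' @param tau Distance threshold, or `"auto"` to place it at the knee of
#'   the sorted distance curve (the point of maximum distance to the chord
#'   joining the curve's endpoints), which truncates the long tail of the
#'   distance histogram.
#' @param r Number of replicates (taken from `stack` when available).
#' @return A list with `components` (kept rows), `distances` (all mean-KNN
#'   distances, for the diagnostic histogram), `kept` (logical mask),
#'   `tau` (the threshold actually used) and `l`.
#' @export
knn_outlier_filter <- function(stack, rho = 0.3, tau = "auto", r = NULL) {
  comp <- if (inherits(stack, "replicate_stack")) stack$components else stack
  if (is.null(r)) {
    if (!inherits(stack, "replicate_stack")) stop("r must be supplied")
    r <- stack$r
  }
  stopifnot(rho > 0, rho <= 1)
  l <- max(1L, as.integer(round(rho * r)))
  if (l >= nrow(comp)) stop("round(rho * R) must be smaller than the stack")
  d <- row_dist(comp)
  diag(d) <- Inf
  dist_knn <- apply(d, 1, function(row) mean(sort.int(row, partial = l)[seq_len(l)]))
  if (identical(tau, "auto")) {
    tau <- knee_threshold(dist_knn)
  }
  stopifnot(is.numeric(tau), tau > 0)
  kept <- dist_knn < tau
  if (!any(kept)) {
    stop("all components filtered out at tau = ", tau,
         "; inspect the distance histogram and raise tau")
  }
  list(components = comp[kept, , drop = FALSE], distances = dist_knn,
       kept = kept, tau = tau, l = l)
}

# knee of the sorted-distance curve: max vertical distance to the chord
knee_threshold <- function(dist_knn) {
  s <- sort(dist_knn)
  n <- length(s)
  t <- (seq_len(n) - 1) / (n - 1)
  chord <- s[1] + t * (s[n] - s[1])
  s[which.max(chord - s)]
}

#' Cluster surviving components and merge each cluster to its median
#'
#' KMeans (Euclidean, K clusters, 10 restarts, seeded) on the filtered
#' component rows; each cluster is collapsed to its per-gene median and the
#' merged rows are l1-normalized so every consensus program is a
#' relative-weight vector summing to 1.
#'
#' @param components Filtered components matrix (rows l2-normalized).
#' @param k Number of consensus programs.
#' @param seed Seed for the KMeans restarts.
#' @param nstart KMeans restarts (default 10).
#' @return A list with `spectra_l1` (k x genes, rows summing to 1),
#'   `spectra_raw` (the unnormalized medians) and `cluster` (per-row
#'   assignments).
#' @export
cluster_and_merge <- function(components, k, seed = 0, nstart = 10) {
  if (nrow(components) < k) {
    stop("fewer surviving components (", nrow(components),
         ") than clusters (", k, ")")
  }
  km <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(components, centers = k, nstart = nstart,
                                 iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, k) > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("KMeans failed to produce k non-empty clusters")
  med <- matrix(0, k, ncol(components))
  for (cl in seq_len(k)) {
    rows <- components[km$cluster == cl, , drop = FALSE]
    med[cl, ] <- apply(rows, 2, stats::median)
  }
  l1 <- rowSums(abs(med))
  spectra <- med
  spectra[l1 > 0, ] <- med[l1 > 0, , drop = FALSE] / l1[l1 > 0]
  dimnames(spectra) <- list(paste0("gep_", seq_len(k)), colnames(components))
  dimnames(med) <- dimnames(spectra)
  list(spectra_l1 = spectra, spectra_raw = med, cluster = km$cluster)
}

#' Refit per-cell usages against fixed consensus spectra
#'
#' Solves, for every cell i, `min ||norm_i - sum_k U_ik * spectra_k||_2`
#' subject to `U_ik >= 0` (one NNLS per cell with a shared design), then
#' row-normalizes usages to sum to 1. Cells whose profile is orthogonal to
#' all spectra get an all-zero usage row, which is left as zeros and
#' reported rather than normalized.
#'
#' @param norm Cells x H variance-scaled matrix.
#' @param spectra_l1 K x H consensus spectra.
#' @param nonneg Use NNLS (default). `FALSE` uses unconstrained least
#'   squares (needed when spectra may be negative, as for consensus ICA).
#' @return A list with `usage` (cells x K raw coefficients),
#'   `usage_norm` (rows summing to 1; all-zero rows kept) and
#'   `zero_cells` (indices of all-zero usage rows).
#' @export
refit_usage <- function(norm, spectra_l1, nonneg = TRUE) {
  a <- t(spectra_l1)                       # H x K design
  if (nonneg) {
    u <- t(nnls_multi(a, t(norm)))
  } else {
    u <- t(qr.solve(a, t(norm)))
  }
  dimnames(u) <- list(rownames(norm), rownames(spectra_l1))
  tot <- rowSums(u)
  zero <- which(tot == 0)
  un <- u
  nz <- tot != 0
  un[nz, ] <- u[nz, , drop = FALSE] / tot[nz]
  if (length(zero)) {
    warning(length(zero), " cell(s) received all-zero usage; left unnormalized")
  }
  list(usage = u, usage_norm = un, zero_cells = zero)
}

#' Re-express consensus spectra in TPM units over all genes
#'
#' With the normalized usage matrix fixed, fits one NNLS per gene:
#' `min ||T_j - usage_norm %*% g_j||_2` with `g_j >= 0`. Because T covers
#' all genes (including ones excluded from factorization), the result is a
#' K x M spectra matrix in transcripts-per-million units whose entries are
#' the expected TPM increase of gene j per unit of normalized usage of
#' program k.
#'
#' @param tpm Cells x M TPM matrix.
#' @param usage_norm Cells x K normalized usage matrix.
#' @return K x M non-negative spectra matrix in TPM units.
#' @export
refit_spectra_tpm <- function(tpm, usage_norm) {
  g <- nnls_multi(usage_norm, tpm)
  rownames(g) <- colnames(usage_norm)
  g
}

#' Consensus step over a replicate stack
#'
#' Applies [knn_outlier_filter()], [cluster_and_merge()], [refit_usage()]
#' and (optionally) [refit_spectra_tpm()] in sequence.
#'
#' @param stack A `replicate_stack`.
#' @param norm The variance-scaled matrix the replicates were fit to.
#' @param rho,tau Outlier-filter parameters (see [knn_outlier_filter()]);
#'   `filter = FALSE` skips filtering entirely (used by the K-selection
#'   diagnostic).
#' @param tpm Optional cells x M TPM matrix for the TPM-unit refit.
#' @param seed Seed for KMeans.
#' @param filter Apply the outlier filter (default TRUE).
#' @return An object of class `cnmf_consensus` with `spectra_l1`,
#'   `usage`, `usage_norm`, `spectra_tpm` (or NULL), `knn_distances`,
#'   `kept`, `cluster`, and the parameters used.
#' @export
consensus <- function(stack, norm, rho = 0.3, tau = "auto", tpm = NULL,
                      seed = 0, filter = TRUE) {
  if (filter) {
    flt <- knn_outlier_filter(stack, rho = rho, tau = tau)
    comp <- flt$components
    distances <- flt$distances
    kept <- flt$kept
    tau_used <- flt$tau
  } else {
    comp <- stack$components
    distances <- NULL
    kept <- rep(TRUE, nrow(comp))
    tau_used <- NA_real_
  }
  mrg <- cluster_and_merge(comp, stack$k, seed = seed)
  usg <- refit_usage(norm, mrg$spectra_l1)
  spectra_tpm <- if (!is.null(tpm)) refit_spectra_tpm(tpm, usg$usage_norm)
  structure(list(spectra_l1 = mrg$spectra_l1,
                 usage = usg$usage,
                 usage_norm = usg$usage_norm,
                 zero_cells = usg$zero_cells,
                 spectra_tpm = spectra_tpm,
                 knn_distances = distances,
                 kept = kept,
                 cluster = mrg$cluster,
                 params = list(rho = rho, tau = tau_used, k = stack$k,
                               r = stack$r)),
            class = "cnmf_consensus")
}

#' End-to-end consensus NMF
#'
#' Convenience wrapper running [preprocess()], [run_replicates()] and
#' [consensus()] on a raw count matrix.
#'
#' @param raw Cells x genes integer count matrix.
#' @param k Number of programs.
#' @param r Number of NMF replicates.
#' @param rho,tau Outlier-filter parameters.
#' @param h Number of over-dispersed genes.
#' @param seed Base seed (replicates use `seed + 1 ... seed + r`).
#' @param ... Passed to [preprocess()].
#' @return A list with `preprocess` (class `cnmf_preprocess`), `stack`
#'   (class `replicate_stack`) and `consensus` (class `cnmf_consensus`,
#'   including TPM-unit spectra).
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_params(n_cells = 300, n_genes = 500,
#'                                    activity_n_genes = 80, seed = 1))
#' fit <- cnmf(sim$counts, k = 14, r = 10, tau = "auto", h = 200,
#'             min_counts = 100)
#' dim(fit$consensus$spectra_tpm)
#' }
#' @export
cnmf <- function(raw, k, r = 50, rho = 0.3, tau = "auto", h = 2000,
                 seed = 0, ...) {
  prep <- preprocess(raw, h = h, ...)
  stack <- run_replicates(prep$norm, k = k, r = r, base_seed = seed)
  cons <- consensus(stack, prep$norm, rho = rho, tau = tau,
                    tpm = prep$tpm[, colnames(prep$filtered_counts),
                                   drop = FALSE],
                    seed = seed)
  list(preprocess = prep, stack = stack, consensus = cons)
}
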