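#' @title Preprocessing: filtering, over-dispersed gene selection, variance
#'   scaling and TPM
#' @description
#' The factorization input is built in a fixed order: (1) remove low-count
#' cells and rarely detected genes, (2) select the H most over-dispersed
#' genes by the v-score, (3) scale each selected gene to unit sample
#' variance. Selection happens before scaling on purpose: after scaling,
#' noise-driven variation in low-variance genes sits on the same scale as
#' biological variation. Counts are never log-transformed, centered, or
#' per-cell normalized -- non-negativity must be preserved for NMF, and
#' cells with more counts are allowed to contribute more information.
#' @name preprocess
NULL

#' Filter cells by total counts and genes by detection rate
#'
#' Removes cells with fewer than `min_counts` total UMIs and genes detected
#' (count > 0) in fewer than `ceiling(n_cells / 500)` of the retained cells
#' (i.e. genes not seen in at least 1 out of 500 cells).
#'
#' @param raw Cells x genes integer matrix with dimnames.
#' @param min_counts Minimum per-cell total (default 1000).
#' @param detection_rate A gene must be detected in at least
#'   `ceiling(n_cells * detection_rate)` cells (default 1/500).
#' @return Filtered cells x genes matrix.
#' @export
filter_cells_genes <- function(raw, min_counts = 1000, detection_rate = 1 / 500) {
  stopifnot(!is.null(rownames(raw)), !is.null(colnames(raw)))
  keep_cells <- rowSums(raw) >= min_counts
  if (!any(keep_cells)) {
    stop("cell filter removed every cell (all totals < ", min_counts, ")")
  }
  out <- raw[keep_cells, , drop = FALSE]
  min_cells <- ceiling(nrow(out) * detection_rate)
  keep_genes <- colSums(out > 0) >= min_cells
  if (!any(keep_genes)) {
    stop("gene detection filter removed every gene")
  }
  out[, keep_genes, drop = FALSE]
}

#' Over-dispersion v-scores
#'
#' Scores each gene's variability in excess of technical noise. The Fano
#' factor `F = var/mean` of a Poisson gene is 1; under the gamma-Poisson
#' (biological-coefficient-of-variation) noise typical of droplet data,
#' the technical null Fano rises with the mean as
#' `F_null(mu) = c0 + c1*sqrt(mu) + c2*mu` (the exact form when the
#' per-entry coefficient of variation is `b0 + 1/sqrt(mu)` times a
#' gene-level factor). The null is fit from the data: running
#' 33rd-percentile points of Fano within 50 log-mean bins (the percentile
#' keeps differentially expressed genes from inflating the null) are fit
#' against the basis `(1, sqrt(mu), mu)` by non-negative least squares.
#' The v-score is `F / F_null(mean)`: each gene's Fano factor relative to
#' the fitted technical null at its mean. `method = "fano"` skips the
#' null fit and returns plain Fano factors.
#'
#' @param counts Cells x genes count matrix.
#' @param method `"vscore"` (default) or `"fano"`.
#' @return Numeric vector of scores, one per gene (NA for all-zero genes).
#' @export
vscores <- function(counts, method = c("vscore", "fano")) {
  method <- match.arg(method)
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  score <- rep(NA_real_, length(mu))
  pos <- mu > 0
  ff <- v[pos] / mu[pos]
  if (method == "fano") {
    score[pos] <- ff
    names(score) <- colnames(counts)
    return(score)
  }
  qp <- running_quantile(log(mu[pos]), ff, p = 0.33, n_bins = 50)
  basis <- cbind(1, sqrt(exp(qp$x)), exp(qp$x))
  cf <- nnls_gram(crossprod(basis), crossprod(basis, qp$y))
  null_ff <- pmax(cf[1] + cf[2] * sqrt(mu[pos]) + cf[3] * mu[pos], 1e-8)
  score[pos] <- ff / null_ff
  names(score) <- colnames(counts)
  score
}

# running quantile of y within n_bins equal-width bins of x; empty bins dropped
running_quantile <- function(x, y, p, n_bins) {
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  idx <- findInterval(x, br, rightmost.closed = TRUE)
  xs <- tapply(x, idx, mean)
  ys <- tapply(y, idx, stats::quantile, probs = p, names = FALSE)
  list(x = as.numeric(xs), y = as.numeric(ys))
}

#' Select the H most over-dispersed genes
#'
#' Deterministic given the counts: genes are ranked by decreasing v-score
#' with ties broken by gene name, and the top `h` returned in that order.
#'
#' @param counts Cells x genes count matrix (post-filtering).
#' @param h Number of genes to keep (the method's default is 2000).
#' @param method Passed to [vscores()].
#' @return A list with `genes` (character, length `h`) and `scores` (all
#'   gene scores).
#' @export
select_overdispersed <- function(counts, h = 2000, method = "vscore") {
  stopifnot(h >= 1)
  if (h > ncol(counts)) {
    stop("h (", h, ") exceeds the number of genes (", ncol(counts), ")")
  }
  sc <- vscores(counts, method = method)
  ord <- order(-sc, colnames(counts), na.last = TRUE)
  list(genes = colnames(counts)[ord[seq_len(h)]], scores = sc)
}

#' Scale selected genes to unit sample variance
#'
#' Divides each selected gene column by its sample standard deviation
#' (n - 1 denominator). No centering and no log transform, so the result
#' stays non-negative.
#'
#' @param counts Cells x genes matrix.
#' @param genes Character vector of gene names to keep and scale.
#' @return A list with `norm` (cells x length(genes) matrix, unit-variance
#'   columns) and `gene_sd` (the standard deviations used).
#' @export
variance_scale <- function(counts, genes) {
  x <- counts[, genes, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) cannot be scaled; remove: ",
         paste(utils::head(genes[sds == 0], 5), collapse = ", "))
  }
  list(norm = sweep(x, 2, sds, `/`), gene_sd = sds)
}

#' Transcripts per million
#'
#' Scales each cell's counts to sum to 1e6. Computed over all genes --
#' including ones later removed by the detection filter -- so that TPM
#' denominators reflect the full library.
#'
#' @param counts Cells x genes matrix with positive row totals.
#' @return Matrix of the same shape with rows summing to 1e6.
#' @export
compute_tpm <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(rownames(counts)[totals <= 0], 5), collapse = ", "))
  }
  1e6 * counts / totals
}

#' Run the full preprocessing pipeline
#'
#' Filter cells and genes, compute the all-genes TPM matrix for the
#' retained cells, select the `h` most over-dispersed genes, and scale them
#' to unit variance. For full-transcript (non-UMI) data set
#' `scale_from_tpm = TRUE` to variance-scale the selected genes of the TPM
#' matrix instead of the raw counts.
#'
#' @param raw Cells x genes integer count matrix.
#' @param h Number of over-dispersed genes (default 2000).
#' @param scale_from_tpm Scale TPM values instead of raw counts (for
#'   full-transcript data).
#' @param method Over-dispersion statistic, see [vscores()].
#' @param min_counts,detection_rate Passed to [filter_cells_genes()].
#' @return An object of class `cnmf_preprocess` with elements
#'   `filtered_counts` (cells x retained genes), `norm` (cells x h, the
#'   factorization input), `overdispersed_genes`, `gene_sd`, `tpm`
#'   (cells x all genes, rows sum to 1e6), and `vscores`.
#' @export
preprocess <- function(raw, h = 2000, scale_from_tpm = FALSE,
                       method = "vscore", min_counts = 1000,
                       detection_rate = 1 / 500) {
  filtered <- filter_cells_genes(raw, min_counts, detection_rate)
  tpm <- compute_tpm(raw[rownames(filtered), , drop = FALSE])
  sel <- select_overdispersed(filtered, h = h, method = method)
  src <- if (scale_from_tpm) tpm[, colnames(filtered), drop = FALSE] else filtered
  vs <- variance_scale(src, sel$genes)
  structure(list(filtered_counts = filtered,
                 norm = vs$norm,
                 overdispersed_genes = sel$genes,
                 gene_sd = vs$gene_sd,
                 tpm = tpm,
                 vscores = sel$scores),
            class = "cnmf_preprocess")
}
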