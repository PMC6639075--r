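#' Marker-gene association by multivariate regression on z-scored TPM
#'
#' For every gene j, the TPM profile is z-scored,
#' `Z_j = (T_j - mean_j) / sd_j`, and regressed (ordinary least squares,
#' no intercept -- z-scoring removes the gene mean) against the
#' un-normalized consensus usage matrix. The coefficient `beta_kj` is the
#' number of expression standard deviations gene j is expected to rise per
#' additional unit of usage of program k, holding other usages fixed;
#' regressing against all usages jointly avoids misattributing activity
#' genes to the identity program of the cell types that express the
#' activity. No p-values are reported: expression residuals are far from
#' normal, so the coefficients are meaningful but their OLS p-values are
#' not.
#'
#' When the usage matrix is a cluster indicator matrix, `beta_kj` is
#' exactly the mean z-scored expression of gene j in cluster k, which is
#' how hard-clustering baselines are scored on the same footing.
#'
#' @param tpm Cells x M TPM matrix (genes of the filtered count matrix).
#' @param usage Cells x K un-normalized usage matrix.
#' @return An object of class `marker_table`: `beta` (K x M coefficients),
#'   `gene_mean`, `gene_sd`, and `dropped` (genes with zero variance,
#'   excluded from `beta`).
#' @export
marker_regression <- function(tpm, usage) {
  mu <- colMeans(tpm)
  sd_ <- apply(tpm, 2, stats::sd)
  dropped <- colnames(tpm)[sd_ == 0]
  keep <- sd_ > 0
  z <- sweep(sweep(tpm[, keep, drop = FALSE], 2, mu[keep], `-`),
             2, sd_[keep], `/`)
  utu <- crossprod(usage)
  utz <- crossprod(usage, z)
  beta <- tryCatch(solve(utu, utz), error = function(e) NULL)
  if (is.null(beta)) {
    warning("rank-deficient usage matrix; returning the minimum-norm solution")
    sv <- svd(utu)
    d_inv <- ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
    beta <- sv$v %*% (d_inv * crossprod(sv$u, utz))
  }
  dimnames(beta) <- list(colnames(usage), colnames(z))
  structure(list(beta = beta, gene_mean = mu, gene_sd = sd_,
                 dropped = dropped),
            class = "marker_table")
}

#' Gene-set enrichment of one program's marker coefficients
#'
#' One-sided Mann-Whitney U test (normal approximation with tie
#' correction) comparing the coefficients of genes in the set against
#' those of genes outside it, after flooring all negative coefficients at
#' zero. Negative coefficients mark genes expressed more highly in cells
#' that do not use the program; flooring them keeps variation among
#' genes unrelated to the program (usually the large majority) from
#' driving the rank statistic. Being a rank test, the result is invariant
#' to any monotone rescaling of the positive coefficients.
#'
#' @param beta_k Named coefficient vector for one program (a row of the
#'   [marker_regression()] `beta`).
#' @param geneset Character vector of gene names; must intersect the
#'   scored genes and must not cover all of them.
#' @return A list with `p_value` (one-sided, geneset greater), `statistic`
#'   (the Mann-Whitney U for the geneset), `n_set`, `n_background`.
#' @export
geneset_enrichment <- function(beta_k, geneset) {
  stopifnot(!is.null(names(beta_k)))
  in_set <- names(beta_k) %in% geneset
  if (!any(in_set)) stop("geneset has no overlap with scored genes")
  if (all(in_set)) stop("geneset covers all scored genes")
  x <- pmax(beta_k, 0)
  a <- x[in_set]
  b <- x[!in_set]
  if (length(unique(x)) == 1) {
    # fully tied after flooring: the normal approximation is 0/0; by
    # symmetry the one-sided p is 1/2
    return(list(p_value = 0.5, statistic = length(a) * length(b) / 2,
                n_set = length(a), n_background = length(b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       n_set = length(a), n_background = length(b))
}

#' Enrichment of many gene sets against all programs
#'
#' Applies [geneset_enrichment()] to every program x gene-set pair and
#' reports raw p-values plus, as a clearly separated extra column,
#' Benjamini-Hochberg FDR across the gene sets within each program.
#'
#' @param markers A `marker_table` from [marker_regression()].
#' @param genesets Named list of character vectors.
#' @return Data frame with columns `program`, `geneset`, `statistic`,
#'   `p_value`, `fdr_bh`.
#' @export
enrich_genesets <- function(markers, genesets) {
  stopifnot(inherits(markers, "marker_table"), length(genesets) > 0)
  res <- do.call(rbind, lapply(rownames(markers$beta), function(prog) {
    rows <- lapply(names(genesets), function(gs) {
      e <- geneset_enrichment(markers$beta[prog, ], genesets[[gs]])
      data.frame(program = prog, geneset = gs, statistic = e$statistic,
                 p_value = e$p_value)
    })
    out <- do.call(rbind, rows)
    out$fdr_bh <- stats::p.adjust(out$p_value, method = "BH")
    out
  }))
  rownames(res) <- NULL
  res
}
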