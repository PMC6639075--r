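#' Simulation parameters for the single-cell GEP simulator
#'
#' Builds and validates the parameter set for [simulate_dataset()]. Defaults
#' are the benchmark conditions used throughout the package: 13 identity
#' programs plus one activity program expressed by 30% of the cells of four
#' cell types at a usage drawn uniformly from \[0.1, 0.7\], a 6% doublet
#' rate, and Splatter-style gamma gene means, lognormal differential
#' expression (DE) factors, lognormal library sizes and biological
#' coefficient of variation (BCV) overdispersion. The gamma/lognormal
#' hyperparameters default to values fit to a real organoid dataset
#' (`mean_shape = 0.34`, `mean_rate = 7.68`, `lib_loc = 7.64`,
#' `lib_scale = 0.78`, etc.).
#'
#' @param n_cells Number of singlet cells to simulate (doublets are appended
#'   on top of these; see [make_doublets()]).
#' @param n_genes Number of genes.
#' @param n_identity Number of identity programs (cell types).
#' @param de_prob Probability that a gene is differentially expressed in an
#'   identity program.
#' @param de_loc,de_scale Location and scale of the lognormal DE factor
#'   distribution (natural-log parameterization, as in Splatter). `de_loc`
#'   controls the signal-to-noise of the simulation.
#' @param activity_n_genes Number of genes carrying DE factors in the
#'   activity program.
#' @param activity_celltypes Number of cell types that can express the
#'   activity program.
#' @param activity_frac Fraction of cells of those types that express it.
#' @param activity_usage_low,activity_usage_high Bounds of the uniform
#'   distribution of the activity usage phi in expressing cells.
#' @param doublet_rate Fraction of the final cells that are doublets.
#' @param mean_rate,mean_shape Gamma rate/shape of base gene mean expression.
#' @param lib_loc,lib_scale Lognormal location/scale of library sizes.
#' @param expout_prob,expout_loc,expout_scale Expression-outlier gene
#'   probability and lognormal factor location/scale.
#' @param bcv_dispersion,bcv_dof Common BCV and degrees of freedom of the
#'   inverse-chi-square gene-level BCV inflation.
#' @param celltype_probs Multinomial cell-type proportions; default uniform.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [sim_preset()] for the canonical benchmark presets.
#' @export
sim_params <- function(n_cells = 2000,
                       n_genes = 5000,
                       n_identity = 13,
                       de_prob = 0.025,
                       de_loc = 1.0,
                       de_scale = 1.0,
                       activity_n_genes = 800,
                       activity_celltypes = 4,
                       activity_frac = 0.30,
                       activity_usage_low = 0.10,
                       activity_usage_high = 0.70,
                       doublet_rate = 0.06,
                       mean_rate = 7.68,
                       mean_shape = 0.34,
                       lib_loc = 7.64,
                       lib_scale = 0.78,
                       expout_prob = 0.00286,
                       expout_loc = 6.15,
                       expout_scale = 0.49,
                       bcv_dispersion = 0.448,
                       bcv_dof = 22.087,
                       celltype_probs = NULL,
                       seed = 1L) {
  if (is.null(celltype_probs)) {
    celltype_probs <- rep(1 / n_identity, n_identity)
  }
  p <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
            n_identity = as.integer(n_identity), de_prob = de_prob,
            de_loc = de_loc, de_scale = de_scale,
            activity_n_genes = as.integer(activity_n_genes),
            activity_celltypes = as.integer(activity_celltypes),
            activity_frac = activity_frac,
            activity_usage_low = activity_usage_low,
            activity_usage_high = activity_usage_high,
            doublet_rate = doublet_rate,
            mean_rate = mean_rate, mean_shape = mean_shape,
            lib_loc = lib_loc, lib_scale = lib_scale,
            expout_prob = expout_prob, expout_loc = expout_loc,
            expout_scale = expout_scale,
            bcv_dispersion = bcv_dispersion, bcv_dof = bcv_dof,
            celltype_probs = celltype_probs, seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_cells >= 2, p$n_genes >= 1, p$n_identity >= 1)
  probs <- c(p$de_prob, p$activity_frac, p$doublet_rate, p$expout_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  if (p$doublet_rate >= 1) stop("doublet_rate must be < 1")
  if (p$activity_celltypes > p$n_identity) {
    stop("activity_celltypes cannot exceed n_identity")
  }
  if (p$activity_usage_low >= p$activity_usage_high) {
    stop("activity_usage_low must be < activity_usage_high")
  }
  if (p$n_genes < p$activity_n_genes) {
    stop("n_genes must be >= activity_n_genes")
  }
  if (length(p$celltype_probs) != p$n_identity) {
    stop("celltype_probs must have one entry per identity program")
  }
  if (abs(sum(p$celltype_probs) - 1) > 1e-8) {
    stop("celltype_probs must sum to 1")
  }
  invisible(p)
}

#' Canonical simulation presets
#'
#' `"benchmark"` is the reduced-scale benchmark used by the package's
#' evaluation harness (2000 singlets, 5000 genes, 800 activity genes, 6%
#' doublets, `de_loc = 1`). `"doublet50"` is the same with a 50% doublet
#' rate. `"skewed"` replaces the uniform cell-type proportions with a
#' realistic 15-type skewed composition spanning two orders of magnitude.
#'
#' @param name One of `"benchmark"`, `"doublet50"`, `"skewed"`.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_preset <- function(name = c("benchmark", "doublet50", "skewed"), ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    benchmark = list(),
    doublet50 = list(doublet_rate = 0.50),
    skewed = list(
      n_identity = 15L,
      celltype_probs = c(0.215, 0.210, 0.195, 0.130, 0.0924, 0.0328,
                         0.028, 0.0269, 0.0149, 0.0119, 0.0114, 0.009,
                         0.009, 0.008, 0.006)))
  if (name == "skewed") {
    # proportions are quoted to 3 significant digits; renormalize exactly
    base$celltype_probs <- base$celltype_probs / sum(base$celltype_probs)
  }
  do.call(sim_params, utils::modifyList(base, over))
}
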