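#' @title Splatter-style single-cell simulator with an activity program and
#'   doublets
#' @description
#' The simulator draws gene expression programs (GEPs) the way Splatter
#' draws group profiles -- gamma base means, median-based expression-outlier
#' replacement, lognormal differential-expression factors -- then mixes one
#' activity program into a subset of cells of a few cell types, applies
#' lognormal library sizes and inverse-chi-square BCV overdispersion, draws
#' Poisson counts, and finally appends doublets built by summing and
#' down-sampling pairs of singlets. All randomness comes from R's RNG: the
#' exported pipeline entry point [simulate_dataset()] seeds it once from
#' `params$seed`, while the individual stage functions consume the current
#' RNG state so they can be composed and tested independently.
#' @name simulate
NULL

#' Sample ground-truth gene expression programs
#'
#' Draws the `n_identity` identity programs and one activity program.
#' Base gene means come from `Gamma(mean_shape, rate = mean_rate)`;
#' expression-outlier genes (probability `expout_prob`) have their mean
#' replaced by `median(means) * LogNormal(expout_loc, expout_scale)`.
#' Each identity program multiplies a `de_prob` fraction of genes by
#' lognormal DE factors (up-regulation only); the activity program applies
#' DE factors to exactly `activity_n_genes` randomly designated genes.
#' Every program is renormalized to a relative-proportion vector so that
#' the simulated library size sets a cell's expected total count.
#'
#' @param params A [sim_params()] object.
#' @return A list with `programs` (`(n_identity+1) x n_genes` matrix of
#'   strictly positive proportions, last row the activity program),
#'   `de_foldchange` (same shape; 1 for non-DE genes), `base_means`, and
#'   `activity_genes` (indices of the designated activity genes).
#' @export
sample_programs <- function(params) {
  validate_sim_params(params)
  m <- params$n_genes
  means <- stats::rgamma(m, shape = params$mean_shape, rate = params$mean_rate)
  out_mask <- stats::runif(m) < params$expout_prob
  if (any(out_mask)) {
    fac <- stats::rlnorm(sum(out_mask), params$expout_loc, params$expout_scale)
    means[out_mask] <- stats::median(means) * fac
  }
  n_prog <- params$n_identity + 1L
  fc <- matrix(1, n_prog, m)
  for (p in seq_len(params$n_identity)) {
    de_mask <- stats::runif(m) < params$de_prob
    if (any(de_mask)) {
      fc[p, de_mask] <- stats::rlnorm(sum(de_mask), params$de_loc,
                                      params$de_scale)
    }
  }
  act_genes <- sample.int(m, params$activity_n_genes)
  fc[n_prog, act_genes] <- stats::rlnorm(params$activity_n_genes,
                                         params$de_loc, params$de_scale)
  programs <- sweep(fc, 2, means, `*`)
  programs <- programs / rowSums(programs)
  dimnames(programs) <- list(
    c(paste0("identity_", seq_len(params$n_identity)), "activity"),
    paste0("gene_", seq_len(m)))
  dimnames(fc) <- dimnames(programs)
  list(programs = programs, de_foldchange = fc, base_means = means,
       activity_genes = sort(act_genes))
}

#' Assign cells to identity programs and activity usages
#'
#' Cell types are multinomial with `celltype_probs`. `activity_celltypes`
#' types are designated (a random subset under the current RNG state), and
#' within those types an `activity_frac` fraction of cells expresses the
#' activity program at a usage `phi ~ U(activity_usage_low,
#' activity_usage_high)`; all other cells have `phi = 0`.
#'
#' @param params A [sim_params()] object.
#' @return A list with integer `identity`, numeric `phi`, and
#'   `activity_types` (the designated type indices).
#' @export
assign_cells <- function(params) {
  validate_sim_params(params)
  n <- params$n_cells
  identity <- sample.int(params$n_identity, n, replace = TRUE,
                         prob = params$celltype_probs)
  activity_types <- sort(sample.int(params$n_identity,
                                    params$activity_celltypes))
  phi <- numeric(n)
  eligible <- which(identity %in% activity_types)
  expressing <- eligible[stats::runif(length(eligible)) < params$activity_frac]
  phi[expressing] <- stats::runif(length(expressing),
                                  params$activity_usage_low,
                                  params$activity_usage_high)
  list(identity = identity, phi = phi, activity_types = activity_types)
}

#' Simulate singlet counts from programs and assignments
#'
#' The pre-trended mean profile of cell i is the library-size-scaled mixture
#' `lambda_i = L_i * (phi_i * Z_act + (1 - phi_i) * Z_identity(i))` with
#' `L_i ~ LogNormal(lib_loc, lib_scale)`. Overdispersion follows the
#' Splatter BCV recipe: per gene j one chi-square draw gives an
#' inverse-chi-square factor `sqrt(bcv_dof / chisq_j)`, the per-entry BCV is
#' `(bcv_dispersion + 1/sqrt(lambda_ij)) * sqrt(bcv_dof / chisq_j)`, the
#' mean is perturbed by `Gamma(shape = 1/B^2, scale = lambda * B^2)` (so the
#' perturbed mean keeps expectation lambda and CV B), and counts are Poisson
#' around the perturbed mean.
#'
#' @param programs Program matrix from [sample_programs()].
#' @param assign Assignment list from [assign_cells()].
#' @param params A [sim_params()] object.
#' @return A list with the integer `counts` matrix (cells x genes) and the
#'   drawn `library_size` vector.
#' @export
simulate_counts <- function(programs, assign, params) {
  n <- length(assign$identity)
  act_row <- params$n_identity + 1L
  lib <- stats::rlnorm(n, params$lib_loc, params$lib_scale)
  mix <- (1 - assign$phi) * programs[assign$identity, , drop = FALSE] +
    assign$phi * matrix(programs[act_row, ], n, ncol(programs), byrow = TRUE)
  lambda <- lib * mix
  m <- ncol(lambda)
  chisq_fac <- sqrt(params$bcv_dof / stats::rchisq(m, df = params$bcv_dof))
  pos <- lambda > 0
  bcv <- (params$bcv_dispersion + 1 / sqrt(pmax(lambda, .Machine$double.xmin))) *
    matrix(chisq_fac, n, m, byrow = TRUE)
  perturbed <- matrix(0, n, m)
  perturbed[pos] <- stats::rgamma(sum(pos), shape = 1 / bcv[pos]^2,
                                  scale = lambda[pos] * bcv[pos]^2)
  counts <- matrix(0L, n, m)
  counts[pos] <- stats::rpois(sum(pos), perturbed[pos])
  dimnames(counts) <- list(paste0("cell_", seq_len(n)), colnames(programs))
  list(counts = counts, library_size = lib)
}

#' Down-sample a count vector to a target total without replacement
#'
#' Multivariate-hypergeometric down-sampling: observed molecules are removed
#' uniformly at random until `target` remain, so zeros stay zero and
#' expectations scale by `target / sum(x)`.
#'
#' @param x Non-negative integer vector.
#' @param target Target total, `<= sum(x)`.
#' @return Integer vector with `sum == target`.
#' @export
downsample_counts <- function(x, target) {
  total <- sum(x)
  stopifnot(target <= total, target >= 0)
  if (target == total) return(x)
  pool <- rep.int(seq_along(x), x)
  kept <- pool[sample.int(total, target)]
  out <- tabulate(kept, nbins = length(x))
  storage.mode(out) <- "integer"
  names(out) <- names(x)
  out
}

#' Append doublets to a singlet count matrix
#'
#' A deterministic number of doublets, `round(rate / (1 - rate) *
#' n_singlets)`, is appended so the doublet fraction of the output equals
#' `rate` up to rounding. Each doublet sums the count vectors of two
#' distinct singlets (parents drawn without replacement within a doublet,
#' with replacement across doublets) and down-samples the sum to the
#' maximum of the two parents' totals.
#'
#' @param counts Singlet cells x genes integer matrix.
#' @param rate Doublet rate in `[0, 1)`.
#' @return A list with the augmented `counts` matrix, `parents`
#'   (n_total x 2, `NA` for singlets), and logical `is_doublet`.
#' @export
make_doublets <- function(counts, rate) {
  stopifnot(rate >= 0, rate < 1)
  n <- nrow(counts)
  n_dbl <- round(rate / (1 - rate) * n)
  if (n_dbl > 0 && n < 2) stop("need at least 2 singlets to form doublets")
  if (n_dbl == 0) {
    return(list(counts = counts, is_doublet = rep(FALSE, n),
                parents = matrix(NA_integer_, n, 2)))
  }
  totals <- rowSums(counts)
  dbl <- matrix(0L, n_dbl, ncol(counts))
  parents <- matrix(NA_integer_, n + n_dbl, 2)
  for (d in seq_len(n_dbl)) {
    pr <- sample.int(n, 2)
    combined <- counts[pr[1], ] + counts[pr[2], ]
    dbl[d, ] <- downsample_counts(combined, max(totals[pr]))
    parents[n + d, ] <- pr
  }
  rownames(dbl) <- paste0("doublet_", seq_len(n_dbl))
  colnames(dbl) <- colnames(counts)
  list(counts = rbind(counts, dbl),
       is_doublet = c(rep(FALSE, n), rep(TRUE, n_dbl)),
       parents = parents)
}

#' Simulate a full dataset with ground truth
#'
#' Runs the whole generator -- programs, cell assignments, singlet counts,
#' doublets -- under a single seed, and returns counts together with a
#' `sim_truth` object recording everything the benchmark needs: per-cell
#' identity, activity usage phi, library size, doublet provenance, the true
#' program matrix and the per-gene DE fold-changes.
#'
#' For doublets, `identity` is the parent with the larger realized total
#' count and `phi` is the parent-total-weighted mean of the parents' phis
#' (a doublet's expression is the down-sampled sum of its parents, so this
#' is the activity fraction of its expected profile).
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_data` with `counts` (cells x genes integer
#'   matrix) and `truth` (class `sim_truth`).
#' @examples
#' sim <- simulate_dataset(sim_params(n_cells = 50, n_genes = 200,
#'                                    activity_n_genes = 40, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$is_doublet)
#' @export
simulate_dataset <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed)
  prog <- sample_programs(params)
  assign <- assign_cells(params)
  sim <- simulate_counts(prog$programs, assign, params)
  dbl <- make_doublets(sim$counts, params$doublet_rate)

  n_tot <- nrow(dbl$counts)
  singlet_totals <- rowSums(sim$counts)
  identity <- c(assign$identity, rep(NA_integer_, n_tot - params$n_cells))
  phi <- c(assign$phi, rep(NA_real_, n_tot - params$n_cells))
  lib <- c(sim$library_size, rep(NA_real_, n_tot - params$n_cells))
  for (i in which(dbl$is_doublet)) {
    pr <- dbl$parents[i, ]
    w <- singlet_totals[pr]
    identity[i] <- assign$identity[pr[which.max(w)]]
    phi[i] <- sum(w * assign$phi[pr]) / sum(w)
    lib[i] <- max(w)
  }
  truth <- structure(list(
    identity = identity,
    phi = phi,
    library_size = lib,
    is_doublet = dbl$is_doublet,
    parents = dbl$parents,
    activity_types = assign$activity_types,
    programs = prog$programs,
    de_foldchange = prog$de_foldchange,
    activity_genes = prog$activity_genes,
    params = params), class = "sim_truth")
  structure(list(counts = dbl$counts, truth = truth), class = "sim_data")
}
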