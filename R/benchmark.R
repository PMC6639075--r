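#' @title Benchmark harness: component matching, FDR-ROC, cell
#'   classification, and baselines
#' @description
#' Evaluates GEP recovery against simulation ground truth: inferred
#' components are matched to true programs by maximum Pearson correlation,
#' marker coefficients are turned into a sensitivity-vs-FDR curve using
#' the true DE fold-changes, and activity-expressing cells are called by
#' thresholding the normalized activity usage. The same evaluation path is
#' applied to the consensus-ICA and ground-truth-clustering baselines so
#' methods differ only in how the usage/spectra estimates are produced.
#' @name benchmark
NULL

#' Match inferred components to ground-truth programs
#'
#' Both matrices are restricted to a common gene set (normally the
#' over-dispersed genes) and the truth programs are divided by the sample
#' standard deviation of each gene, putting them on the scale of
#' components learned from variance-scaled data. Every inferred component
#' is then assigned to its maximum-Pearson truth program (with
#' replacement: several inferred components may map to one program).
#'
#' @param spectra Inferred K x H matrix (columns named by gene).
#' @param truth_programs True programs x genes matrix (proportions).
#' @param gene_sd Named per-gene standard deviations used to normalize the
#'   truth programs; NULL skips normalization (use when both inputs are
#'   already on a common scale).
#' @param scale_spectra Also divide the inferred spectra by `gene_sd`
#'   (use when the spectra are in the data's raw units, e.g. TPM).
#' @return A list with `assignment` (per inferred component, the index of
#'   its best truth program), `correlation` (K x n_truth Pearson matrix)
#'   and `best_cor`.
#' @export
match_components <- function(spectra, truth_programs, gene_sd = NULL,
                             scale_spectra = FALSE) {
  genes <- intersect(colnames(spectra), colnames(truth_programs))
  stopifnot(length(genes) >= 2)
  a <- spectra[, genes, drop = FALSE]
  b <- truth_programs[, genes, drop = FALSE]
  if (!is.null(gene_sd)) {
    sd_pos <- pmax(gene_sd[genes], 1e-12)
    b <- sweep(b, 2, sd_pos, `/`)
    if (scale_spectra) a <- sweep(a, 2, sd_pos, `/`)
  }
  cors <- stats::cor(t(a), t(b))
  assignment <- apply(cors, 1, which.max)
  list(assignment = assignment, correlation = cors,
       best_cor = cors[cbind(seq_len(nrow(cors)), assignment)])
}

#' Sensitivity-vs-FDR curve for one program's marker coefficients
#'
#' Genes with a ground-truth fold-change >= 2 are true positives for the
#' program, genes with fold-change exactly 1 are true negatives, and genes
#' in between are ignored. Sweeping the coefficient threshold gives
#' (sensitivity, FDR) pairs; the sensitivity at a target FDR is read off
#' the curve by linear interpolation at crossings, taking the best
#' sensitivity attainable at or below the target.
#'
#' @param scores Named coefficient vector (a row of a `marker_table` beta).
#' @param foldchange Named true fold-change vector for the same program.
#' @param fdr_target FDR at which to report sensitivity (default 0.05).
#' @return A list with `curve` (data frame: `threshold`, `sensitivity`,
#'   `fdr`), `sensitivity_at_fdr`, `n_pos`, `n_neg`.
#' @export
roc_with_fdr <- function(scores, foldchange, fdr_target = 0.05) {
  genes <- intersect(names(scores), names(foldchange))
  fc <- foldchange[genes]
  sc <- scores[genes]
  pos <- fc >= 2
  neg <- fc == 1
  use <- pos | neg
  sc <- sc[use]; pos <- pos[use]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0) stop("no true-positive genes (fold-change >= 2)")
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]; pos <- pos[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per distinct threshold
  sens <- tp[last] / n_pos
  fdr <- fp[last] / (tp[last] + fp[last])
  curve <- data.frame(threshold = sc[last], sensitivity = sens, fdr = fdr)
  # walk from the empty call set (sens 0, fdr 0) down the thresholds
  s <- c(0, sens); f <- c(0, fdr)
  best <- max(s[f <= fdr_target])
  for (i in seq_len(length(s) - 1)) {
    lo <- f[i]; hi <- f[i + 1]
    if ((lo < fdr_target && hi > fdr_target) ||
        (lo > fdr_target && hi < fdr_target)) {
      w <- (fdr_target - lo) / (hi - lo)
      best <- max(best, s[i] + w * (s[i + 1] - s[i]))
    }
  }
  list(curve = curve, sensitivity_at_fdr = best, n_pos = n_pos, n_neg = n_neg)
}

#' Classify activity-expressing cells by a usage threshold
#'
#' Cells whose normalized activity usage is at least `threshold` (default
#' 10%) are called positive. Sensitivity is computed over cells with true
#' phi > 0, specificity over cells with phi = 0, and the Pearson
#' correlation between inferred and true usage over the truly expressing
#' cells.
#'
#' @param activity_usage Normalized usage of the inferred activity program
#'   (one value per cell).
#' @param phi True per-cell activity usage.
#' @param threshold Usage call threshold (default 0.10).
#' @return A list with `sensitivity`, `specificity`, `usage_cor`,
#'   `n_expressing`, `n_nonexpressing`.
#' @export
classify_activity_cells <- function(activity_usage, phi, threshold = 0.10) {
  stopifnot(length(activity_usage) == length(phi))
  called <- activity_usage >= threshold
  expressing <- phi > 0
  list(sensitivity = mean(called[expressing]),
       specificity = mean(!called[!expressing]),
       usage_cor = if (sum(expressing) >= 3 &&
                       stats::sd(activity_usage[expressing]) > 0 &&
                       stats::sd(phi[expressing]) > 0)
         stats::cor(activity_usage[expressing], phi[expressing])
       else NA_real_,
       n_expressing = sum(expressing),
       n_nonexpressing = sum(!expressing))
}

#' Ground-truth hard-clustering baseline
#'
#' Assigns every cell to the cluster of its true identity program, except
#' cells with more than 40% true activity usage, which go to an activity
#' cluster. Each cluster's GEP is the mean TPM of its cells, and the
#' baseline is scored through the same marker-regression path using the
#' binary cluster-indicator matrix as the usage matrix (under which the
#' regression coefficients are exactly the cluster-mean z-scores).
#'
#' @param tpm Cells x M TPM matrix (filtered genes).
#' @param identity Integer true identity per cell.
#' @param phi True activity usage per cell.
#' @param n_identity Number of identity programs.
#' @param activity_cutoff Usage above which a cell joins the activity
#'   cluster (default 0.40, strict).
#' @return A list with `usage` (cells x clusters indicator matrix, empty
#'   clusters dropped), `geps` (cluster-mean TPM), `cluster` (per-cell
#'   assignment), `activity_col` (indicator column of the activity
#'   cluster, or NA if empty).
#' @export
ground_truth_clustering <- function(tpm, identity, phi, n_identity,
                                    activity_cutoff = 0.40) {
  cl <- ifelse(phi > activity_cutoff, n_identity + 1L, identity)
  present <- sort(unique(cl))
  usage <- matrix(0, nrow(tpm), length(present))
  usage[cbind(seq_along(cl), match(cl, present))] <- 1
  labels <- ifelse(present > n_identity, "activity",
                   paste0("identity_", present))
  dimnames(usage) <- list(rownames(tpm), labels)
  geps <- t(usage) %*% tpm / colSums(usage)
  list(usage = usage, geps = geps, cluster = cl,
       activity_col = if ((n_identity + 1L) %in% present)
         match(n_identity + 1L, present) else NA_integer_)
}

#' Run the simulation benchmark for one or more methods
#'
#' Simulates (or reuses) a dataset, preprocesses it, fits the requested
#' methods and evaluates each one against ground truth: component-truth
#' matching, activity detection (best Pearson with the true activity
#' program > 0.8), the sensitivity-at-FDR operating point for
#' activity-program genes, and -- for cNMF, which has interpretable
#' normalized usages -- the 10%-usage cell classification.
#'
#' When several inferred components match the true activity program, the
#' best-correlated one represents it in the ROC and classification.
#'
#' @param sim A `sim_data` object from [simulate_dataset()].
#' @param methods Subset of `c("cnmf", "cica", "gtclust")`.
#' @param k Number of components (the benchmark truth has 14).
#' @param r Number of factorization replicates.
#' @param rho,tau Consensus outlier-filter parameters.
#' @param h Number of over-dispersed genes.
#' @param seed Base seed for factorization replicates and KMeans.
#' @param fdr_target FDR operating point (default 0.05).
#' @return A named list (one entry per method) of evaluation reports:
#'   `matching`, `activity_detected`, `activity_component`, `roc`,
#'   `sensitivity_at_fdr`, `classification` (cNMF only), plus the fitted
#'   objects (`fit`).
#' @export
run_gep_benchmark <- function(sim, methods = "cnmf", k = 14, r = 50,
                              rho = 0.3, tau = "auto", h = 2000, seed = 0,
                              fdr_target = 0.05) {
  stopifnot(inherits(sim, "sim_data"))
  methods <- match.arg(methods, c("cnmf", "cica", "gtclust"),
                       several.ok = TRUE)
  truth <- sim$truth
  prep <- preprocess(sim$counts, h = h)
  cells <- match(rownames(prep$filtered_counts), rownames(sim$counts))
  phi <- truth$phi[cells]
  identity <- truth$identity[cells]
  tpm_m <- prep$tpm[, colnames(prep$filtered_counts), drop = FALSE]
  tpm_sd <- apply(tpm_m, 2, stats::sd)
  od <- prep$overdispersed_genes
  act_row <- nrow(truth$programs)      # the activity program is last
  act_fc <- truth$de_foldchange[act_row, ]

  eval_activity <- function(beta_row) {
    roc_with_fdr(beta_row, act_fc, fdr_target = fdr_target)
  }
  out <- list()

  if ("cnmf" %in% methods) {
    stack <- run_replicates(prep$norm, k = k, r = r, base_seed = seed)
    cons <- consensus(stack, prep$norm, rho = rho, tau = tau, tpm = tpm_m,
                      seed = seed)
    # match in TPM units, both sides scaled by the per-gene TPM sd
    mt <- match_components(cons$spectra_tpm[, od, drop = FALSE],
                           truth$programs, tpm_sd, scale_spectra = TRUE)
    act_comps <- which(mt$assignment == act_row)
    act_comp <- if (length(act_comps))
      act_comps[which.max(mt$best_cor[act_comps])] else NA_integer_
    detected <- length(act_comps) > 0 && max(mt$best_cor[act_comps]) > 0.80
    markers <- marker_regression(tpm_m, cons$usage)
    roc <- if (!is.na(act_comp)) eval_activity(markers$beta[act_comp, ])
    cls <- if (!is.na(act_comp))
      classify_activity_cells(cons$usage_norm[, act_comp], phi)
    out$cnmf <- list(matching = mt, activity_detected = detected,
                     activity_component = act_comp, roc = roc,
                     sensitivity_at_fdr = if (!is.null(roc))
                       roc$sensitivity_at_fdr else NA_real_,
                     classification = cls, markers = markers,
                     fit = cons, preprocess = prep, phi = phi)
  }

  if ("cica" %in% methods) {
    cons <- consensus_ica(prep$norm, k = k, r = r, rho = rho, tau = tau,
                          base_seed = seed)
    markers <- marker_regression(tpm_m, cons$usage)
    # ICA spectra are signed; match on the regression coefficients, which
    # are already in per-sd units, against sd-normalized truth programs
    mt <- match_components(markers$beta[, od, drop = FALSE],
                           truth$programs, tpm_sd)
    act_comps <- which(mt$assignment == act_row)
    act_comp <- if (length(act_comps))
      act_comps[which.max(mt$best_cor[act_comps])] else NA_integer_
    detected <- length(act_comps) > 0 && max(mt$best_cor[act_comps]) > 0.80
    roc <- if (!is.na(act_comp)) eval_activity(markers$beta[act_comp, ])
    out$cica <- list(matching = mt, activity_detected = detected,
                     activity_component = act_comp, roc = roc,
                     sensitivity_at_fdr = if (!is.null(roc))
                       roc$sensitivity_at_fdr else NA_real_,
                     markers = markers, fit = cons)
  }

  if ("gtclust" %in% methods) {
    gt <- ground_truth_clustering(tpm_m, identity, phi,
                                  n_identity = act_row - 1L)
    markers <- marker_regression(tpm_m, gt$usage)
    roc <- if (!is.na(gt$activity_col))
      eval_activity(markers$beta[gt$activity_col, ])
    out$gtclust <- list(roc = roc,
                        sensitivity_at_fdr = if (!is.null(roc))
                          roc$sensitivity_at_fdr else NA_real_,
                        markers = markers, fit = gt)
  }
  out
}
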