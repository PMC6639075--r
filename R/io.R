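#' @title Reading and writing count matrices and pipeline tables
#' @description
#' Counts are exchanged either as MatrixMarket coordinate files with
#' `genes.tsv` / `barcodes.tsv` name sidecars (the common sparse exchange
#' layout) or as dense TSV. All numeric pipeline tables are written with a
#' leading `# units:` comment line, because confusing l1-normalized
#' spectra, TPM-scale spectra and z-score regression coefficients is the
#' main user hazard of this method.
#' @name io
NULL

#' Read a cells x genes count matrix
#'
#' For `format = "mtx"`, `path` is a directory containing `matrix.mtx`,
#' `genes.tsv` and `barcodes.tsv`; orientation is auto-detected by
#' matching the sidecar lengths to the matrix dimensions (override with
#' `orientation`). For `format = "tsv"`, `path` is a dense
#' tab-separated file with gene columns and cell rows (first column = cell
#' names).
#'
#' @param path File (TSV) or directory (MTX).
#' @param format `"auto"` (directory implies MTX), `"mtx"` or `"tsv"`.
#' @param orientation `"auto"`, `"cells_by_genes"` or `"genes_by_cells"`
#'   (MTX only).
#' @return Integer cells x genes matrix with cell rownames and gene
#'   colnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"),
                        orientation = c("auto", "cells_by_genes",
                                        "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") format <- if (dir.exists(path)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE, comment.char = "#")
    m <- as.matrix(df)
    storage.mode(m) <- "integer"
  } else {
    mm <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                               header = FALSE)[, 1]
    cells <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                               header = FALSE)[, 1]
    dims_ok <- function(nc, ng) nrow(mm) == nc && ncol(mm) == ng
    flip <- switch(orientation,
      cells_by_genes = FALSE,
      genes_by_cells = TRUE,
      auto = if (dims_ok(length(cells), length(genes))) FALSE
             else if (dims_ok(length(genes), length(cells))) TRUE
             else stop("sidecar lengths (", length(cells), " barcodes, ",
                       length(genes), " genes) match neither orientation of ",
                       nrow(mm), " x ", ncol(mm), " matrix"))
    if (flip) mm <- t(mm)
    if (!dims_ok(length(cells), length(genes))) {
      stop("matrix is ", nrow(mm), " x ", ncol(mm), " but sidecars have ",
           length(cells), " barcodes and ", length(genes), " genes")
    }
    storage.mode(mm) <- "integer"
    dimnames(mm) <- list(as.character(cells), as.character(genes))
    m <- mm
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) {
    stop("duplicate gene names: ", paste(unique(dup), collapse = ", "))
  }
  m
}

#' Write a cells x genes count matrix
#'
#' @param counts Integer cells x genes matrix.
#' @param path Output directory (MTX) or file (TSV).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(cell = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    utils::write.table(colnames(counts), file.path(path, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(rownames(counts), file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Write a numeric matrix as TSV with a units header
#'
#' Values are written at 6 significant digits; the first line is a
#' `# units:` comment naming the unit system of the values.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file.
#' @param units Character description of the value units.
#' @param id_col Name for the row-name column (default "id").
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, units, id_col = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  vals <- formatC(m, format = "g", digits = 6)
  df <- cbind(rownames(m), as.data.frame(vals, stringsAsFactors = FALSE))
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with a `# units:` comment line.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' Write the ground truth of a simulated dataset
#'
#' Emits `cell_truth.tsv` (identity, phi, library size, doublet
#' provenance), `programs.tsv` (true program proportions) and
#' `de_foldchange.tsv`.
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct <- data.frame(cell = rownames_or_index(truth),
                   identity = truth$identity,
                   phi = truth$phi,
                   library_size = truth$library_size,
                   is_doublet = truth$is_doublet,
                   parent1 = truth$parents[, 1],
                   parent2 = truth$parents[, 2])
  utils::write.table(ct, file.path(dir, "cell_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(truth$programs, file.path(dir, "programs.tsv"),
                   units = "relative proportions (rows sum to 1)",
                   id_col = "program")
  write_matrix_tsv(truth$de_foldchange, file.path(dir, "de_foldchange.tsv"),
                   units = "fold-change (1 = not differentially expressed)",
                   id_col = "program")
  invisible(dir)
}

rownames_or_index <- function(truth) {
  n <- length(truth$identity)
  n_singlet <- sum(!truth$is_doublet)
  c(paste0("cell_", seq_len(n_singlet)),
    if (n > n_singlet) paste0("doublet_", seq_len(n - n_singlet)))
}

#' Write consensus results to a directory
#'
#' Spectra in l1 and (if present) TPM units, usages raw and normalized,
#' and the KNN distance histogram data.
#'
#' @param cons A `cnmf_consensus` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_consensus <- function(cons, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cons$spectra_l1, file.path(dir, "spectra_l1.tsv"),
                   units = "l1-normalized spectra (rows sum to 1)",
                   id_col = "program")
  if (!is.null(cons$spectra_tpm)) {
    write_matrix_tsv(cons$spectra_tpm, file.path(dir, "spectra_tpm.tsv"),
                     units = "TPM per unit normalized usage",
                     id_col = "program")
  }
  write_matrix_tsv(cons$usage, file.path(dir, "usage.tsv"),
                   units = "raw NNLS usage", id_col = "cell")
  if (!is.null(cons$usage_norm)) {
    write_matrix_tsv(cons$usage_norm, file.path(dir, "usage_norm.tsv"),
                     units = "normalized usage (rows sum to 1)",
                     id_col = "cell")
  }
  if (!is.null(cons$knn_distances)) {
    df <- data.frame(component = seq_along(cons$knn_distances),
                     mean_knn_distance = signif(cons$knn_distances, 6),
                     kept = cons$kept)
    utils::write.table(df, file.path(dir, "knn_distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cons$cluster)) {
    # clustergram ordering: surviving components grouped by consensus cluster
    ord <- order(cons$cluster)
    df <- data.frame(order = seq_along(ord),
                     component = which(cons$kept)[ord],
                     cluster = cons$cluster[ord])
    utils::write.table(df, file.path(dir, "clustergram_order.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
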