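make_stack <- function(components, r) {
  structure(list(components = components, k = nrow(components) / r, r = r),
            class = "replicate_stack")
}

test_that("KNN distances match a brute-force oracle and the filter uses strict tau", {
  set.seed(2)
  comp <- matrix(runif(10 * 6), 10, 6)
  comp <- comp / sqrt(rowSums(comp^2))
  r <- 5                          # L = round(0.3 * 5) = 2 wait -> 2? round(1.5)=2
  flt <- knn_outlier_filter(comp, rho = 0.3, tau = 10, r = 10)
  l <- flt$l
  d <- as.matrix(dist(comp))
  diag(d) <- Inf
  brute <- apply(d, 1, function(row) mean(sort(row)[seq_len(l)]))
  expect_equal(flt$distances, brute, ignore_attr = TRUE)
  # strict inequality: tau exactly at a distance excludes that row
  tau <- brute[1]
  flt2 <- knn_outlier_filter(comp, rho = 0.3, tau = tau, r = 10)
  expect_false(flt2$kept[1])
})

test_that("identical replicates pass any tau; a planted outlier is removed", {
  base <- matrix(runif(3 * 8), 3, 8)
  base <- base / sqrt(rowSums(base^2))
  comp <- base[rep(1:3, times = 4), ]          # 4 identical replicates
  flt <- knn_outlier_filter(comp, rho = 0.5, tau = 1e-6, r = 4)
  expect_true(all(flt$kept))
  expect_true(all(flt$distances == 0))

  far <- rep(0, 8); far[8] <- 1                # orthogonal outlier row
  comp2 <- rbind(comp, far)
  flt2 <- knn_outlier_filter(comp2, rho = 0.5, tau = 0.5, r = 4)
  expect_false(flt2$kept[13])
  expect_true(all(flt2$kept[1:12]))
  set.seed(12)
  jitter <- matrix(runif(12 * 8, 0.1, 1), 12, 8)
  expect_error(knn_outlier_filter(jitter, rho = 0.5, tau = 1e-12, r = 4),
               "all components filtered")
})

test_that("cluster medians reproduce hand arithmetic and l1 contracts", {
  rows <- rbind(c(1, 0), c(0.8, 0.2), c(0.6, 0.4))
  mrg <- cluster_and_merge(rows, k = 1, seed = 1)
  expect_equal(unname(mrg$spectra_l1[1, ]), c(0.8, 0.2))

  set.seed(3)
  distinct <- diag(4)[, ]                       # 4 orthogonal programs
  comp <- distinct[rep(1:4, each = 3), ] + 0    # 3 copies each
  mrg2 <- cluster_and_merge(comp, k = 4, seed = 1)
  expect_equal(unname(rowSums(mrg2$spectra_l1)), rep(1, 4))
  # clusters recover the groups: each consensus row equals one basis vector
  best <- apply(mrg2$spectra_l1, 1, which.max)
  expect_setequal(best, 1:4)
  expect_true(all(apply(mrg2$spectra_l1, 1, max) == 1))
  expect_error(cluster_and_merge(rows, k = 5), "fewer surviving")
})

test_that("usage refit solves per-cell NNLS and normalizes rows", {
  g <- rbind(gep_1 = c(1, 0, 0, 0), gep_2 = c(0, 0, 0.5, 0.5))
  colnames(g) <- paste0("g", 1:4)
  norm <- rbind(cell_a = 5 * g[1, ],
                cell_b = 0.3 * g[1, ] + 0.7 * g[2, ],
                cell_c = c(0, 0, 0, 0))
  expect_warning(usg <- refit_usage(norm, g), "all-zero usage")
  expect_equal(unname(usg$usage["cell_a", ]), c(5, 0))
  expect_equal(unname(usg$usage_norm["cell_a", ]), c(1, 0))
  expect_equal(unname(usg$usage["cell_b", ]), c(0.3, 0.7))
  expect_equal(unname(usg$usage_norm["cell_b", ]), c(0.3, 0.7))
  expect_equal(usg$zero_cells, 3, ignore_attr = TRUE)
  expect_true(all(usg$usage_norm["cell_c", ] == 0))

  # against the reference NNLS solver on a random instance
  set.seed(9)
  g2 <- matrix(runif(3 * 6), 3, 6,
               dimnames = list(paste0("gep_", 1:3), paste0("g", 1:6)))
  x <- matrix(runif(4 * 6), 4, 6,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:6)))
  u <- refit_usage(x, g2)$usage
  for (i in 1:4) {
    expect_equal(unname(u[i, ]), pracma::lsqnonneg(t(g2), x[i, ])$x,
                 tolerance = 1e-8)
  }
})

test_that("TPM spectra refit reduces to group means for one-hot usage", {
  set.seed(11)
  n <- 30
  grp <- rep(1:3, each = 10)
  usage <- matrix(0, n, 3, dimnames = list(paste0("c", 1:n),
                                           paste0("gep_", 1:3)))
  usage[cbind(1:n, grp)] <- 1
  tpm <- matrix(runif(n * 5, 0, 100), n, 5,
                dimnames = list(paste0("c", 1:n), paste0("g", 1:5)))
  tpm[, 5] <- 0                                 # all-zero gene
  g <- refit_spectra_tpm(tpm, usage)
  for (k in 1:3) {
    expect_equal(unname(g[k, 1:4]), unname(colMeans(tpm[grp == k, 1:4])),
                 tolerance = 1e-10)
  }
  expect_true(all(g[, 5] == 0))
  # K = 1 with all usages 1: the least-squares scalar is the gene mean
  u1 <- matrix(1, n, 1, dimnames = list(rownames(tpm), "gep_1"))
  expect_equal(unname(refit_spectra_tpm(tpm, u1)[1, ]),
               unname(colMeans(tpm)), tolerance = 1e-10)
})

test_that("consensus of identical replicates equals the single solution", {
  set.seed(21)
  pc <- planted_counts()
  prep <- preprocess(pc$counts, h = 40, min_counts = 100)
  single <- run_nmf_replicate(prep$norm, 3, seed = 500 + 1)
  gn <- single$g / sqrt(rowSums(single$g^2))
  comp <- gn[rep(1:3, times = 6), ]             # 6 identical "replicates"
  colnames(comp) <- colnames(prep$norm)
  stack <- make_stack(comp, r = 6)
  cons <- consensus(stack, prep$norm, rho = 0.5, tau = 0.1, seed = 1)
  # consensus spectra are the l1-normalized rows of the single solution,
  # up to permutation
  l1 <- gn / rowSums(gn)
  cors <- cor(t(cons$spectra_l1), t(l1))
  expect_equal(unname(sort(apply(cors, 1, max))), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(rowSums(cons$spectra_l1)), rep(1, 3))
  expect_equal(unname(rowSums(cons$usage_norm)), rep(1, nrow(prep$norm)),
               tolerance = 1e-12)
})
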