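test_that("component matching recovers identities, permutations and rescalings", {
  set.seed(1)
  truth <- matrix(runif(3 * 12), 3, 12,
                  dimnames = list(paste0("p", 1:3), paste0("g", 1:12)))
  mt <- match_components(truth, truth)
  expect_equal(unname(mt$assignment), 1:3)
  expect_equal(unname(mt$best_cor), rep(1, 3))
  perm <- truth[c(3, 1, 2), ] * 7.5
  mt2 <- match_components(perm, truth)
  expect_equal(unname(mt2$assignment), c(3, 1, 2))
  expect_equal(unname(mt2$best_cor), rep(1, 3))
})

test_that("matching equals a brute-force argmax with replacement", {
  set.seed(2)
  truth <- matrix(runif(2 * 10), 2, 10,
                  dimnames = list(paste0("p", 1:2), paste0("g", 1:10)))
  inferred <- matrix(runif(3 * 10), 3, 10,
                     dimnames = list(paste0("i", 1:3), paste0("g", 1:10)))
  mt <- match_components(inferred, truth)
  for (i in 1:3) {
    cors <- c(cor(inferred[i, ], truth[1, ]), cor(inferred[i, ], truth[2, ]))
    expect_equal(unname(mt$assignment[i]), which.max(cors))
    expect_equal(unname(mt$best_cor[i]), max(cors))
  }
})

test_that("the FDR-ROC reaches closed-form operating points", {
  fc <- c(rep(3, 10), rep(1, 20))
  names(fc) <- paste0("g", 1:30)
  # perfect ranking: sensitivity 1 at FDR 0
  perfect <- c(seq(30, 21), seq(20, 1) / 20)
  names(perfect) <- names(fc)
  roc <- roc_with_fdr(perfect, fc)
  expect_equal(roc$sensitivity_at_fdr, 1)
  expect_equal(roc$n_pos, 10)
  # genes with 1 < fc < 2 are excluded from scoring
  fc2 <- fc; fc2[11:15] <- 1.5
  roc2 <- roc_with_fdr(perfect, fc2)
  expect_equal(roc2$n_neg, 15)
  expect_error(roc_with_fdr(perfect, rep(1, 30)), "no true-positive")
})

test_that("random scores give near-chance sensitivity at a strict FDR", {
  set.seed(3)
  fc <- c(rep(2.5, 300), rep(1, 300))
  names(fc) <- paste0("g", 1:600)
  sens <- replicate(30, {
    sc <- rnorm(600); names(sc) <- names(fc)
    roc_with_fdr(sc, fc)$sensitivity_at_fdr
  })
  # base FDR is 0.5 at every prefix in expectation; sensitivity attainable
  # at FDR <= 0.05 is close to zero
  expect_lt(mean(sens), 0.05)
  # at a target above the base rate every gene can be called
  sc <- rnorm(600); names(sc) <- names(fc)
  expect_equal(roc_with_fdr(sc, fc, fdr_target = 0.75)$sensitivity_at_fdr, 1)
})

test_that("activity-cell classification uses the 10% threshold contracts", {
  phi <- c(rep(0, 50), runif(50, 0.1, 0.7))
  # perfect inference: phi >= 0.1 by construction, all expressing called
  cls <- classify_activity_cells(phi, phi)
  expect_equal(cls$sensitivity, 1)
  expect_equal(cls$specificity, 1)
  expect_equal(cls$usage_cor, 1)
  # all-zero usage: nothing called
  cls0 <- classify_activity_cells(rep(0, 100), phi)
  expect_equal(cls0$sensitivity, 0)
  expect_equal(cls0$specificity, 1)
  # threshold is >=
  cls_thr <- classify_activity_cells(c(0.0999, 0.1, 0.2), c(0.5, 0.5, 0.5),
                                     threshold = 0.10)
  expect_equal(cls_thr$sensitivity, 2 / 3)
})

test_that("ground-truth clustering applies the 40% rule and mean-TPM programs", {
  tpm <- matrix(c(10, 20, 30, 40, 50, 60,
                  1, 2, 3, 4, 5, 6), 6, 2,
                dimnames = list(paste0("c", 1:6), c("g1", "g2")))
  identity <- c(1L, 1L, 2L, 2L, 1L, 2L)
  phi <- c(0, 0, 0, 0.39, 0.5, 0.75)
  gt <- ground_truth_clustering(tpm, identity, phi, n_identity = 2)
  expect_equal(unname(gt$cluster), c(1, 1, 2, 2, 3, 3))
  expect_equal(unname(gt$geps["identity_1", ]),
               colMeans(tpm[1:2, ]), ignore_attr = TRUE)
  expect_equal(unname(gt$geps["identity_2", ]),
               colMeans(tpm[3:4, ]), ignore_attr = TRUE)
  expect_equal(unname(gt$geps["activity", ]),
               colMeans(tpm[5:6, ]), ignore_attr = TRUE)
  expect_equal(unname(colSums(gt$usage)), c(2, 2, 2))
  # no activity cells: identity clusters only
  gt0 <- ground_truth_clustering(tpm, identity, rep(0, 6), n_identity = 2)
  expect_true(is.na(gt0$activity_col))
  expect_equal(ncol(gt0$usage), 2)
})

test_that("FastICA recovers planted independent non-Gaussian sources", {
  set.seed(5)
  n <- 500
  s_true <- cbind(runif(n, -1, 1)^3, sign(rnorm(n)) * runif(n))
  a_mix <- matrix(c(2, 1, 1, 3, 0.5, -1), 2, 3)
  x <- s_true %*% a_mix + matrix(rnorm(n * 3, 0, 0.01), n, 3)
  wh <- cnmfr:::whiten_pca(x, 2)
  fit <- run_ica_replicate(wh, seed = 1)
  cors <- abs(cor(fit$usage, s_true))
  expect_true(all(apply(cors, 2, max) > 0.95))
  # the median-usage sign rule makes orientation deterministic
  expect_true(all(apply(fit$usage, 2, median) <= 0))
})

test_that("sign-flipped replicates align to an identical component stack", {
  set.seed(6)
  x <- matrix(rnorm(200 * 8), 200, 8)
  colnames(x) <- paste0("g", 1:8)
  wh <- cnmfr:::whiten_pca(x, 3)
  f1 <- run_ica_replicate(wh, seed = 4)
  f2 <- run_ica_replicate(wh, seed = 4)
  expect_identical(f1$spectra, f2$spectra)
})
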