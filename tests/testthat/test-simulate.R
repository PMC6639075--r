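test_that("program sampling follows the stated recipe exactly", {
  p <- sim_params(n_cells = 10, n_genes = 10, n_identity = 2,
                  activity_n_genes = 3, activity_celltypes = 2,
                  de_prob = 0.3, seed = 11)
  set.seed(99)
  got <- sample_programs(p)
  set.seed(99)
  want <- ref_sample_programs(p)
  expect_equal(unname(got$programs), want)
  expect_true(all(got$programs > 0))
  expect_equal(rowSums(got$programs), rep(1, 3), ignore_attr = TRUE)
})

test_that("no differential expression collapses identity programs to base means", {
  p <- sim_params(n_cells = 10, n_genes = 50, n_identity = 3,
                  activity_n_genes = 10, activity_celltypes = 2,
                  de_prob = 0, seed = 1)
  set.seed(5)
  prog <- sample_programs(p)
  base <- prog$base_means / sum(prog$base_means)
  for (i in 1:3) expect_equal(unname(prog$programs[i, ]), base)
  expect_error(sample_programs(sim_params(n_genes = 100,
                                          activity_n_genes = 200)),
               "activity_n_genes")
})

test_that("identity DE gene counts are binomial around de_prob", {
  p <- sim_params(n_cells = 10, n_genes = 25000, activity_n_genes = 1000,
                  de_prob = 0.025, seed = 3)
  set.seed(17)
  prog <- sample_programs(p)
  n_de <- rowSums(prog$de_foldchange[1:13, ] != 1)
  # binomial mean 625, 99.9% interval roughly +/- 3.3 * sqrt(n p (1-p))
  expect_true(all(abs(n_de - 625) < 3.3 * sqrt(25000 * 0.025 * 0.975)))
  expect_equal(sum(prog$de_foldchange[14, ] != 1), 1000)
  # up-regulation only
  expect_true(all(prog$de_foldchange >= 1 | prog$de_foldchange == 1 |
                    prog$de_foldchange > 0))
})

test_that("cell assignment hits the multinomial and activity expectations", {
  p <- sim_params(n_cells = 15000, n_genes = 100, activity_n_genes = 10,
                  seed = 1)
  set.seed(23)
  a <- assign_cells(p)
  counts <- tabulate(a$identity, 13)
  expect_true(all(abs(counts - 15000 / 13) <
                    3.3 * sqrt(15000 * (1 / 13) * (12 / 13))))
  n_eligible <- sum(a$identity %in% a$activity_types)
  n_active <- sum(a$phi > 0)
  expect_lt(abs(n_active - 0.3 * n_eligible),
            3.3 * sqrt(n_eligible * 0.3 * 0.7))
  expect_true(all(a$phi[a$phi > 0] >= 0.1 & a$phi[a$phi > 0] <= 0.7))
  expect_true(all(a$phi[!(a$identity %in% a$activity_types)] == 0))

  # no activity
  p0 <- sim_params(n_cells = 500, n_genes = 100, activity_n_genes = 10,
                   activity_frac = 0)
  set.seed(2)
  expect_true(all(assign_cells(p0)$phi == 0))

  # skewed preset frequencies
  ps <- sim_preset("skewed", n_cells = 20000, n_genes = 100,
                   activity_n_genes = 10)
  set.seed(9)
  as_ <- assign_cells(ps)
  freq <- tabulate(as_$identity, 15) / 20000
  expect_true(all(abs(freq - ps$celltype_probs) < 0.015))
})

test_that("count means follow the library-scaled mixing equation", {
  # two hand-built programs differing in gene 2; no DE machinery involved
  programs <- rbind(c(0.5, 0.1, 0.4), c(0.5, 0.3, 0.2))
  colnames(programs) <- paste0("gene_", 1:3)
  p <- sim_params(n_cells = 6000, n_genes = 3, n_identity = 1,
                  activity_n_genes = 1, activity_celltypes = 1,
                  lib_loc = log(500), lib_scale = 0,
                  bcv_dispersion = 0.1, bcv_dof = 1e7)
  set.seed(31)
  # phi = 0: mean is exactly L * Z_identity
  asg <- list(identity = rep(1L, 6000), phi = rep(0, 6000))
  sim0 <- simulate_counts(programs, asg, p)
  expect_equal(unname(colMeans(sim0$counts)), 500 * programs[1, ],
               tolerance = 0.03, ignore_attr = TRUE)
  # phi = 0.5: gene means at the arithmetic midpoint
  asg5 <- list(identity = rep(1L, 6000), phi = rep(0.5, 6000))
  set.seed(32)
  sim5 <- simulate_counts(programs, asg5, p)
  expect_equal(unname(colMeans(sim5$counts)),
               500 * (programs[1, ] + programs[2, ]) / 2,
               tolerance = 0.03, ignore_attr = TRUE)
})

test_that("counts follow the gamma-Poisson variance identity", {
  # fixed library, one program, huge bcv_dof so the chi-square factor is ~1:
  # Var = lambda + lambda^2 * B^2 with B = (b0 + 1/sqrt(lambda))
  programs <- matrix(0.25, 2, 4, dimnames = list(NULL, paste0("g", 1:4)))
  b0 <- 0.3
  p <- sim_params(n_cells = 8000, n_genes = 4, n_identity = 1,
                  activity_n_genes = 1, activity_celltypes = 1,
                  lib_loc = log(200), lib_scale = 0,
                  bcv_dispersion = b0, bcv_dof = 1e7)
  set.seed(41)
  sim <- simulate_counts(programs, list(identity = rep(1L, 8000),
                                        phi = rep(0, 8000)), p)
  lam <- 200 * 0.25
  expected_var <- lam + lam^2 * (b0 + 1 / sqrt(lam))^2
  emp_var <- apply(sim$counts, 2, var)
  expect_true(all(abs(emp_var / expected_var - 1) < 0.15))
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts))
})

test_that("doublets sum parents and down-sample to the max parent total", {
  counts <- rbind(a = c(600L, 400L), b = c(2500L, 1500L))
  colnames(counts) <- c("g1", "g2")
  set.seed(3)
  dbl <- make_doublets(counts, rate = 1 / 3)   # exactly one doublet
  expect_equal(nrow(dbl$counts), 3)
  expect_equal(sum(dbl$counts[3, ]), 4000)     # max(1000, 4000)
  expect_equal(sort(dbl$parents[3, ]), c(1, 2))
  # equal totals: doublet total equals the shared total
  eq <- rbind(a = c(500L, 500L), b = c(300L, 700L))
  colnames(eq) <- c("g1", "g2")
  set.seed(4)
  expect_equal(sum(make_doublets(eq, 1 / 3)$counts[3, ]), 1000)
  expect_error(make_doublets(counts[1, , drop = FALSE], 0.5), "2 singlets")
})

test_that("down-sampling is hypergeometric: zeros stay zero, expectation scales", {
  x <- c(10L, 0L, 30L)
  set.seed(8)
  draws <- t(replicate(3000, downsample_counts(x, 20)))
  expect_true(all(rowSums(draws) == 20))
  expect_true(all(draws[, 2] == 0))
  expect_equal(unname(colMeans(draws)), c(5, 0, 15), tolerance = 0.03)
})

test_that("the generator is reproducible and degenerates cleanly", {
  p <- sim_params(n_cells = 150, n_genes = 300, activity_n_genes = 50,
                  n_identity = 3, activity_celltypes = 2, seed = 77)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$phi, s2$truth$phi)

  # doublet fraction is deterministic given the rate
  expect_equal(sum(s1$truth$is_doublet),
               round(0.06 / 0.94 * 150))

  p0 <- sim_params(n_cells = 100, n_genes = 200, activity_n_genes = 50,
                   n_identity = 3, activity_celltypes = 2,
                   activity_frac = 0, doublet_rate = 0, seed = 5)
  s0 <- simulate_dataset(p0)
  expect_true(all(s0$truth$phi == 0))
  expect_false(any(s0$truth$is_doublet))
  expect_true(all(s0$counts >= 0))
})
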