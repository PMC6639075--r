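# Small deterministic fixtures shared across test files.

# A tiny simulated dataset: fast to generate, still exercises every stage
# (activity program, doublets, filtering). Cached per session.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_params(
        n_cells = 250, n_genes = 400, activity_n_genes = 80,
        n_identity = 4, activity_celltypes = 2, doublet_rate = 0.08,
        lib_loc = log(2000), seed = 42))
    }
    cache
  }
})

# Counts with planted structure: `k` blocks of cells each over-expressing a
# block of genes; returns list(counts, block) for clustering-style checks.
planted_counts <- function(n_per_block = 40, k = 3, genes_per_block = 25,
                           base = 30, boost = 6, seed = 7) {
  set.seed(seed)
  n <- n_per_block * k
  m <- genes_per_block * k
  lambda <- matrix(base, n, m)
  block <- rep(seq_len(k), each = n_per_block)
  for (b in seq_len(k)) {
    lambda[block == b, (b - 1) * genes_per_block + seq_len(genes_per_block)] <-
      base * boost
  }
  counts <- matrix(rpois(n * m, lambda), n, m,
                   dimnames = list(paste0("cell_", seq_len(n)),
                                   paste0("gene_", seq_len(m))))
  list(counts = counts, block = block)
}

# Independent straight-line transcription of the program-sampling recipe,
# used as the exact oracle for sample_programs() under a shared seed.
ref_sample_programs <- function(p) {
  m <- p$n_genes
  means <- rgamma(m, shape = p$mean_shape, rate = p$mean_rate)
  out_mask <- runif(m) < p$expout_prob
  if (any(out_mask)) {
    means[out_mask] <- median(means) *
      rlnorm(sum(out_mask), p$expout_loc, p$expout_scale)
  }
  fc <- matrix(1, p$n_identity + 1, m)
  for (g in seq_len(p$n_identity)) {
    mask <- runif(m) < p$de_prob
    if (any(mask)) fc[g, mask] <- rlnorm(sum(mask), p$de_loc, p$de_scale)
  }
  act <- sample.int(m, p$activity_n_genes)
  fc[p$n_identity + 1, act] <- rlnorm(p$activity_n_genes, p$de_loc,
                                      p$de_scale)
  prog <- sweep(fc, 2, means, `*`)
  prog / rowSums(prog)
}

# Exhaustive one-sided Mann-Whitney p-value by enumerating all group
# assignments (oracle for small two-group rank tests).
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_obs <- u_stat(a, b)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(us >= u_obs)
}
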