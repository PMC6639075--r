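# cnmfr — consensus NMF for gene expression programs in scRNA-seq

Single-cell RNA-seq profiles are mixtures: every cell expresses the gene
program of its cell type (*identity* program) and, on top of it, programs
for whatever it happens to be doing — dividing, responding to hypoxia,
depolarizing (*activity* programs). Hard clustering collapses each cell
to one program and therefore misattributes activity genes to cell types.
`cnmfr` disentangles the two by consensus non-negative matrix
factorization (cNMF): it models the cells × genes matrix as

```
C̃ ≈ U G        U ≥ 0 (cells × K usages),  G ≥ 0 (K × genes programs)
```

and stabilizes the notoriously run-to-run variable NMF solution by
running R independently seeded replicates, filtering outlier components
by their mean distance to their `round(rho·R)` nearest neighbours,
clustering the survivors with KMeans, taking per-gene medians, and
refitting usages and transcripts-per-million-scale spectra by
non-negative least squares. The package is aimed at method developers
and analysts who want GEP-level (rather than cluster-level) structure
out of UMI count matrices, plus a fully instrumented synthetic benchmark
for validating that kind of inference.

It contains, as first-class tested code:

* a Splatter-style gamma–Poisson **simulator** with one activity program
  (usage φ ~ U(0.1, 0.7) in 30% of cells of four types) and doublets
  built by summing and down-sampling real cell pairs;
* **preprocessing**: count filters, v-score over-dispersed gene
  selection, unit-variance scaling, TPM;
* the **factorization and consensus** machinery (HALS NMF solver, KNN
  outlier filter, median merge, NNLS refits);
* **model-order diagnostics** (stability/error curve, PCA scree);
* **marker-gene regression** on z-scored TPM and floored one-sided
  Mann–Whitney gene-set enrichment;
* a **benchmark harness** with consensus-ICA and ground-truth-clustering
  baselines, sensitivity-vs-FDR curves, and activity-cell
  classification;
* a staged **command line** (`inst/scripts/cnmf`) covering
  simulate/prepare/factorize/combine/k-selection/consensus/markers/enrich/benchmark.

## Worked example

The benchmark preset simulates 2,000 singlet cells × 5,000 genes
(13 identity programs, one activity program on 800 genes, 6% doublets),
then runs the full pipeline and scores recovery against ground truth
(about 3 minutes on one CPU):

```r
library(cnmfr)
sim <- simulate_dataset(sim_params(seed = 1))
res <- run_gep_benchmark(sim, methods = c("cnmf", "gtclust"),
                         k = 14, r = 50, seed = 1)
```

Output for this seed:

```
best Pearson per true program (13 identity + activity):
 [1] 0.89 0.41 0.62 0.83 0.32 0.77 0.86 0.83 0.84 0.34 0.91 0.89 0.86 0.87
activity detected (r > 0.8): TRUE
sensitivity at 5% FDR  cNMF: 10.4 %  truth-clustering bound: 33.3 %
activity cells called at 10% usage: sens 95.1 % spec 79.4 %  usage r: 0.73
```

Reading this: most identity programs and the activity program are
recovered above r = 0.8 (three identities are split/merged at this
reduced scale); thresholding the normalized activity usage at 10% calls
95% of truly expressing cells and 79% of silent cells correctly, and the
inferred usage tracks the simulated mixing proportion φ at r = 0.73.
Gene-level sensitivity at 5% FDR is strongly scale-dependent — at this
size even the ground-truth clustering upper bound reaches only ~33–45%
— see the methods vignette
(`vignettes/consensus-nmf-methods.Rmd`) for why, and for every modelling
choice and parameter default.

On real data you would instead call

```r
counts <- read_counts("path/to/mtx_dir")        # or a dense TSV
fit <- cnmf(counts, k = 20, r = 100, tau = "auto")
markers <- marker_regression(
  fit$preprocess$tpm[, colnames(fit$preprocess$filtered_counts)],
  fit$consensus$usage)
```

after choosing `k` with `stability_error_curve()` / `pca_scree()` and
`tau` from the returned `knn_distances` histogram.

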