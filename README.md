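# rnmfimpute

Robust graph-regularized non-negative matrix factorization for imputing
dropout zeros in single-cell RNA-seq count matrices.

## The problem

Droplet and plate-based scRNA-seq measures each transcript imperfectly: many
genes that are expressed in a cell are recorded as zero ("dropouts"),
especially lowly expressed genes. The resulting zero rates of 40–95% bias
clustering, visualization and differential expression. Imputation methods
reconstruct the missing signal — but a zero is not always a dropout. A
*biological* zero (the gene genuinely off in that cell type) must be left
alone, or the method invents false signal ("over-imputation").

## The model

Let `X` be the filtered, median-library log-normalized gene×cell matrix
(`N(x_gc) = ln(m · x_gc / t_c + 1)` with `t_c` the library size of cell `c`
and `m` the median library size), restricted to highly variable genes. The
model factorizes `X ≈ W H` with non-negative gene factors `W` (G×k) and cell
factors `H` (k×C), and treats observed and zero entries asymmetrically:

```
min_{W,H ≥ 0}  1/2 Σ_{x_gc ≠ 0} (x_gc − (WH)_gc)²          observed: L2 loss
             + 1/2 Σ_{x_gc = 0} ℓ_C(x_gc − (WH)_gc)        zeros: correntropy loss
             + α/2 ‖K_G − W Wᵀ‖²_F + β/2 ‖K_C − Hᵀ H‖²_F   similarity graphs
             + λ/2 Σ_{x_gc = 0} (WH)²_gc                    zero shrinkage
```

where `ℓ_C(r) = 1 − exp(−r²/2σ²)` is bounded and saturating: a zero that the
low-rank structure insists should be large (a probable dropout) stops being
penalized, while small residuals behave like L2. `K_G`/`K_C` are gene–gene
and cell–cell similarity graphs (average of cosine and Pearson similarity,
clipped at 0) that keep the factors consistent with the data geometry.

The non-convex objective is minimized by half-quadratic alternation: a
closed-form weight `m_gc = exp(−r²_gc/2σ²)` is computed for every zero
entry, the resulting weighted NMF subproblem takes one multiplicative
update per factor, and the two stages alternate until the relative
objective change falls below tolerance. The update is damped automatically
(geometric backtracking) in the rare regimes where the plain multiplicative
step would not descend, so the objective trace is always non-increasing.
The imputed matrix is `X̂ = W H` (or `X̂` substituted only at zeros).

## Worked example

```r
library(rnmfimpute)

# simulate 3 groups of cells with dropout calibrated to 70% observed zeros
params <- calibrate_dropout(
  sim_params(n_genes = 300, n_cells = 150, n_groups = 3, seed = 7),
  target_zero_rate = 0.7
)
sim <- simulate_groups(params)
sim
#> SimTruth: 300 genes x 150 cells, 3 groups; zero rate 69.9% observed / 12.1% true

proc <- preprocess_counts(count_matrix(sim$observed_counts), hvg_n = 300)
proc
#> ProcessedMatrix: 276 genes x 150 cells (67.3% zeros)

graphs <- build_graphs(proc)
fit <- rnmf_fit(proc, graphs = graphs,
                hyper = hyperparams(k = 5, sigma = 0.1),
                init_seed = 1, max_iter = 200, tol = 1e-6)
imputed <- rnmf_impute(fit)            # X-hat = W H

labels <- sim$group_labels[match(proc$cell_ids, colnames(sim$observed_counts))]
cluster_and_score(proc,    labels, seed = 1)$ari   # 0.119  (raw data)
cluster_and_score(imputed, labels, seed = 1)$ari   # 0.591  (imputed)

truth_norm <- log_normalize(count_matrix(sim$true_counts))
recovery_metrics(imputed, truth_norm$values[proc$gene_ids, proc$cell_ids])
#> RMSE 1.231, PCC 0.878  (vs log-normalized true counts)
```

At 70% dropout the raw log-normalized matrix clusters at ARI 0.12; after
robust imputation the same seeded K-means recovers the three groups at ARI
0.59, and the reconstruction correlates at r = 0.88 with the normalized
true (pre-dropout) counts.

Hyperparameters (`k` from {2,10,20,30,40,50}; `σ`, `α`, `β`, `λ` on decade
grids) are chosen by `random_search()`: 10% of the non-zero entries are
masked, each sampled configuration is fitted on the masked matrix, and the
configuration with the lowest RMSE on the held-out entries wins.

## Command line

```sh
Rscript inst/cli/rnmf-impute impute   --input counts.csv --outdir run --k 20 --seed 1
Rscript inst/cli/rnmf-impute simulate --preset sim1 --outdir simdir
Rscript inst/cli/rnmf-impute tune     --input counts.csv --outdir tune --n-samples 1000
Rscript inst/cli/rnmf-impute evaluate --imputed run/imputed.csv --simdir simdir --outdir eval
Rscript inst/cli/rnmf-impute ksweep   --preset sim9 --k-list 2,10,20 --outdir sweep
```

Subcommands accept `--format {mtx_dir,csv,tsv}` (10x-style Matrix-Market
directory or dense tables), write all artifacts as plain text, and are
reproducible from the resolved `config.txt` plus seeds.

## Vignette

`vignettes/robust-nmf-imputation.Rmd` documents the model and its
assumptions, the solver and its safeguards, what the synthetic generator
does and does not emulate, and all numerical choices.
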