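# scLatentDeconv

Cell-type deconvolution of bulk RNA-seq against single-cell references that
were assembled from **multiple studies with batch effects**.

Bulk RNA-seq averages a tissue's transcriptome over an unknown mixture of
cell types. Estimating the mixing fractions against single-cell reference
profiles is routine when reference and bulk come from one study — and
fragile when the reference must be stitched together from several
single-cell cohorts, because batch, platform and tissue effects in the
reference leak into the estimated fractions. `scLatentDeconv` addresses this
by learning a confounder-purged latent space and deconvolving there:

1. **Adversarial deconfounding autoencoder.** An encoder/decoder pair
   minimises the reconstruction error
   $\mathbb{E}\,\lVert x - g_\varphi(f_\Phi(x))\rVert_2^2$ while a
   co-trained adversary $h_\nu$ tries to predict the confounder $c$ (batch,
   study, tissue) from the latent code $z = f_\Phi(x)$; the joint objective
   $\min \mathbb{E}\left[\lVert x - g_\varphi(f_\Phi(x))\rVert_2^2 -
   \lambda\,L(h_\nu(f_\Phi(x)), c)\right]$ (default $\lambda = 1$) is
   alternated with one adversary epoch per round.
2. **Reference panel** $R$: the coordinate-wise median latent vector per
   cell type.
3. **Per-sample regression** $T = P R$: each bulk sample is normalised like
   the reference (counts-per-10k + log1p), embedded by the *same* encoder,
   and regressed on the panel rows with a gradient-boosted linear model;
   negative coefficients are clipped to zero and the rest renormalised to a
   probability vector. A non-negative least-squares solver is included as an
   independent oracle, and an optional *reference-pseudobulk anchor*
   (`buildReferenceAnchor()`) absorbs the systematic latent offset that
   log-transformed mixtures acquire.

Around the core sit: single-cell preprocessing (QC filters, CP10K/log1p,
standardized-dispersion HVG selection, MAGIC-style diffusion imputation),
negative-binomial synthetic data with known type/batch structure, two
pseudobulk simulators with ground-truth proportions, benchmarking metrics
(per-type Pearson r, MSE, mAD), and a phenotype layer (mutual-information
feature ranking, boosted classification with AUROC, Wilcoxon rank-sum
comparisons).

## Worked example

Synthetic two-batch reference, pseudobulks with known proportions, train,
deconvolve, score (settings scaled down for a quick run):

```r
library(scLatentDeconv)

## 1. a synthetic two-batch reference: 4 cell types, 2,000 genes
sc <- simulateScCounts(syntheticSpec(seed = 1))
sc
#> ScReference: 2000 genes x 3000 cells
#>   cell types: typeA, typeB, typeC, typeD
#>   batches:    batch1, batch2

## 2. pseudobulks with known mixing proportions
bulks <- simulateBulkRandom(sc, nSamples = 20, nCellsPerSample = 300, seed = 2)

## 3. preprocess + train the adversarial autoencoder
prep <- preprocessReference(sc, rownames(bulks$expression),
                            nHVG = 500, nCells = 1500, seed = 3)
model <- trainAAE(prep$logcounts, prep$sc$batch, latentDim = 50,
                  hidden = c(128, 64), advHidden = 32, lambda = 1,
                  aeEpochs = 15, advEpochs = 8, jointRounds = 12, seed = 4)

## 4. reference panel, curvature anchor, embedding, proportions
panel  <- buildReferencePanel(encodeCells(model, prep$logcounts), prep$sc$cell_type)
anchor <- buildReferenceAnchor(model, prep$sc, prep$panel)
blat   <- embedBulk(model, normalizeBulk(bulks$expression, prep$panel))
est    <- estimateProportions(panel, blat, method = "boosted_linear", anchor = anchor)
round(proportions(est)[1:3, ], 3)
#>         typeA typeB typeC typeD
#> bulk001 0.126 0.520 0.354 0.000
#> bulk002 0.107 0.511 0.196 0.187
#> bulk003 0.522 0.000 0.210 0.268

## 5. score against the known truth
s <- scoreProportions(est, bulks$trueProportions)
s$perType
#>   cell_type   pearson
#> 1     typeA 0.9843556
#> 2     typeB 0.9873772
#> 3     typeC 0.9804268
#> 4     typeD 0.9731846
c(overall_r = s$r, mse = s$mse, mad = s$mad)
#>   overall_r         mse         mad
#> 0.973141674 0.002377641 0.037319629

## how well is the batch hidden? (2 classes, chance = 0.5)
adversaryAccuracy(model, encodeCells(model, prep$logcounts), prep$sc$batch)
#> [1] 0.4833333
```

Per-type correlations of 0.97–0.99 and a mean absolute deviation of 0.037
mean the estimated fractions track the true mixing fractions closely, while
the adversary's chance-level batch accuracy (0.48 for two batches) shows the
embedding no longer exposes the confounder to it.

For file-based workflows, `runPipeline("config.json")` executes
preprocess → train → embed → deconvolve from a JSON configuration and
writes TSV artifacts; `inst/scripts/scper.R` wraps the same functions as a
small command line (`synth`, `simulate-bulk`, `run`, `evaluate`). Identical
configuration and seed give byte-identical outputs.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
synthetic reference generation, preprocessing, adversarial training,
pseudobulk simulation, latent-space deconvolution, scoring, and the
phenotype layer — logging the measured accuracy along the way, and writes a
JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical conventions,
and known limitations.
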