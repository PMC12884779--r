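#' Specification for a synthetic single-cell dataset
#'
#' Describes a negative-binomial gene-by-cell count world with known
#' cell-type structure (marker genes with a fold-change) and a known batch
#' confounder (a block of genes shifted by a batch fold-change). Defaults
#' emulate a two-study reference with visible batch effects: 2,000 genes,
#' four cell types of 750 cells each, 50 markers per type at 8-fold,
#' two equally sized batches with 500 batch-affected genes at 4-fold.
#'
#' @param nGenes number of genes.
#' @param cellTypes named integer vector: cells per type.
#' @param nMarkerGenesPerType marker genes per type (disjoint blocks).
#' @param markerFoldChange multiplicative fold on marker genes in their type.
#' @param batches named numeric vector of batch assignment fractions
#'   (must sum to 1).
#' @param batchEffectGenes number of genes carrying the batch effect.
#' @param batchEffectFold multiplicative fold on those genes in the second
#'   and subsequent batches (fold^(batch index - 1)).
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseMeanRange base gene means are drawn log-uniformly in this range.
#' @param librarySizeLognormal c(meanlog, sdlog) of the per-cell library-size
#'   factor.
#' @param seed integer seed.
#' @return a validated list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nGenes = 2000,
                          cellTypes = c(typeA = 750, typeB = 750,
                                        typeC = 750, typeD = 750),
                          nMarkerGenesPerType = 50,
                          markerFoldChange = 8,
                          batches = c(batch1 = 0.5, batch2 = 0.5),
                          batchEffectGenes = 500,
                          batchEffectFold = 4,
                          nbDispersion = 0.3,
                          baseMeanRange = c(0.1, 5),
                          librarySizeLognormal = c(0, 0.3),
                          seed = 1) {
    spec <- list(nGenes = as.integer(nGenes), cellTypes = cellTypes,
                 nMarkerGenesPerType = as.integer(nMarkerGenesPerType),
                 markerFoldChange = markerFoldChange, batches = batches,
                 batchEffectGenes = as.integer(batchEffectGenes),
                 batchEffectFold = batchEffectFold,
                 nbDispersion = nbDispersion, baseMeanRange = baseMeanRange,
                 librarySizeLognormal = librarySizeLognormal,
                 seed = as.integer(seed))
    stopifnot(spec$nGenes > 0, all(spec$cellTypes > 0),
              !is.null(names(spec$cellTypes)),
              spec$nMarkerGenesPerType >= 0, spec$markerFoldChange > 0,
              abs(sum(spec$batches) - 1) < 1e-8, !is.null(names(spec$batches)),
              spec$batchEffectGenes >= 0, spec$batchEffectFold > 0,
              spec$nbDispersion > 0, all(spec$baseMeanRange > 0),
              spec$nMarkerGenesPerType * length(spec$cellTypes) +
                  spec$batchEffectGenes <= spec$nGenes)
    class(spec) <- "SyntheticSpec"
    spec
}

#' Generate synthetic single-cell counts with known structure
#'
#' Counts are drawn per gene and cell from a negative binomial whose mean is
#' the product of a base gene mean, the type-specific marker fold (for that
#' type's marker genes), the batch fold (for batch-effect genes in that
#' cell's batch), and a per-cell lognormal library-size factor. Marker and
#' batch-effect gene blocks are disjoint, so the cell-type signal and the
#' confounder are separable in principle. Fully reproducible given the seed.
#'
#' @param spec a [syntheticSpec()] object.
#' @return an [ScReference-class] with \code{cell_type}, \code{batch} and
#'   \code{patient} annotations; the marker/batch gene assignments are kept
#'   in \code{metadata()} under \code{truth}.
#' @export
simulateScCounts <- function(spec = syntheticSpec()) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    set.seed(spec$seed)
    G <- spec$nGenes
    types <- names(spec$cellTypes)
    K <- length(types)
    N <- sum(spec$cellTypes)
    genes <- sprintf("gene%04d", seq_len(G))
    cells <- sprintf("cell%05d", seq_len(N))
    cellType <- rep(types, times = spec$cellTypes)

    # batch assignment within each type follows the global fractions, so
    # batch and type are not artificially confounded
    batchNames <- names(spec$batches)
    batch <- unlist(lapply(spec$cellTypes, function(n) {
        counts <- largestRemainder(spec$batches, n)
        sample(rep(batchNames, times = counts))
    }), use.names = FALSE)

    baseMean <- exp(stats::runif(G, log(spec$baseMeanRange[1]),
                                 log(spec$baseMeanRange[2])))
    markerIdx <- split(seq_len(K * spec$nMarkerGenesPerType),
                       rep(seq_len(K), each = spec$nMarkerGenesPerType))
    names(markerIdx) <- types
    batchIdx <- if (spec$batchEffectGenes > 0)
        K * spec$nMarkerGenesPerType + seq_len(spec$batchEffectGenes) else integer()

    libFactor <- stats::rlnorm(N, spec$librarySizeLognormal[1],
                               spec$librarySizeLognormal[2])
    size <- 1 / spec$nbDispersion
    counts <- matrix(0L, G, N, dimnames = list(genes, cells))
    for (b in batchNames) {
        for (tp in types) {
            idx <- which(batch == b & cellType == tp)
            if (!length(idx)) next
            mu <- baseMean
            mu[markerIdx[[tp]]] <- mu[markerIdx[[tp]]] * spec$markerFoldChange
            if (length(batchIdx)) {
                bPow <- match(b, batchNames) - 1
                mu[batchIdx] <- mu[batchIdx] * spec$batchEffectFold^bPow
            }
            lam <- outer(mu, libFactor[idx])
            counts[, idx] <- stats::rnbinom(length(lam), size = size, mu = lam)
        }
    }
    # a few patients per batch, cells assigned at random, so patient-wise
    # pseudobulks mix all cell types
    patient <- paste0(batch, "_pat", sample.int(4, N, replace = TRUE))
    sc <- ScReference(counts, cell_type = cellType, batch = batch,
                      patient = patient)
    metadata(sc)$truth <- list(marker_genes = lapply(markerIdx, function(i) genes[i]),
                               batch_genes = genes[batchIdx],
                               spec = spec)
    sc
}

#' Noiseless or noisy convex mixtures of reference latents
#'
#' Oracle input for testing the latent-space regression: returns
#' \eqn{\sum_c P_c R_c} plus optional Gaussian noise. With zero noise the
#' output is the exact convex combination of panel rows.
#'
#' @param panel a [ReferencePanel-class].
#' @param props non-negative proportion vectors summing to 1; a vector or a
#'   samples-by-types matrix.
#' @param noiseSd standard deviation of added Gaussian noise (default 0).
#' @param seed seed for the noise draw.
#' @return a [LatentEmbedding-class] of mixture latents (one row per
#'   proportion vector).
#' @export
makeMixtureLatents <- function(panel, props, noiseSd = 0, seed = 1) {
    R <- panelMatrix(panel)
    P <- if (is.matrix(props)) props else matrix(props, 1)
    if (ncol(P) != nrow(R))
        stop("proportion vectors have ", ncol(P), " entries but the panel has ",
             nrow(R), " cell types")
    stopifnot(min(P) >= 0, all(abs(rowSums(P) - 1) < 1e-8))
    T <- P %*% R
    if (noiseSd > 0) {
        set.seed(seed)
        T <- T + matrix(stats::rnorm(length(T), 0, noiseSd), nrow(T))
    }
    rownames(T) <- if (!is.null(rownames(P))) rownames(P)
                   else sprintf("mix%03d", seq_len(nrow(T)))
    LatentEmbedding(T)
}
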