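#' Quality-control filtering of cells and genes
#'
#' Removes cells with fewer than \code{minDetectedGenes} detected genes or
#' with a detected-gene count outside the per-dataset
#' \code{[Q_lower, Q_upper]} quantile band, then removes genes detected in
#' fewer than \code{minCellsPerGene} of the *retained* cells (the gene filter
#' is applied after the cell filter, so detection counts refer to surviving
#' cells).
#'
#' @param sc an [ScReference-class].
#' @param minDetectedGenes minimum detected genes per cell (default 200).
#' @param minCellsPerGene minimum retained cells a gene must be detected in
#'   (default 3).
#' @param outlierQuantiles length-2 vector of quantile bounds on the
#'   detected-gene distribution (default \code{c(0.01, 0.99)}).
#' @return list with \code{filtered} (ScReference) and \code{qc}, a list of
#'   pre-filter statistics: \code{detected_genes_per_cell},
#'   \code{library_size_per_cell}, \code{genes_detected_in_n_cells}, and the
#'   quantile bounds used.
#' @export
filterCellsGenes <- function(sc, minDetectedGenes = 200, minCellsPerGene = 3,
                             outlierQuantiles = c(0.01, 0.99)) {
    stopifnot(is(sc, "ScReference"),
              length(outlierQuantiles) == 2,
              outlierQuantiles[1] >= 0, outlierQuantiles[2] <= 1,
              outlierQuantiles[1] < outlierQuantiles[2])
    cts <- as.matrix(assay(sc, "counts"))
    det <- colSums(cts > 0)
    lib <- colSums(cts)
    genesInCells <- rowSums(cts > 0)
    qc <- list(detected_genes_per_cell = det,
               library_size_per_cell = lib,
               genes_detected_in_n_cells = genesInCells,
               lower_quantile = outlierQuantiles[1],
               upper_quantile = outlierQuantiles[2])
    qb <- stats::quantile(det, outlierQuantiles, names = FALSE, type = 7)
    keepCell <- det >= minDetectedGenes & det >= qb[1] & det <= qb[2]
    if (!any(keepCell))
        stop("cell filter removed every cell (thresholds: >= ", minDetectedGenes,
             " detected genes, quantile band [", qb[1], ", ", qb[2], "])")
    sub <- cts[, keepCell, drop = FALSE]
    keepGene <- rowSums(sub > 0) >= minCellsPerGene
    if (!any(keepGene))
        stop("gene filter removed every gene (threshold: detected in >= ",
             minCellsPerGene, " retained cells)")
    list(filtered = sc[keepGene, keepCell], qc = qc)
}

#' Counts-per-10k normalisation with log1p transform
#'
#' Scales each column (cell or sample) to a library size of 10,000
#' (\eqn{Y_{gj} = 10^4 X_{gj} / L_j}) and applies \eqn{\log(1 + Y)}
#' elementwise. Columns with zero library size are left all-zero and flagged.
#'
#' @param mat non-negative numeric matrix, genes in rows.
#' @return list with \code{cp10k}, \code{log1p} matrices and
#'   \code{zero_library} logical per column.
#' @examples
#' cp10kNormalize(matrix(c(1, 1, 2), 3, 1,
#'                dimnames = list(c("a", "b", "c"), "s1")))$cp10k
#' @export
cp10kNormalize <- function(mat) {
    mat <- as.matrix(mat)
    if (min(mat) < 0) stop("input matrix must be non-negative")
    L <- colSums(mat)
    if (!any(L > 0)) stop("all columns have zero library size")
    scale <- ifelse(L > 0, 1e4 / L, 0)
    cp10k <- sweep(mat, 2, scale, "*")
    list(cp10k = cp10k, log1p = log1p(cp10k), zero_library = L == 0)
}

#' Highly variable gene selection by standardized dispersion
#'
#' For each gene, computes the mean and variance of its log-normalised
#' expression across cells, fits a smooth mean-variance trend
#' \eqn{f(\log\bar\mu_g)} by local polynomial regression of log-variance on
#' log-mean, and ranks genes by the standardized dispersion
#' \eqn{\delta_g = \log\bar v_g - f(\log\bar\mu_g)}, descending. Ties are
#' broken lexicographically by gene identifier. Genes with zero variance or
#' zero mean are ranked last (their dispersion is undefined).
#'
#' @param logmat log-normalised matrix, genes in rows.
#' @param nHVG number of genes to return (clamped, with a warning, when fewer
#'   are available).
#' @param span loess span; default adapts so that at least 30 genes support
#'   each local fit.
#' @return list with \code{panel} (ordered gene identifiers) and
#'   \code{stats}, a data.frame with per-gene mean, variance, trend,
#'   dispersion and rank.
#' @export
selectHVGs <- function(logmat, nHVG = 5000, span = NULL) {
    logmat <- as.matrix(logmat)
    mu <- rowMeans(logmat)
    v <- apply(logmat, 1, stats::var)
    usable <- v > 0 & mu > 0
    if (!any(usable))
        stop("all genes have zero variance; cannot rank dispersions")
    lmu <- log(mu[usable])
    lv <- log(v[usable])
    if (is.null(span))
        span <- max(0.3, min(1, 30 / sum(usable)))
    trend <- rep(NA_real_, nrow(logmat))
    names(trend) <- rownames(logmat)
    if (sum(usable) >= 10) {
        fit <- stats::loess(lv ~ lmu, span = span, degree = 2,
                            family = "gaussian")
        trend[usable] <- stats::predict(fit, lmu)
    } else {
        trend[usable] <- mean(lv)     # too few genes for a local fit
    }
    delta <- rep(NA_real_, nrow(logmat))
    names(delta) <- rownames(logmat)
    delta[usable] <- lv - trend[usable]
    ids <- rownames(logmat)
    ord <- order(-ifelse(is.na(delta), -Inf, delta), ids, method = "radix")
    rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
    n <- min(nHVG, sum(usable))
    if (n < nHVG)
        warning("requested ", nHVG, " HVGs but only ", n,
                " genes have a defined dispersion; returning ", n)
    stats <- data.frame(gene = ids, mean = mu, variance = v,
                        trend = trend, dispersion = delta, rank = rank,
                        row.names = NULL)
    list(panel = ids[ord][seq_len(n)], stats = stats)
}

#' Intersect gene sets of reference and bulk data
#'
#' Returns the shared genes \eqn{G^* = genes(X) \cap genes(U)} in the order
#' of the single-cell reference. An empty intersection raises an error that
#' shows example identifiers from each side, which catches identifier
#' namespace mismatches (e.g. symbols vs Ensembl ids).
#'
#' @param sc [ScReference-class] or character vector of gene identifiers.
#' @param bulk [BulkExpression-class] or character vector.
#' @return character vector of shared genes, reference order.
#' @export
intersectGenes <- function(sc, bulk) {
    g1 <- if (is.character(sc)) sc else rownames(sc)
    g2 <- if (is.character(bulk)) bulk else rownames(bulk)
    if (!length(g1) || !length(g2)) stop("both gene sets must be non-empty")
    shared <- g1[g1 %in% g2]
    if (!length(shared))
        stop("no shared genes between reference and bulk; examples - ",
             "reference: ", paste(utils::head(g1, 3), collapse = ", "),
             "; bulk: ", paste(utils::head(g2, 3), collapse = ", "))
    shared
}

# Largest-remainder apportionment of `total` over non-negative weights.
# Ties in the remainders are broken in index order.
largestRemainder <- function(weights, total) {
    w <- weights / sum(weights)
    raw <- w * total
    base <- floor(raw)
    left <- total - sum(base)
    if (left > 0) {
        rem <- raw - base
        up <- order(-rem, seq_along(rem))[seq_len(left)]
        base[up] <- base[up] + 1
    }
    as.integer(base)
}

#' Stratified subsampling of cells, balancing cell types
#'
#' Draws \code{nCells} cells with per-type quotas as equal as possible
#' (largest-remainder apportionment over types). When a type has fewer cells
#' than its quota, all its cells are taken and the deficit is redistributed
#' among the remaining types proportionally to their residual quotas.
#'
#' @param sc an [ScReference-class].
#' @param nCells total number of cells to keep.
#' @param seed integer seed; the draw is reproducible.
#' @return an [ScReference-class] with \code{nCells} cells (or fewer if the
#'   dataset itself is smaller).
#' @export
stratifiedSubsample <- function(sc, nCells = 5000, seed = 1) {
    types <- unique(sc$cell_type)
    K <- length(types)
    if (nCells < K)
        stop("nCells (", nCells, ") is smaller than the number of cell types (", K, ")")
    avail <- vapply(types, function(t) sum(sc$cell_type == t), integer(1))
    if (nCells >= sum(avail)) return(sc)
    quota <- largestRemainder(rep(1, K), nCells)
    names(quota) <- types
    # redistribute deficits from small types to types with spare capacity
    repeat {
        short <- quota > avail
        if (!any(short)) break
        deficit <- sum(quota[short] - avail[short])
        quota[short] <- avail[short]
        roomIdx <- which(!short & quota < avail)
        if (!length(roomIdx) || deficit == 0) break
        add <- largestRemainder(pmax(avail[roomIdx] - quota[roomIdx], 0), deficit)
        add <- pmin(add, avail[roomIdx] - quota[roomIdx])
        quota[roomIdx] <- quota[roomIdx] + add
        if (sum(add) == deficit) next else deficit <- deficit - sum(add)
        if (sum(quota) >= nCells) break
    }
    set.seed(seed)
    keep <- unlist(lapply(types, function(t) {
        idx <- which(sc$cell_type == t)
        if (length(idx) <= quota[t]) idx else sort(sample(idx, quota[t]))
    }), use.names = FALSE)
    sc[, sort(keep)]
}

# kNN graph -> symmetrized adaptive-Gaussian affinity -> row-stochastic
# Markov operator over cells. `logmat` is genes x cells.
diffusionOperator <- function(logmat, kNeighbors = 15) {
    X <- t(as.matrix(logmat))              # cells x genes
    n <- nrow(X)
    if (kNeighbors >= n)
        stop("kNeighbors (", kNeighbors, ") must be smaller than the number of cells (", n, ")")
    # squared euclidean distances via the crossprod identity
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    D2[D2 < 0] <- 0
    diag(D2) <- Inf
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        dk <- sort(D2[i, ], partial = kNeighbors)[kNeighbors]
        # include every cell tied at the k-th neighbour distance, so exactly
        # duplicated cells get symmetric affinity rows
        o <- which(D2[i, ] <= dk)
        sigma2 <- max(dk, .Machine$double.eps)
        A[i, o] <- exp(-D2[i, o] / sigma2)
    }
    A <- (A + t(A)) / 2
    diag(A) <- 1                           # self-affinity keeps M well-posed
    A / rowSums(A)
}

#' Graph-diffusion imputation of single-cell expression
#'
#' Markov-affinity smoothing in the style of MAGIC: builds a cell-cell
#' k-nearest-neighbour graph on the log-normalised profiles, weights edges
#' with an adaptive Gaussian kernel (bandwidth = distance to the k-th
#' neighbour), symmetrizes, row-normalises to a Markov transition matrix
#' \eqn{M} and returns \eqn{(M^t \tilde Y^T)^T}. With
#' \code{diffusionSteps = 0} the input is returned unchanged.
#'
#' @param logmat log-normalised matrix, genes in rows, cells in columns.
#' @param kNeighbors neighbours for the affinity graph (default 15).
#' @param diffusionSteps Markov powering steps \eqn{t} (default 3).
#' @return imputed matrix, same shape and dimnames as the input.
#' @export
imputeDiffusion <- function(logmat, kNeighbors = 15, diffusionSteps = 3) {
    logmat <- as.matrix(logmat)
    if (diffusionSteps == 0) return(logmat)
    M <- diffusionOperator(logmat, kNeighbors)
    Z <- t(logmat)                         # cells x genes
    for (s in seq_len(diffusionSteps)) Z <- M %*% Z
    out <- t(Z)
    out[out < 0] <- 0
    dimnames(out) <- dimnames(logmat)
    out
}

#' One-call single-cell preprocessing chain
#'
#' QC filter, stratified subsample, CP10K + log1p, gene-panel construction
#' (intersection with the bulk gene set first, then HVG selection within the
#' shared genes), and diffusion imputation restricted to the panel.
#'
#' @param sc [ScReference-class] of raw counts.
#' @param bulkGenes character vector of bulk gene identifiers (or a
#'   [BulkExpression-class]); panel genes are guaranteed to exist in it.
#' @param nHVG,nCells,seed,kNeighbors,diffusionSteps see the individual steps.
#' @param minDetectedGenes,minCellsPerGene,outlierQuantiles QC settings.
#' @return list with \code{sc} (filtered+subsampled ScReference),
#'   \code{panel} (ordered gene ids), \code{logcounts} (imputed
#'   log-normalised panel x cells matrix), \code{hvgStats} and \code{qc}.
#' @export
preprocessReference <- function(sc, bulkGenes, nHVG = 5000, nCells = 5000,
                                seed = 1, kNeighbors = 15, diffusionSteps = 3,
                                minDetectedGenes = 200, minCellsPerGene = 3,
                                outlierQuantiles = c(0.01, 0.99)) {
    flt <- filterCellsGenes(sc, minDetectedGenes, minCellsPerGene, outlierQuantiles)
    sub <- stratifiedSubsample(flt$filtered, nCells, seed)
    shared <- intersectGenes(sub, bulkGenes)
    norm <- cp10kNormalize(assay(sub[shared, ], "counts"))
    hvg <- selectHVGs(norm$log1p, nHVG)
    lm <- norm$log1p[hvg$panel, , drop = FALSE]
    imputed <- imputeDiffusion(lm, kNeighbors, diffusionSteps)
    list(sc = sub, panel = hvg$panel, logcounts = imputed,
         hvgStats = hvg$stats, qc = flt$qc)
}

#' Normalise a bulk matrix like the single-cell reference
#'
#' Applies the same CP10K + log1p operators to bulk profiles and restricts to
#' the gene panel in panel order. Missing panel genes are an error (no silent
#' zero-fill). Values that do not look like counts (non-integers) are passed
#' through the same transform with a warning.
#'
#' @param bulk [BulkExpression-class] or genes-by-samples matrix.
#' @param panel ordered gene identifiers.
#' @param libraryGenes genes over which the library size is computed before
#'   panel restriction; defaults to all genes present in \code{bulk}. Pass
#'   the shared gene set \eqn{G^*} to match the reference normalisation
#'   exactly.
#' @return log-normalised panel x samples matrix.
#' @export
normalizeBulk <- function(bulk, panel, libraryGenes = NULL) {
    vals <- if (is(bulk, "SummarizedExperiment")) assay(bulk, "values") else as.matrix(bulk)
    missing <- setdiff(panel, rownames(vals))
    if (length(missing))
        stop(length(missing), " panel gene(s) missing from the bulk matrix, e.g. ",
             paste(utils::head(missing, 3), collapse = ", "))
    if (!is.null(libraryGenes)) {
        libMissing <- setdiff(libraryGenes, rownames(vals))
        if (length(libMissing))
            stop(length(libMissing), " library gene(s) missing from the bulk matrix")
        vals <- vals[libraryGenes, , drop = FALSE]
    }
    if (max(abs(vals - round(vals))) > 1e-8)
        warning("bulk values are not integer counts; applying CP10K + log1p anyway")
    norm <- cp10kNormalize(vals)
    norm$log1p[panel, , drop = FALSE]
}
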