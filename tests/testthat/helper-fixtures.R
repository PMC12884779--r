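# Shared fixtures. Heavy artifacts (trained models, end-to-end runs) are
# memoized so several test files can reuse them within one session.
# Training configurations here are scaled down from the package defaults
# (fewer epochs, smaller panels and hidden layers) to keep the suite fast;
# the properties under test do not depend on the full-scale settings.

suppressMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
    if (!exists(name, envir = .fixtures))
        assign(name, force(expr), envir = .fixtures)
    get(name, envir = .fixtures)
}

# tiny deterministic single-cell reference for unit tests
tinySc <- function(nGenes = 30, nCells = 20, seed = 5) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nCells, 3), nGenes, nCells,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("c%02d", seq_len(nCells))))
    ScReference(m,
                cell_type = rep(c("A", "B"), length.out = nCells),
                batch = rep(c("b1", "b2"), each = nCells / 2),
                patient = rep(c("p1", "p2", "p3", "p4"), length.out = nCells))
}

# four-type two-batch world at synthetic defaults (3,000 cells, 2,000 genes)
deconfWorld <- function() fixture("deconfWorld", {
    sc <- simulateScCounts(syntheticSpec(seed = 101))
    prep <- preprocessReference(sc, rownames(sc), nHVG = 500, nCells = 3000,
                                seed = 1)
    n <- ncol(prep$logcounts)
    set.seed(42)
    test <- sort(sample(n, floor(0.2 * n)))
    train <- setdiff(seq_len(n), test)
    list(prep = prep, train = train, test = test)
})

# joint adversarial training on the four-type world at a given lambda
deconfModel <- function(lambda) fixture(paste0("deconfModel", lambda), {
    w <- deconfWorld()
    trainAAE(w$prep$logcounts[, w$train],
             w$prep$sc$batch[w$train],
             latentDim = 50L, hidden = c(128, 64), advHidden = 32L,
             lambda = lambda, aeEpochs = 15, advEpochs = 8, jointRounds = 12,
             seed = 7)
})

# full synthetic pipeline: five types, 50 random-proportion pseudobulks
e2eWorld <- function() fixture("e2eWorld", {
    spec <- syntheticSpec(cellTypes = c(tA = 600, tB = 600, tC = 600,
                                        tD = 600, tE = 600), seed = 21)
    sc <- simulateScCounts(spec)
    bulks <- simulateBulkRandom(sc, nSamples = 50, nCellsPerSample = 300,
                                seed = 5)
    prep <- preprocessReference(sc, rownames(bulks$expression), nHVG = 1000,
                                nCells = 2500, seed = 1)
    model <- trainAAE(prep$logcounts, prep$sc$batch, latentDim = 64L,
                      hidden = c(256, 128), advHidden = 32L, lambda = 1,
                      aeEpochs = 25, advEpochs = 10, jointRounds = 15,
                      seed = 7)
    cellLat <- encodeCells(model, prep$logcounts)
    panel <- buildReferencePanel(cellLat, prep$sc$cell_type)
    anchor <- buildReferenceAnchor(model, prep$sc, prep$panel)
    bulkLat <- embedBulk(model, normalizeBulk(bulks$expression, prep$panel))
    list(sc = sc, bulks = bulks, prep = prep, model = model,
         cellLat = cellLat, panel = panel, anchor = anchor, bulkLat = bulkLat)
})

# small trained model on low-dimensional data for cheap aae unit tests
miniTrained <- function() fixture("miniTrained", {
    set.seed(9)
    x <- matrix(abs(rnorm(60 * 150, 2)), 60, 150,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("c%03d", 1:150)))
    lab <- factor(rep(c("u", "v"), length.out = 150))
    list(x = x, labels = lab,
         model = trainAAE(x, lab, latentDim = 8L, hidden = 16L, advHidden = 8L,
                          lambda = 1, aeEpochs = 6, advEpochs = 4,
                          jointRounds = 4, batchSize = 32, seed = 3))
})

# LDA probe used for separability checks on embeddings
probeAccuracy <- function(Ztrain, labTrain, Ztest, labTest) {
    fit <- suppressWarnings(MASS::lda(Ztrain, grouping = factor(labTrain)))
    mean(as.character(predict(fit, Ztest)$class) == as.character(labTest))
}

# tiny pipeline config on disk; returns the config path
tinyPipelineDirs <- function() fixture("tinyPipelineDirs", {
    root <- tempfile("pipe")
    dir.create(root)
    spec <- syntheticSpec(nGenes = 300,
                          cellTypes = c(a = 150, b = 150, c = 150),
                          nMarkerGenesPerType = 20, batchEffectGenes = 60,
                          seed = 31)
    sc <- simulateScCounts(spec)
    writeScDataset(sc, file.path(root, "sc"))
    bulks <- simulateBulkRandom(sc, nSamples = 8, nCellsPerSample = 120, seed = 3)
    write.table(bulks$expression, file.path(root, "bulk.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    cfg <- list(sc_path = file.path(root, "sc"),
                bulk_path = file.path(root, "bulk.tsv"),
                out_dir = file.path(root, "out"),
                seed = 11, n_hvg = 100, n_cells = 450, latent_dim = 16,
                hidden = c(32), adv_hidden = 8, lambda = 1,
                ae_epochs = 4, adv_epochs = 2, joint_rounds = 3,
                k_neighbors = 10, batch_size = 64)
    cfgPath <- file.path(root, "config.json")
    jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE)
    list(root = root, cfgPath = cfgPath, truth = bulks$trueProportions)
})

# exact two-sided Wilcoxon rank-sum p-value by full enumeration (oracle)
enumWilcoxP <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    combs <- utils::combn(nx + ny, nx)
    W <- apply(combs, 2, function(idx)
        sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
    wobs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
    pl <- mean(W <= wobs); pg <- mean(W >= wobs)
    min(1, 2 * min(pl, pg))
}

# brute-force AUROC by pair counting (oracle)
pairCountAUROC <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}
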