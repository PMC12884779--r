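test_that("QC filtering applies cell thresholds, then gene thresholds", {
    # 6 genes x 5 cells; cell c5 detects only 2 genes, gene g6 only in c5
    m <- matrix(0, 6, 5, dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
    m[1:4, 1:4] <- 5
    m[5, 1:2] <- 2          # gene detected in 2 retained cells -> dropped
    m[c(1, 6), 5] <- 3      # c5: 2 detected genes
    sc <- ScReference(m, cell_type = rep("A", 5))
    res <- filterCellsGenes(sc, minDetectedGenes = 3, minCellsPerGene = 3,
                            outlierQuantiles = c(0, 1))
    expect_setequal(colnames(res$filtered), paste0("c", 1:4))
    # g5 detected in 2 retained cells, g6 in none: both out
    expect_setequal(rownames(res$filtered), paste0("g", 1:4))
    # QC stats describe the pre-filter matrix
    expect_equal(unname(res$qc$detected_genes_per_cell["c5"]), 2)
    expect_equal(unname(res$qc$library_size_per_cell["c1"]), sum(m[, 1]))
})

test_that("QC filtering is idempotent and degenerate quantiles keep all cells", {
    set.seed(1)
    m <- matrix(rpois(50 * 40, 2) + 1, 50, 40,   # all d_j equal (no zeros)
                dimnames = list(paste0("g", 1:50), paste0("c", 1:40)))
    sc <- ScReference(m, cell_type = rep(c("A", "B"), 20))
    once <- filterCellsGenes(sc, minDetectedGenes = 10)
    expect_equal(ncol(once$filtered), 40)   # identical d_j => inside [Q.01, Q.99]
    twice <- filterCellsGenes(once$filtered, minDetectedGenes = 10)
    expect_identical(dim(twice$filtered), dim(once$filtered))
    expect_identical(rownames(twice$filtered), rownames(once$filtered))
})

test_that("QC filtering errors when a step empties the matrix", {
    m <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
    sc <- ScReference(m, cell_type = rep("A", 3))
    expect_error(filterCellsGenes(sc, minDetectedGenes = 100), "cell filter")
    expect_error(filterCellsGenes(sc, minDetectedGenes = 1, minCellsPerGene = 10),
                 "gene filter")
})

test_that("CP10K normalisation matches the closed form and conserves column sums", {
    m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
    norm <- cp10kNormalize(m)
    expect_equal(norm$cp10k[, 1], c(a = 2500, b = 2500, c = 5000))
    expect_equal(norm$log1p[, 1],
                 c(a = log(2501), b = log(2501), c = log(5001)))
    # zero entries stay zero through both transforms
    expect_equal(cp10kNormalize(matrix(c(0, 4), 2, 1,
                 dimnames = list(c("a", "b"), "s")))$log1p[1, 1], 0)
    # property: random non-negative matrices conserve the 1e4 column sum
    set.seed(7)
    for (i in 1:5) {
        x <- matrix(rpois(60, 3), 12, 5,
                    dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
        x[, 3] <- x[, 3] + 1   # guarantee nonzero library
        cs <- colSums(cp10kNormalize(x)$cp10k)
        nz <- colSums(x) > 0
        expect_true(all(abs(cs[nz] - 1e4) < 1e-6))
    }
    expect_error(cp10kNormalize(matrix(-1, 2, 2,
        dimnames = list(c("a", "b"), c("x", "y")))), "non-negative")
    z <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_true(cp10kNormalize(z)$zero_library[1])
})

test_that("HVG ranking matches a brute-force recomputation of dispersion", {
    set.seed(11)
    n <- 150
    logmat <- matrix(abs(rnorm(n * 80, 2, 0.5)), n, 80,
                     dimnames = list(sprintf("g%03d", 1:n), sprintf("c%02d", 1:80)))
    res <- selectHVGs(logmat, nHVG = n)
    # independent recomputation: same trend definition, own code path
    mu <- rowMeans(logmat); v <- apply(logmat, 1, var)
    fit <- loess(log(v) ~ log(mu), span = max(0.3, min(1, 30 / n)), degree = 2)
    delta <- log(v) - predict(fit, log(mu))
    ord <- rownames(logmat)[order(-delta, rownames(logmat))]
    expect_identical(res$panel, ord)
    expect_equal(unname(res$stats$dispersion), unname(delta), tolerance = 1e-10)
})

test_that("an inflated-variance gene ranks first and clamping warns", {
    set.seed(2)
    means <- runif(100, 2, 8)   # spread of means so the trend has support
    base <- matrix(rnorm(100 * 60, rep(means, 60), 1), 100, 60,
                   dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:60)))
    base[17, ] <- rnorm(60, means[17], sqrt(10))  # ~10x the trend variance
    res <- selectHVGs(base, nHVG = 10)
    expect_identical(res$panel[1], "g017")
    expect_warning(selectHVGs(base, nHVG = 500), "only")
    expect_error(selectHVGs(matrix(1, 5, 4,
        dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))), "zero variance")
})

test_that("gene intersection keeps reference order and reports mismatches", {
    expect_identical(intersectGenes(c("A", "B", "C"), c("B", "C", "D")),
                     c("B", "C"))
    expect_identical(intersectGenes(c("C", "A", "B"), c("A", "B", "C")),
                     c("C", "A", "B"))
    expect_error(intersectGenes(c("A", "B"), c("X", "Y")), "A")
})

test_that("stratified subsampling apportions quotas and redistributes deficits", {
    set.seed(3)
    mk <- function(sizes) {
        n <- sum(sizes)
        m <- matrix(rpois(20 * n, 2), 20, n,
                    dimnames = list(paste0("g", 1:20), paste0("c", seq_len(n))))
        ScReference(m, cell_type = rep(names(sizes), sizes))
    }
    sc <- mk(c(t1 = 2000, t2 = 2000, t3 = 2000))
    sub <- stratifiedSubsample(sc, 5000, seed = 1)
    expect_equal(as.vector(table(sub$cell_type)[c("t1", "t2", "t3")]),
                 c(1667, 1667, 1666))
    # deficit redistribution: small type fully taken
    sc2 <- mk(c(t1 = 100, t2 = 3000, t3 = 3000))
    sub2 <- stratifiedSubsample(sc2, 5000, seed = 1)
    tab <- table(sub2$cell_type)
    expect_equal(unname(tab["t1"]), 100)
    expect_equal(sum(tab), 5000)
    expect_equal(abs(diff(as.vector(tab[c("t2", "t3")]))) <= 1, TRUE)
    # determinism
    sub2b <- stratifiedSubsample(sc2, 5000, seed = 1)
    expect_identical(colnames(sub2), colnames(sub2b))
    expect_error(stratifiedSubsample(sc, 2, seed = 1), "smaller")
})

test_that("diffusion imputation is a proper Markov smoother", {
    set.seed(4)
    logmat <- matrix(abs(rnorm(40 * 60, 2)), 40, 60,
                     dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
    # t = 0 is the identity
    expect_identical(imputeDiffusion(logmat, diffusionSteps = 0), logmat)
    # operator rows sum to one before powering
    M <- scLatentDeconv:::diffusionOperator(logmat, kNeighbors = 10)
    expect_equal(rowSums(M), rep(1, 60), tolerance = 1e-12)
    # exactly duplicated cells end up with equal imputed profiles
    logmat[, 2] <- logmat[, 1]
    imp <- imputeDiffusion(logmat, kNeighbors = 10, diffusionSteps = 3)
    expect_equal(imp[, 1], imp[, 2], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # diffusion can only shrink per-gene variance (averaging)
    vBefore <- apply(logmat, 1, var)
    vAfter <- apply(imp, 1, var)
    expect_true(all(vAfter <= vBefore + 1e-12))
    expect_error(imputeDiffusion(logmat, kNeighbors = 60), "smaller")
})

test_that("bulk normalisation refuses missing panel genes", {
    m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_error(normalizeBulk(m, c("a", "zz")), "missing")
    out <- normalizeBulk(m, c("c", "a"))
    expect_identical(rownames(out), c("c", "a"))
})
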