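test_that("reference panel rows are coordinate-wise medians", {
    set.seed(8)
    Z <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(sprintf("c%02d", 1:20), NULL))
    lab <- rep(c("A", "B", "C", "D"), 5)
    panel <- buildReferencePanel(LatentEmbedding(Z), lab)
    # brute-force per-coordinate sort-and-pick oracle
    for (tp in c("A", "B", "C", "D")) {
        rows <- Z[lab == tp, , drop = FALSE]
        manual <- apply(rows, 2, function(v) {
            s <- sort(v); n <- length(s)
            if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
        })
        expect_equal(unname(panelMatrix(panel)[tp, ]), unname(manual))
    }
    # a type with one cell returns that cell's latent exactly
    p1 <- buildReferencePanel(LatentEmbedding(Z[1:3, ]), c("X", "Y", "Y"))
    expect_equal(unname(panelMatrix(p1)["X", ]), unname(Z[1, ]))
    # outlier robustness: median of (1, 2, 100) is 2
    z3 <- matrix(c(1, 2, 100), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
    expect_equal(unname(panelMatrix(
        buildReferencePanel(LatentEmbedding(z3), rep("T", 3)))[1, 1]), 2)
    expect_error(buildReferencePanel(LatentEmbedding(Z), lab[1:5]), "label")
})

test_that("the NNLS solver matches a constrained optimiser on small systems", {
    set.seed(12)
    for (i in 1:10) {
        A <- matrix(rnorm(30 * 4), 30, 4)
        b <- rnorm(30)
        ours <- scLatentDeconv:::nnlsSolve(A, b)
        ref <- optim(rep(0.1, 4), function(x) sum((A %*% x - b)^2),
                     method = "L-BFGS-B", lower = 0,
                     control = list(maxit = 500, factr = 1e3))$par
        expect_equal(ours, ref, tolerance = 1e-4)
        expect_true(all(ours >= 0))
    }
})

test_that("noiseless convex combinations are recovered by both estimators", {
    set.seed(14)
    R <- matrix(rnorm(5 * 40, sd = 3), 5, 40,
                dimnames = list(paste0("t", 1:5), NULL))
    panel <- ReferencePanel(R)
    props <- t(vapply(1:8, function(i) {
        p <- rexp(5); p / sum(p)
    }, numeric(5)))
    mix <- makeMixtureLatents(panel, props, noiseSd = 0)
    estN <- estimateProportions(panel, mix, method = "nnls")
    estB <- estimateProportions(panel, mix, method = "boosted_linear")
    for (i in 1:8) {
        expect_lt(sum(abs(proportions(estN)[i, ] - props[i, ])), 1e-3)
        expect_lt(sum(abs(proportions(estB)[i, ] - proportions(estN)[i, ])), 0.1)
    }
    # half/half mixture of two types, rest absent
    half <- makeMixtureLatents(panel, c(0.5, 0.5, 0, 0, 0))
    for (m in list(estB, estN)) NULL
    for (meth in c("nnls", "boosted_linear")) {
        est <- estimateProportions(panel, half, method = meth)
        expect_lt(sum(abs(proportions(est)[1, ] - c(0.5, 0.5, 0, 0, 0))), 0.05)
    }
})

test_that("clip-and-renormalise follows the stated rule", {
    r <- clipRenormalize(c(-0.2, 0.6, 0.6))
    expect_equal(r$p, c(0, 0.5, 0.5))
    expect_false(r$degenerate)
    u <- clipRenormalize(c(-1, -2, 0))
    expect_equal(u$p, rep(1 / 3, 3))
    expect_true(u$degenerate)
    # degenerate path through the full estimator: a zero latent vector
    R <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), NULL))
    z <- matrix(0, 1, 2, dimnames = list("s1", NULL))
    est <- estimateProportions(ReferencePanel(R), LatentEmbedding(z),
                               method = "nnls")
    expect_true(degenerateFlags(est))
    expect_equal(unname(proportions(est)[1, ]), c(0.5, 0.5))
})

test_that("every emitted proportion vector is a probability vector", {
    set.seed(15)
    R <- matrix(rnorm(4 * 25), 4, 25, dimnames = list(paste0("t", 1:4), NULL))
    T <- matrix(rnorm(30 * 25, sd = 2), 30, 25,
                dimnames = list(sprintf("s%02d", 1:30), NULL))
    for (meth in c("nnls", "boosted_linear")) {
        est <- estimateProportions(ReferencePanel(R), LatentEmbedding(T),
                                   method = meth)
        P <- proportions(est)
        expect_true(min(P) >= 0)
        expect_equal(unname(rowSums(P)), rep(1, 30), tolerance = 1e-9)
    }
    expect_error(estimateProportions(ReferencePanel(R),
        LatentEmbedding(matrix(0, 2, 7,
            dimnames = list(c("a", "b"), NULL)))), "mismatch")
})

test_that("scoring matches brute-force metrics and flags undefined r", {
    P <- matrix(c(0.6, 0.4, 0.3, 0.7, 0.5, 0.5), 3, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("A", "B")))
    s <- scoreProportions(P, P)
    expect_equal(s$perType$pearson, c(1, 1))
    expect_equal(s$mse, 0)
    expect_equal(s$mad, 0)
    truth <- matrix(c(0.5, 0.5), 1, 2,
                    dimnames = list("s1", c("A", "B")))
    pred <- matrix(c(0.6, 0.4), 1, 2, dimnames = list("s1", c("A", "B")))
    s2 <- scoreProportions(pred, truth)
    expect_equal(s2$mad, 0.1)
    expect_equal(s2$mse, 0.01)
    expect_true(all(is.na(s2$perType$pearson)))   # single sample: r undefined
    # brute-force oracle on random instances
    set.seed(16)
    for (i in 1:5) {
        tr <- matrix(runif(8 * 3), 8, 3,
                     dimnames = list(paste0("s", 1:8), c("A", "B", "C")))
        tr <- tr / rowSums(tr)
        pr <- matrix(runif(8 * 3), 8, 3, dimnames = dimnames(tr))
        pr <- pr / rowSums(pr)
        s3 <- scoreProportions(pr, tr)
        expect_equal(s3$mse, mean((pr - tr)^2))
        expect_equal(s3$mad, mean(abs(pr - tr)))
        expect_equal(s3$r, cor(as.numeric(pr), as.numeric(tr)))
        for (k in 1:3)
            expect_equal(s3$perType$pearson[k], cor(tr[, k], pr[, k]))
    }
    # zero-variance truth: NA, not zero
    constT <- matrix(0.5, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
    sNA <- scoreProportions(constT, constT)
    expect_true(all(is.na(sNA$perType$pearson)))
})
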