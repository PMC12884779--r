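test_that("encoding is deterministic and shared between cells and bulk", {
    mt <- miniTrained()
    z1 <- encodeCells(mt$model, mt$x)
    z2 <- encodeCells(mt$model, mt$x)
    expect_identical(latentCoords(z1), latentCoords(z2))
    expect_equal(dim(latentCoords(z1)), c(150, 8))
    # one row in -> one latent row out
    one <- encodeCells(mt$model, mt$x[, 1, drop = FALSE])
    expect_equal(nrow(latentCoords(one)), 1)
    # a bulk sample with a cell's exact profile lands on the cell's latent
    zb <- embedBulk(mt$model, mt$x[, 3, drop = FALSE])
    expect_equal(unname(latentCoords(zb)[1, ]),
                 unname(latentCoords(z1)[3, ]))
    # permuting samples permutes rows identically
    perm <- c(5, 1, 9)
    zp <- embedBulk(mt$model, mt$x[, perm])
    expect_equal(unname(latentCoords(zp)),
                 unname(latentCoords(z1)[perm, ]))
    # gene-order and missing-gene guards
    shuffled <- mt$x[rev(rownames(mt$x)), ]
    expect_error(encodeCells(mt$model, shuffled), "order")
    expect_error(embedBulk(mt$model, mt$x[-1, ]), "missing")
})

test_that("reconstruction loss follows the squared-norm definition", {
    mt <- miniTrained()
    expect_gte(reconstructionLoss(mt$model, mt$x), 0)
    # zero all weights: reconstruction is 0, loss = mean squared norm of x
    m0 <- mt$model
    for (i in seq_along(m0@decoder)) {
        m0@decoder[[i]]$W[] <- 0
        m0@decoder[[i]]$b[] <- 0
    }
    expect_equal(reconstructionLoss(m0, mt$x),
                 mean(rowSums(t(mt$x)^2)))
})

test_that("adversary cross-entropy has its closed-form anchors", {
    # uniform prediction (all-zero adversary) -> log K
    model <- aaeModel(paste0("g", 1:10), factor(rep(c("a", "b", "c"), 4)),
                      latentDim = 4L, hidden = 8L, advHidden = 4L, seed = 1)
    for (i in seq_along(model@adversaries$confounder)) {
        model@adversaries$confounder[[i]]$W[] <- 0
        model@adversaries$confounder[[i]]$b[] <- 0
    }
    z <- LatentEmbedding(matrix(rnorm(12 * 4), 12, 4,
                                dimnames = list(paste0("r", 1:12), NULL)))
    labs <- factor(rep(c("a", "b", "c"), 4))
    expect_equal(adversaryLoss(model, z, labs), log(3), tolerance = 1e-12)
    # perfect prediction -> 0 (crafted logits through the internal loss)
    logits <- matrix(-50, 6, 2)
    y <- rep(1:2, 3)
    logits[cbind(1:6, y)] <- 50
    expect_lt(scLatentDeconv:::crossEntropy(logits, y), 1e-10)
    # unseen class guard
    expect_error(adversaryLoss(model, z, factor(rep("zz", 12))), "unseen")
})

test_that("pretraining reduces reconstruction loss and respects zero epochs", {
    mt <- miniTrained()
    h <- trainingHistory(mt$model)
    ae <- h[h$phase == "ae_pretrain", ]
    expect_lt(ae$reconstruction[nrow(ae)], ae$reconstruction[1])
    # zero epochs / rounds are no-ops
    m0 <- aaeModel(rownames(mt$x), mt$labels, latentDim = 8L, hidden = 16L,
                   advHidden = 8L, seed = 3)
    expect_identical(pretrainAutoencoder(m0, mt$x, epochs = 0), m0)
    expect_identical(pretrainAdversary(m0, mt$x, mt$labels, epochs = 0), m0)
    expect_identical(jointAdversarialTrain(m0, mt$x, mt$labels, rounds = 0), m0)
    # single-class labels are rejected for adversarial training
    m1c <- aaeModel(rownames(mt$x), factor(rep("one", 150)), latentDim = 8L,
                    hidden = 16L, advHidden = 8L, seed = 3)
    expect_error(pretrainAdversary(m1c, mt$x, factor(rep("one", 150))),
                 "single class")
})

test_that("training is bitwise reproducible under a fixed seed", {
    set.seed(5)
    x <- matrix(abs(rnorm(40 * 80, 2)), 40, 80,
                dimnames = list(paste0("g", 1:40), paste0("c", 1:80)))
    lab <- factor(rep(c("u", "v"), 40))
    args <- list(x, lab, latentDim = 6L, hidden = 12L, advHidden = 6L,
                 lambda = 1, aeEpochs = 3, advEpochs = 2, jointRounds = 2,
                 batchSize = 32, seed = 21)
    m1 <- do.call(trainAAE, args)
    m2 <- do.call(trainAAE, args)
    expect_identical(trainingHistory(m1), trainingHistory(m2))
    expect_identical(latentCoords(encodeCells(m1, x)),
                     latentCoords(encodeCells(m2, x)))
})

test_that("a pretrained adversary learns real labels but not shuffled ones", {
    set.seed(31)
    # two well-separated expression groups aligned with the label
    n <- 120
    x <- matrix(abs(rnorm(30 * n, 2)), 30, n,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:n)))
    lab <- factor(rep(c("u", "v"), each = n / 2))
    x[1:15, lab == "v"] <- x[1:15, lab == "v"] + 6
    m <- aaeModel(rownames(x), lab, latentDim = 6L, hidden = 12L,
                  advHidden = 8L, seed = 2)
    m <- pretrainAutoencoder(m, x, epochs = 15, batchSize = 32, seed = 3)
    mAdv <- pretrainAdversary(m, x, lab, epochs = 40, batchSize = 32,
                              lr = 1e-2, seed = 4)
    z <- encodeCells(mAdv, x)
    expect_gt(adversaryAccuracy(mAdv, z, lab), 0.9)
    shuf <- factor(sample(as.character(lab)))
    mShuf <- pretrainAdversary(m, x, shuf, epochs = 20, batchSize = 32,
                               lr = 1e-2, seed = 4)
    accShuf <- adversaryAccuracy(mShuf, encodeCells(mShuf, x), shuf)
    expect_lt(accShuf, 0.5 + 0.2)   # near the 2-class chance level
})

test_that("joint adversarial training removes batch information at lambda = 1", {
    w <- deconfWorld()
    batch <- w$prep$sc$batch
    ctype <- w$prep$sc$cell_type
    xte <- w$prep$logcounts[, w$test]

    m1 <- deconfModel(1)
    zTr <- latentCoords(encodeCells(m1, w$prep$logcounts[, w$train]))
    zTe <- latentCoords(encodeCells(m1, xte))
    advAcc1 <- adversaryAccuracy(m1, zTe, batch[w$test])
    expect_lte(advAcc1, 0.5 + 0.10)
    # biology survives: a fresh probe still separates the four cell types
    typeAcc <- probeAccuracy(zTr, ctype[w$train], zTe, ctype[w$test])
    expect_gt(typeAcc, 0.8)

    m0 <- deconfModel(0)
    zTe0 <- latentCoords(encodeCells(m0, xte))
    advAcc0 <- adversaryAccuracy(m0, zTe0, batch[w$test])
    expect_gt(advAcc0, 0.8)
    # lambda-monotonicity (direction only)
    expect_lte(advAcc1, advAcc0)
})
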