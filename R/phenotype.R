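# kNN mutual information between one continuous feature and a discrete
# label (Ross 2014): for each point, eps_i = distance to the k-th nearest
# neighbour within its own class; m_i = points of any class within eps_i.
# MI = digamma(N) - <digamma(N_c)> + <digamma(k)> - <digamma(m)>.
miKnnDiscrete <- function(x, y, k = 3) {
    n <- length(x)
    y <- as.integer(factor(y))
    nC <- tabulate(y)
    psiK <- numeric(n); psiM <- numeric(n)
    for (i in seq_len(n)) {
        same <- which(y == y[i]); same <- same[same != i]
        ki <- min(k, length(same))
        if (ki == 0) { psiK[i] <- NA; next }
        d <- abs(x[same] - x[i])
        eps <- sort(d, partial = ki)[ki]
        m <- sum(abs(x - x[i]) <= eps) - 1
        psiK[i] <- digamma(ki)
        psiM[i] <- digamma(max(m, 1))
    }
    ok <- !is.na(psiK)
    mi <- digamma(n) - mean(digamma(nC[y[ok]])) + mean(psiK[ok]) - mean(psiM[ok])
    max(mi, 0)
}

#' Rank cell-type proportions by mutual information with a phenotype
#'
#' Estimates the mutual information between each proportion feature and a
#' binary label with a k-nearest-neighbour estimator. Because the estimator
#' is randomised (a tiny jitter breaks ties, as in common implementations),
#' the calculation is repeated \code{nRepeats} times (default 20) and the
#' per-feature scores averaged; features are ranked by the mean, descending.
#'
#' @param P a [ProportionEstimate-class] or samples x features matrix.
#' @param labels binary phenotype per sample (two classes, each with >= 2
#'   samples).
#' @param nRepeats repeats to average (default 20).
#' @param k neighbours for the estimator (default 3).
#' @param seed master seed; repeat seeds derive from it.
#' @return data.frame with feature, mean MI (\code{mi}), rank, and one
#'   column per repeat; ordered by rank.
#' @export
rankFeaturesMI <- function(P, labels, nRepeats = 20, k = 3, seed = 1) {
    X <- if (is(P, "ProportionEstimate")) proportions(P) else as.matrix(P)
    y <- factor(labels)
    if (nlevels(y) != 2) stop("labels must have exactly two classes")
    if (min(table(y)) < 2) stop("each class needs at least two samples")
    reps <- matrix(0, ncol(X), nRepeats,
                   dimnames = list(colnames(X), paste0("rep", seq_len(nRepeats))))
    for (r in seq_len(nRepeats)) {
        set.seed(seed * 100L + r)
        for (j in seq_len(ncol(X))) {
            x <- X[, j]
            jitter <- 1e-10 * max(mean(abs(x)), 1) * stats::rnorm(length(x))
            reps[j, r] <- miKnnDiscrete(x + jitter, y, k)
        }
    }
    mi <- rowMeans(reps)
    ord <- order(-mi, rownames(reps))
    out <- data.frame(feature = rownames(reps), mi = mi,
                      rank = match(seq_len(nrow(reps)), ord), row.names = NULL)
    out <- cbind(out, reps)
    out[ord, , drop = FALSE]
}

# ---- small gradient-boosted regression trees (logistic loss) ------------

# exhaustive-split regression tree on (X, g, h) Newton targets; returns a
# nested list usable by treePredict
fitTree <- function(X, g, h, depth, minObs = 4, lambdaReg = 1) {
    build <- function(rows, d) {
        leafVal <- -sum(g[rows]) / (sum(h[rows]) + lambdaReg)
        if (d == 0 || length(rows) < 2 * minObs)
            return(list(leaf = TRUE, value = leafVal))
        best <- NULL
        baseScore <- sum(g[rows])^2 / (sum(h[rows]) + lambdaReg)
        for (j in seq_len(ncol(X))) {
            xv <- X[rows, j]
            ord <- order(xv)
            gs <- cumsum(g[rows][ord]); hs <- cumsum(h[rows][ord])
            gt <- gs[length(rows)]; ht <- hs[length(rows)]
            for (s in minObs:(length(rows) - minObs)) {
                if (xv[ord[s]] == xv[ord[s + 1]]) next
                gain <- gs[s]^2 / (hs[s] + lambdaReg) +
                    (gt - gs[s])^2 / (ht - hs[s] + lambdaReg) - baseScore
                if (is.null(best) || gain > best$gain)
                    best <- list(gain = gain, feature = j,
                                 cut = (xv[ord[s]] + xv[ord[s + 1]]) / 2)
            }
        }
        if (is.null(best) || best$gain <= 1e-12)
            return(list(leaf = TRUE, value = leafVal))
        left <- rows[X[rows, best$feature] <= best$cut]
        right <- setdiff(rows, left)
        list(leaf = FALSE, feature = best$feature, cut = best$cut,
             left = build(left, d - 1), right = build(right, d - 1))
    }
    build(seq_len(nrow(X)), depth)
}

treePredict <- function(tree, X) {
    pred <- numeric(nrow(X))
    walk <- function(node, rows) {
        if (node$leaf) { pred[rows] <<- node$value; return(invisible()) }
        go <- X[rows, node$feature] <= node$cut
        if (any(go)) walk(node$left, rows[go])
        if (any(!go)) walk(node$right, rows[!go])
    }
    walk(tree, seq_len(nrow(X)))
    pred
}

# boosted-trees binary classifier: depth-3 trees, logistic loss,
# Newton leaf values, shrinkage eta
boostedTreesFit <- function(X, y, nRounds = 100, eta = 0.1, depth = 3) {
    X <- as.matrix(X)
    y <- as.numeric(y)                  # 0/1
    F <- rep(0, nrow(X))
    trees <- vector("list", nRounds)
    for (m in seq_len(nRounds)) {
        p <- 1 / (1 + exp(-F))
        g <- p - y
        h <- pmax(p * (1 - p), 1e-6)
        tr <- fitTree(X, g, h, depth)
        trees[[m]] <- tr
        F <- F + eta * treePredict(tr, X)
    }
    list(trees = trees, eta = eta)
}

boostedTreesPredict <- function(fit, X) {
    X <- as.matrix(X)
    F <- rep(0, nrow(X))
    for (tr in fit$trees) F <- F + fit$eta * treePredict(tr, X)
    1 / (1 + exp(-F))
}

# stratified fold assignment
stratifiedFolds <- function(y, nFolds) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
}

#' Cross-validated classification over increasing feature counts
#'
#' Ranks features by mutual information, then for each k in \code{kGrid}
#' trains a gradient-boosted tree classifier (depth 3, 100 rounds, learning
#' rate 0.1) on the top-k features under repeated stratified
#' cross-validation and reports the mean AUROC. The best k is the one
#' maximising mean AUROC (ties broken towards fewer features).
#'
#' @param P proportions (samples x features) or [ProportionEstimate-class].
#' @param labels binary phenotype per sample.
#' @param kGrid feature counts to evaluate (default 1..number of features).
#' @param nFolds folds per repeat (default 5, reduced if a class is small).
#' @param nRepeats cross-validation repeats (default 10).
#' @param nRounds,eta,depth classifier settings.
#' @param miRepeats repeats for the MI ranking (default 20).
#' @param seed master seed.
#' @return list with \code{auroc} (data.frame k vs mean AUROC),
#'   \code{bestK}, \code{features} (the top-bestK features) and
#'   \code{ranking}.
#' @export
selectTopKClassify <- function(P, labels, kGrid = NULL, nFolds = 5,
                               nRepeats = 10, nRounds = 100, eta = 0.1,
                               depth = 3, miRepeats = 20, seed = 1) {
    X <- if (is(P, "ProportionEstimate")) proportions(P) else as.matrix(P)
    y <- factor(labels)
    if (nlevels(y) != 2) stop("labels must have exactly two classes")
    if (length(y) < 10) stop("at least 10 samples required")
    nFolds <- min(nFolds, min(table(y)))
    if (nFolds < 2) stop("too few samples per class for cross-validation")
    ranking <- rankFeaturesMI(X, y, nRepeats = miRepeats, seed = seed)
    ordered <- ranking$feature
    if (is.null(kGrid)) kGrid <- seq_len(ncol(X))
    kGrid <- kGrid[kGrid >= 1 & kGrid <= ncol(X)]
    y01 <- as.integer(y) - 1L
    means <- numeric(length(kGrid))
    for (ki in seq_along(kGrid)) {
        feats <- ordered[seq_len(kGrid[ki])]
        aucs <- c()
        for (r in seq_len(nRepeats)) {
            set.seed(seed * 1000L + r)
            fold <- stratifiedFolds(y01, nFolds)
            scores <- numeric(length(y01))
            for (f in seq_len(nFolds)) {
                tr <- fold != f
                fit <- boostedTreesFit(X[tr, feats, drop = FALSE], y01[tr],
                                       nRounds, eta, depth)
                scores[!tr] <- boostedTreesPredict(fit, X[!tr, feats, drop = FALSE])
            }
            aucs <- c(aucs, aurocScore(scores, y01))
        }
        means[ki] <- mean(aucs)
    }
    best <- kGrid[order(-means, kGrid)][1]
    list(auroc = data.frame(k = kGrid, mean_auroc = means),
         bestK = best, features = ordered[seq_len(best)], ranking = ranking)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties counted as one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric score per sample (higher = more positive).
#' @param labels binary labels; the larger level (or 1) is the positive
#'   class. Both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
    y <- if (is.factor(labels)) as.integer(labels) == nlevels(labels)
         else labels == max(labels)
    nPos <- sum(y); nNeg <- sum(!y)
    if (nPos == 0 || nNeg == 0) stop("both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Group-wise comparison of proportions (Wilcoxon rank-sum)
#'
#' For each cell type, a two-sided Wilcoxon rank-sum test of the proportion
#' between the two groups, with group medians, the direction of change, and
#' Benjamini-Hochberg adjusted p-values alongside the raw ones. The 0.05
#' threshold is conventional and reported, not enforced.
#'
#' @param P proportions (samples x cell types) or
#'   [ProportionEstimate-class].
#' @param groups two-level grouping per sample (e.g. responder status).
#' @return data.frame: cell_type, median per group, direction, p_value,
#'   p_adjusted.
#' @export
compareProportions <- function(P, groups) {
    X <- if (is(P, "ProportionEstimate")) proportions(P) else as.matrix(P)
    g <- factor(groups)
    if (nlevels(g) != 2) stop("exactly two groups required")
    a <- levels(g)[1]; b <- levels(g)[2]
    res <- lapply(seq_len(ncol(X)), function(j) {
        xa <- X[g == a, j]; xb <- X[g == b, j]
        p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL)$p.value)
        if (is.nan(p)) p <- 1   # all observations tied: no rank separation
        data.frame(cell_type = colnames(X)[j],
                   median_group1 = stats::median(xa),
                   median_group2 = stats::median(xb),
                   direction = if (stats::median(xb) > stats::median(xa))
                       "up" else if (stats::median(xb) < stats::median(xa))
                       "down" else "none",
                   p_value = p)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out
}
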