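#' Build the per-cell-type reference panel of median latents
#'
#' Coordinate-wise median of each cell type's latent vectors; even-sized
#' groups use the midpoint of the two central values. Each row of the result
#' is the representation \eqn{R_c} of one cell type.
#'
#' @param latents a [LatentEmbedding-class] (rows = cells).
#' @param cellType label per latent row.
#' @return a [ReferencePanel-class] with one row per type, in sorted label
#'   order.
#' @export
buildReferencePanel <- function(latents, cellType) {
    Z <- latentCoords(latents)
    if (length(cellType) != nrow(Z))
        stop("one cell-type label per latent row required")
    types <- sort(unique(as.character(cellType)))
    R <- t(vapply(types, function(tp) {
        rows <- which(cellType == tp)
        if (!length(rows)) stop("cell type '", tp, "' has no cells")
        apply(Z[rows, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(Z))))
    rownames(R) <- types
    ReferencePanel(R)
}

# Lawson-Hanson non-negative least squares: min ||A x - b||^2, x >= 0.
# A is m x n with small n (cell types), so the active-set solve is cheap.
nnlsSolve <- function(A, b, tol = 1e-10, maxIter = NULL) {
    n <- ncol(A)
    if (is.null(maxIter)) maxIter <- 10 * n
    x <- numeric(n)
    passive <- logical(n)
    w <- crossprod(A, b - A %*% x)
    iter <- 0
    while (any(!passive) && any(w[!passive] > tol) && iter < maxIter) {
        iter <- iter + 1
        j <- which(!passive)[which.max(w[!passive])]
        passive[j] <- TRUE
        repeat {
            Ap <- A[, passive, drop = FALSE]
            s <- numeric(n)
            s[passive] <- qr.solve(Ap, b)
            if (all(s[passive] > tol)) { x <- s; break }
            inP <- which(passive)
            neg <- inP[s[inP] <= tol]
            alpha <- min(x[neg] / (x[neg] - s[neg]))
            x <- x + alpha * (s - x)
            passive[passive & x <= tol] <- FALSE
            x[!passive] <- 0
        }
        w <- crossprod(A, b - A %*% x)
    }
    as.numeric(x)
}

# Gradient boosting with a linear base learner: each round fits the current
# residual with an L2-penalised linear model and adds a shrunk (eta) copy to
# the ensemble, stopping on a training-loss plateau. The ensemble's summed
# weights are the extracted coefficients. Unlike cyclic coordinate descent,
# the full linear base fit converges geometrically at rate (1 - eta) even on
# the near-collinear panels latent medians produce. No intercept: the model
# is T = P * R.
boostedLinearCoefs <- function(A, b, rounds = 500, eta = 0.3, alpha = 1e-3,
                               tol = 1e-12) {
    n <- ncol(A)
    H <- crossprod(A) + diag(alpha, n)
    ch <- chol(H)
    beta <- numeric(n)
    r <- b
    rssPrev <- sum(r^2)
    for (it in seq_len(rounds)) {
        delta <- backsolve(ch, forwardsolve(t(ch), crossprod(A, r)))
        beta <- beta + eta * delta
        r <- r - eta * (A %*% delta)
        rss <- sum(r^2)
        if (rssPrev - rss <= tol * max(rssPrev, 1)) break   # plateau
        rssPrev <- rss
    }
    as.numeric(beta)
}

#' Estimate cell-type proportions of bulk samples in latent space
#'
#' For each bulk sample independently, treats the latent coordinates as
#' observations and the transposed reference panel (latent dims x cell
#' types) as the design matrix, solving \eqn{T = P R} for the coefficient
#' vector \eqn{P}. Negative coefficients are clipped to zero and the rest
#' renormalised to sum to one. When every clipped coefficient is zero the
#' uniform vector is emitted and the sample flagged degenerate.
#'
#' @param panel a [ReferencePanel-class].
#' @param bulkLatents a [LatentEmbedding-class] of bulk samples (or a
#'   samples x latent matrix).
#' @param method \code{"boosted_linear"} (gradient boosting with linear base
#'   learners, the primary estimator) or \code{"nnls"} (non-negative least
#'   squares, retained as an independent oracle).
#' @param anchor optional curvature anchor from [buildReferenceAnchor()]: the
#'   embedding of a pseudobulk mixed from the reference cells themselves,
#'   with its known composition. Because the encoder is trained on single
#'   cells, bulk mixtures acquire a shared off-manifold latent offset; the
#'   anchor column absorbs it, and the anchor coefficient is folded back
#'   into the type coefficients via the anchor's composition before
#'   clipping.
#' @param rounds,eta,alpha boosting rounds, shrinkage and L2 penalty for the
#'   boosted-linear method.
#' @return a [ProportionEstimate-class].
#' @export
estimateProportions <- function(panel, bulkLatents,
                                method = c("boosted_linear", "nnls"),
                                anchor = NULL,
                                rounds = 500, eta = 0.3, alpha = 1e-3) {
    method <- match.arg(method)
    R <- panelMatrix(panel)
    T <- if (is(bulkLatents, "LatentEmbedding")) latentCoords(bulkLatents)
         else as.matrix(bulkLatents)
    if (ncol(T) != ncol(R))
        stop("latent dimension mismatch: bulk has ", ncol(T),
             ", panel has ", ncol(R))
    if (nrow(R) < 2) stop("at least two cell types required")
    A <- t(R)                                 # d_latent x K design
    K <- nrow(R)
    if (!is.null(anchor)) {
        if (length(anchor$latent) != ncol(R))
            stop("anchor latent dimension does not match the panel")
        pref <- anchor$composition[rownames(R)]
        if (anyNA(pref)) stop("anchor composition must cover every panel cell type")
    }
    M <- nrow(T)
    raw <- matrix(0, M, K, dimnames = list(rownames(T), rownames(R)))
    P <- raw
    degen <- logical(M)
    for (m in seq_len(M)) {
        b <- T[m, ]
        if (is.null(anchor)) {
            beta <- if (method == "nnls") nnlsSolve(A, b)
                    else boostedLinearCoefs(A, b, rounds, eta, alpha)
        } else if (method == "nnls") {
            # the anchor coefficient may take either sign under the
            # non-negative solver: try +u and -u, keep the better fit
            fits <- lapply(c(1, -1), function(sg) {
                Ax <- cbind(A, sg * anchor$latent)
                bt <- nnlsSolve(Ax, b)
                list(beta = bt, sign = sg,
                     rss = sum((Ax %*% bt - b)^2))
            })
            best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
            beta <- best$beta[seq_len(K)] +
                best$sign * best$beta[K + 1] * pref
        } else {
            bt <- boostedLinearCoefs(cbind(A, anchor$latent), b, rounds, eta, alpha)
            beta <- bt[seq_len(K)] + bt[K + 1] * pref
        }
        raw[m, ] <- beta
        clipped <- pmax(beta, 0)
        if (sum(clipped) <= 0) {
            P[m, ] <- rep(1 / K, K)
            degen[m] <- TRUE
        } else {
            P[m, ] <- clipped / sum(clipped)
        }
    }
    new("ProportionEstimate", proportions = P, rawCoefficients = raw,
        degenerate = degen, method = method)
}

#' Build a curvature anchor from the reference cells
#'
#' Sums the reference cells' raw counts into one pseudobulk, normalises it
#' exactly like a bulk sample and embeds it with the trained encoder. The
#' resulting latent carries the same mixture-curvature offset that real bulk
#' embeddings acquire (the encoder is trained on single cells, and a log1p
#' profile of a mixture is not the mixture of log1p profiles), while its
#' cell-type composition is known: the reference's own cell-count fractions.
#' [estimateProportions()] can use this pair to absorb the offset.
#'
#' @param model a trained [AAEModel-class].
#' @param sc the [ScReference-class] the model was trained on (counts used).
#' @param panel ordered panel gene identifiers (as in the model).
#' @param libraryGenes optional gene set for the library normalisation, see
#'   [normalizeBulk()].
#' @return list with \code{latent} (numeric vector) and \code{composition}
#'   (named cell-count fractions).
#' @export
buildReferenceAnchor <- function(model, sc, panel = panelGenes(model),
                                 libraryGenes = NULL) {
    cts <- as.matrix(assay(sc, "counts"))
    pb <- matrix(rowSums(cts), ncol = 1,
                 dimnames = list(rownames(cts), "reference_pseudobulk"))
    u <- latentCoords(embedBulk(model, normalizeBulk(pb, panel, libraryGenes)))[1, ]
    comp <- table(sc$cell_type) / ncol(sc)
    list(latent = u, composition = stats::setNames(as.numeric(comp), names(comp)))
}

#' Clip negative coefficients and renormalise to a probability vector
#'
#' The post-processing rule applied to raw regression coefficients:
#' negatives to zero, survivors scaled to sum to one; an all-non-positive
#' vector falls back to uniform (flagged by the caller).
#'
#' @param beta numeric coefficient vector.
#' @return list with \code{p} (probability vector) and \code{degenerate}.
#' @export
clipRenormalize <- function(beta) {
    clipped <- pmax(beta, 0)
    if (sum(clipped) <= 0)
        list(p = rep(1 / length(beta), length(beta)), degenerate = TRUE)
    else
        list(p = clipped / sum(clipped), degenerate = FALSE)
}

#' Score predicted against true proportions
#'
#' Per-cell-type Pearson r across samples, overall r across all
#' (sample, type) pairs, mean squared error and mean absolute deviation.
#' A correlation undefined for lack of variance (or fewer than two samples)
#' is reported as \code{NA}, never as zero.
#'
#' @param pred a [ProportionEstimate-class] or samples x types matrix.
#' @param truth samples x types matrix of ground-truth proportions; sample
#'   and type names must match.
#' @return list with \code{perType} (data.frame of per-type r), \code{r}
#'   (overall), \code{mse}, \code{mad}.
#' @export
scoreProportions <- function(pred, truth) {
    P <- if (is(pred, "ProportionEstimate")) proportions(pred) else as.matrix(pred)
    truth <- as.matrix(truth)
    if (!is.null(rownames(P)) && !is.null(rownames(truth))) {
        if (!setequal(rownames(P), rownames(truth)))
            stop("sample sets of prediction and truth differ")
        truth <- truth[rownames(P), , drop = FALSE]
    }
    if (!is.null(colnames(P)) && !is.null(colnames(truth))) {
        if (!setequal(colnames(P), colnames(truth)))
            stop("cell-type sets of prediction and truth differ")
        truth <- truth[, colnames(P), drop = FALSE]
    }
    stopifnot(all(dim(P) == dim(truth)))
    perType <- vapply(seq_len(ncol(P)), function(k) {
        x <- truth[, k]; y <- P[, k]
        if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
            NA_real_
        else stats::cor(x, y)
    }, numeric(1))
    overall <- if (stats::sd(as.numeric(truth)) == 0 ||
                   stats::sd(as.numeric(P)) == 0) NA_real_
               else stats::cor(as.numeric(P), as.numeric(truth))
    list(perType = data.frame(cell_type = colnames(P), pearson = perType,
                              row.names = NULL),
         r = overall,
         mse = mean((P - truth)^2),
         mad = mean(abs(P - truth)))
}
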