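# Adversarial deconfounding autoencoder: an encoder/decoder pair trained to
# reconstruct log-normalised expression while a co-trained adversary tries to
# predict nuisance labels (batch/study/tissue) from the latent code. The
# joint objective is  min  E||x - g(f(x))||^2 - lambda * L(h(f(x)), c),
# alternated with one adversary epoch minimising L.

# normalise the confounder argument to a named list of factors
asConfounderList <- function(labels) {
    if (is.data.frame(labels) || is(labels, "DataFrame"))
        labels <- as.list(as.data.frame(labels))
    if (!is.list(labels)) labels <- list(confounder = labels)
    if (is.null(names(labels)) || any(names(labels) == ""))
        names(labels) <- paste0("confounder", seq_along(labels))
    lapply(labels, function(v) if (is.factor(v)) v else factor(v))
}

# expression input for the networks: accepts genes x cells (panel order
# enforced) and returns cells x genes
asNetworkInput <- function(model, x, what = "expression") {
    x <- as.matrix(x)
    if (is.null(rownames(x)))
        stop(what, " matrix must carry gene rownames")
    if (!identical(rownames(x), model@panelGenes)) {
        missing <- setdiff(model@panelGenes, rownames(x))
        if (length(missing))
            stop(length(missing), " panel gene(s) missing from the ", what,
                 " matrix, e.g. ", paste(utils::head(missing, 3), collapse = ", "))
        stop(what, " genes are not in panel order; reorder rows to match panelGenes(model)")
    }
    t(x)
}

labelIndices <- function(model, labels) {
    labs <- asConfounderList(labels)
    if (length(labs) != length(model@adversaries))
        stop("model expects ", length(model@adversaries), " confounder(s), got ",
             length(labs))
    lapply(seq_along(labs), function(i) {
        lev <- model@confounderLevels[[i]]
        v <- as.character(labs[[i]])
        unseen <- setdiff(unique(v), lev)
        if (length(unseen))
            stop("unseen confounder class(es): ", paste(unseen, collapse = ", "))
        match(v, lev)
    })
}

#' Initialise an adversarial deconfounding autoencoder
#'
#' Builds an untrained model: encoder |panel| -> hidden -> latent (ReLU
#' hidden layers, linear latent), mirrored decoder, and one adversary
#' (latent -> advHidden -> classes, softmax via the loss) per confounder.
#'
#' @param panelGenes ordered gene identifiers the encoder will expect.
#' @param confounders factor (or named list / data.frame of factors) of
#'   per-cell nuisance labels; only the class levels are used here.
#' @param latentDim latent dimensionality (reference default 100).
#' @param hidden encoder hidden-layer widths (decoder mirrors them).
#' @param advHidden adversary hidden width.
#' @param seed seed for weight initialisation.
#' @return an [AAEModel-class].
#' @export
aaeModel <- function(panelGenes, confounders, latentDim = 100L,
                     hidden = c(512, 256), advHidden = 64L, seed = 1) {
    labs <- asConfounderList(confounders)
    levs <- lapply(labs, levels)
    set.seed(seed)
    G <- length(panelGenes)
    encSizes <- c(G, hidden, latentDim)
    enc <- mlpInit(encSizes, c(rep("relu", length(hidden)), "linear"))
    dec <- mlpInit(rev(encSizes), c(rep("relu", length(hidden)), "linear"))
    advs <- lapply(levs, function(lv)
        mlpInit(c(latentDim, advHidden, length(lv)), c("relu", "linear")))
    names(advs) <- names(labs)
    new("AAEModel", encoder = enc, decoder = dec, adversaries = advs,
        panelGenes = as.character(panelGenes), latentDim = as.integer(latentDim),
        confounderLevels = levs,
        history = data.frame(phase = character(), epoch = integer(),
                             reconstruction = numeric(), adversary = numeric()),
        config = list(hidden = hidden, advHidden = advHidden, seed = seed))
}

#' Encode expression profiles into the latent space
#'
#' Deterministic at inference: the same trained encoder maps reference cells
#' and bulk samples, so identical expression vectors get identical latents.
#'
#' @param model a trained (or untrained) [AAEModel-class].
#' @param x genes x cells (or genes x samples) matrix in panel gene order.
#' @return a [LatentEmbedding-class], one row per column of \code{x}.
#' @export
encodeCells <- function(model, x) {
    inp <- asNetworkInput(model, x)
    z <- mlpForward(model@encoder, inp)$out
    rownames(z) <- colnames(x)
    LatentEmbedding(z)
}

#' @describeIn encodeCells embed bulk samples with the trained encoder; the
#'   bulk matrix must be normalised like the reference and contain every
#'   panel gene (missing genes are an error, never zero-filled).
#' @param bulkLog log-normalised genes x samples matrix over the panel.
#' @export
embedBulk <- function(model, bulkLog) {
    inp <- asNetworkInput(model, bulkLog, what = "bulk")
    z <- mlpForward(model@encoder, inp)$out
    rownames(z) <- colnames(bulkLog)
    LatentEmbedding(z)
}

#' Mean squared reconstruction error
#'
#' Mean over cells of the squared 2-norm between input and reconstruction,
#' \eqn{E\|x - g_\varphi(f_\Phi(x))\|_2^2}.
#'
#' @param model an [AAEModel-class].
#' @param x genes x cells matrix in panel order.
#' @return non-negative scalar.
#' @export
reconstructionLoss <- function(model, x) {
    inp <- asNetworkInput(model, x)
    z <- mlpForward(model@encoder, inp)$out
    xhat <- mlpForward(model@decoder, z)$out
    mean(rowSums((inp - xhat)^2))
}

#' Mean adversary cross-entropy on given latents
#'
#' @param model an [AAEModel-class].
#' @param latents a [LatentEmbedding-class] (or matrix, rows = cells).
#' @param labels confounder labels aligned with latent rows; unseen classes
#'   are an error.
#' @return non-negative scalar (summed over confounders when several).
#' @export
adversaryLoss <- function(model, latents, labels) {
    z <- if (is(latents, "LatentEmbedding")) latentCoords(latents) else as.matrix(latents)
    idx <- labelIndices(model, labels)
    total <- 0
    for (i in seq_along(model@adversaries)) {
        logits <- mlpForward(model@adversaries[[i]], z)$out
        total <- total + crossEntropy(logits, idx[[i]])
    }
    total
}

#' @describeIn adversaryLoss per-confounder classification accuracy of the
#'   adversary on given latents and labels.
#' @export
adversaryAccuracy <- function(model, latents, labels) {
    z <- if (is(latents, "LatentEmbedding")) latentCoords(latents) else as.matrix(latents)
    idx <- labelIndices(model, labels)
    vapply(seq_along(model@adversaries), function(i) {
        logits <- mlpForward(model@adversaries[[i]], z)$out
        mean(max.col(logits, ties.method = "first") == idx[[i]])
    }, numeric(1))
}

appendHistory <- function(model, phase, epoch, recon, adv) {
    model@history <- rbind(model@history,
                           data.frame(phase = phase, epoch = epoch,
                                      reconstruction = recon, adversary = adv))
    model
}

batchIndices <- function(n, batchSize) {
    perm <- sample.int(n)
    split(perm, ceiling(seq_along(perm) / batchSize))
}

#' Pre-train the autoencoder (reconstruction only)
#'
#' Minibatch Adam on the mean squared reconstruction loss. Zero epochs
#' return the model unchanged. A non-finite loss aborts with a diagnostic.
#'
#' @param model an [AAEModel-class].
#' @param x genes x cells log-normalised matrix in panel order.
#' @param epochs number of passes (reference default 50).
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param seed seed for minibatch shuffling.
#' @return the updated model, history appended (one row per epoch).
#' @export
pretrainAutoencoder <- function(model, x, epochs = 50, batchSize = 128,
                                lr = 1e-3, seed = 1) {
    if (epochs == 0) return(model)
    inp <- asNetworkInput(model, x)
    set.seed(seed)
    encState <- adamInit(model@encoder)
    decState <- adamInit(model@decoder)
    for (ep in seq_len(epochs)) {
        tot <- 0
        for (idx in batchIndices(nrow(inp), batchSize)) {
            xb <- inp[idx, , drop = FALSE]
            fe <- mlpForward(model@encoder, xb)
            fd <- mlpForward(model@decoder, fe$out)
            diff <- fd$out - xb
            loss <- mean(rowSums(diff^2))
            if (!is.finite(loss))
                stop("non-finite reconstruction loss at epoch ", ep,
                     "; lower the learning rate")
            # gradients use the element-mean reconstruction error so the
            # lambda * cross-entropy term is on a comparable scale
            dXhat <- 2 * diff / length(xb)
            bd <- mlpBackward(model@decoder, fd$cache, dXhat)
            be <- mlpBackward(model@encoder, fe$cache, bd$dInput)
            up <- adamStep(model@decoder, bd$grads, decState, lr)
            model@decoder <- up$net; decState <- up$state
            up <- adamStep(model@encoder, be$grads, encState, lr)
            model@encoder <- up$net; encState <- up$state
            tot <- tot + loss * nrow(xb)
        }
        model <- appendHistory(model, "ae_pretrain", ep, tot / nrow(inp), NA_real_)
    }
    model
}

#' Pre-train the adversary on frozen-encoder latents
#'
#' @inheritParams pretrainAutoencoder
#' @param labels confounder labels per cell (factor, or list/data.frame with
#'   one element per adversary). Single-class labels are an error:
#'   adversarial training is undefined without class contrast.
#' @param epochs reference default 20.
#' @return the updated model.
#' @export
pretrainAdversary <- function(model, x, labels, epochs = 20, batchSize = 128,
                              lr = 1e-3, seed = 1) {
    idx <- labelIndices(model, labels)
    for (i in seq_along(idx))
        if (length(unique(idx[[i]])) < 2)
            stop("confounder ", i, " has a single class; adversarial training undefined")
    if (epochs == 0) return(model)
    inp <- asNetworkInput(model, x)
    z <- mlpForward(model@encoder, inp)$out
    set.seed(seed)
    states <- lapply(model@adversaries, adamInit)
    for (ep in seq_len(epochs)) {
        tot <- 0
        for (bi in batchIndices(nrow(z), batchSize)) {
            zb <- z[bi, , drop = FALSE]
            for (i in seq_along(model@adversaries)) {
                fa <- mlpForward(model@adversaries[[i]], zb)
                loss <- crossEntropy(fa$out, idx[[i]][bi])
                if (!is.finite(loss)) stop("non-finite adversary loss")
                ba <- mlpBackward(model@adversaries[[i]], fa$cache,
                                  crossEntropyGrad(fa$out, idx[[i]][bi]))
                up <- adamStep(model@adversaries[[i]], ba$grads, states[[i]], lr)
                model@adversaries[[i]] <- up$net; states[[i]] <- up$state
                tot <- tot + loss * length(bi)
            }
        }
        model <- appendHistory(model, "adv_pretrain", ep, NA_real_,
                               tot / (nrow(z) * length(model@adversaries)))
    }
    model
}

#' Alternating joint adversarial training
#'
#' Each round alternates (a) one epoch updating encoder and decoder to
#' minimise reconstruction minus \eqn{\lambda} times the adversary loss
#' (adversary frozen, its gradient flowing back through the latent code) and
#' (b) one epoch updating the adversary on the current latents (autoencoder
#' frozen). \code{lambda = 0} reduces phase (a) to plain autoencoder
#' training. Zero rounds return the model unchanged.
#'
#' @inheritParams pretrainAdversary
#' @param rounds alternation rounds (reference default 30).
#' @param lambda adversarial weight (reference value 1).
#' @return the updated model; history gains one row per round with the
#'   end-of-round reconstruction and adversary losses.
#' @export
jointAdversarialTrain <- function(model, x, labels, rounds = 30, lambda = 1,
                                  batchSize = 128, lr = 1e-3, seed = 1) {
    stopifnot(lambda >= 0)
    idx <- labelIndices(model, labels)
    if (rounds == 0) return(model)
    inp <- asNetworkInput(model, x)
    set.seed(seed)
    encState <- adamInit(model@encoder)
    decState <- adamInit(model@decoder)
    advStates <- lapply(model@adversaries, adamInit)
    for (rd in seq_len(rounds)) {
        # (a) autoencoder phase, adversary frozen
        for (bi in batchIndices(nrow(inp), batchSize)) {
            xb <- inp[bi, , drop = FALSE]
            fe <- mlpForward(model@encoder, xb)
            fd <- mlpForward(model@decoder, fe$out)
            diff <- fd$out - xb
            recon <- mean(rowSums(diff^2))
            if (!is.finite(recon)) stop("joint training diverged (non-finite loss)")
            bd <- mlpBackward(model@decoder, fd$cache, 2 * diff / length(xb))
            dZ <- bd$dInput
            if (lambda > 0) {
                for (i in seq_along(model@adversaries)) {
                    fa <- mlpForward(model@adversaries[[i]], fe$out)
                    ba <- mlpBackward(model@adversaries[[i]], fa$cache,
                                      crossEntropyGrad(fa$out, idx[[i]][bi]))
                    dZ <- dZ - lambda * ba$dInput   # maximise adversary loss
                }
            }
            be <- mlpBackward(model@encoder, fe$cache, dZ)
            up <- adamStep(model@decoder, bd$grads, decState, lr)
            model@decoder <- up$net; decState <- up$state
            up <- adamStep(model@encoder, be$grads, encState, lr)
            model@encoder <- up$net; encState <- up$state
        }
        # (b) adversary epoch, autoencoder frozen
        z <- mlpForward(model@encoder, inp)$out
        for (bi in batchIndices(nrow(z), batchSize)) {
            zb <- z[bi, , drop = FALSE]
            for (i in seq_along(model@adversaries)) {
                fa <- mlpForward(model@adversaries[[i]], zb)
                ba <- mlpBackward(model@adversaries[[i]], fa$cache,
                                  crossEntropyGrad(fa$out, idx[[i]][bi]))
                up <- adamStep(model@adversaries[[i]], ba$grads, advStates[[i]], lr)
                model@adversaries[[i]] <- up$net; advStates[[i]] <- up$state
            }
        }
        recon <- reconstructionLoss(model, x)
        adv <- adversaryLoss(model, encodeCells(model, x), labels)
        if (!is.finite(recon) || !is.finite(adv))
            stop("joint training diverged (non-finite loss) at round ", rd)
        model <- appendHistory(model, "joint", rd, recon, adv)
    }
    model
}

#' Full three-step training schedule
#'
#' Convenience wrapper: initialise, pre-train the autoencoder, pre-train the
#' adversary, then alternate joint adversarial training. All stage seeds are
#' derived from the single \code{seed}.
#'
#' @param logcounts genes x cells log-normalised (and imputed) matrix,
#'   restricted to the gene panel.
#' @param confounders per-cell nuisance labels (factor or list of factors).
#' @param latentDim,hidden,advHidden architecture, see [aaeModel()].
#' @param lambda adversarial weight (reference value 1).
#' @param aeEpochs,advEpochs,jointRounds schedule lengths (reference
#'   defaults 50/20/30).
#' @param batchSize,lr optimiser settings.
#' @param seed master seed.
#' @return a trained [AAEModel-class].
#' @export
trainAAE <- function(logcounts, confounders, latentDim = 100L,
                     hidden = c(512, 256), advHidden = 64L, lambda = 1,
                     aeEpochs = 50, advEpochs = 20, jointRounds = 30,
                     batchSize = 128, lr = 1e-3, seed = 1) {
    model <- aaeModel(rownames(logcounts), confounders, latentDim, hidden,
                      advHidden, seed = seed)
    model <- pretrainAutoencoder(model, logcounts, aeEpochs, batchSize, lr,
                                 seed = seed + 1L)
    model <- pretrainAdversary(model, logcounts, confounders, advEpochs,
                               batchSize, lr, seed = seed + 2L)
    model <- jointAdversarialTrain(model, logcounts, confounders, jointRounds,
                                   lambda, batchSize, lr, seed = seed + 3L)
    model@config <- c(model@config,
                      list(lambda = lambda, aeEpochs = aeEpochs,
                           advEpochs = advEpochs, jointRounds = jointRounds,
                           batchSize = batchSize, lr = lr))
    model
}
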