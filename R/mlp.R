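# Minimal dense-network machinery for the adversarial autoencoder.
# Layers are lists (W: in x out, b: length out, act: "relu" | "linear").
# All matrices are row-major samples: x is n x features.

mlpInit <- function(sizes, acts) {
    stopifnot(length(acts) == length(sizes) - 1)
    lapply(seq_along(acts), function(i) {
        fanIn <- sizes[i]
        # He initialisation for ReLU layers, Glorot-ish for linear
        sd <- if (acts[i] == "relu") sqrt(2 / fanIn) else sqrt(1 / fanIn)
        list(W = matrix(stats::rnorm(fanIn * sizes[i + 1], 0, sd),
                        fanIn, sizes[i + 1]),
             b = numeric(sizes[i + 1]),
             act = acts[i])
    })
}

mlpForward <- function(net, x) {
    cache <- vector("list", length(net))
    h <- x
    for (i in seq_along(net)) {
        z <- h %*% net[[i]]$W
        z <- sweep(z, 2, net[[i]]$b, "+")
        a <- if (net[[i]]$act == "relu") pmax(z, 0) else z
        cache[[i]] <- list(input = h, z = z)
        h <- a
    }
    list(out = h, cache = cache)
}

# dOut: gradient of the loss wrt the network output (n x out).
# Returns per-layer grads and the gradient wrt the network input.
mlpBackward <- function(net, cache, dOut) {
    grads <- vector("list", length(net))
    d <- dOut
    for (i in rev(seq_along(net))) {
        if (net[[i]]$act == "relu") d <- d * (cache[[i]]$z > 0)
        grads[[i]] <- list(W = crossprod(cache[[i]]$input, d), b = colSums(d))
        d <- tcrossprod(d, net[[i]]$W)
    }
    list(grads = grads, dInput = d)
}

adamInit <- function(net) {
    lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                 mb = l$b * 0, vb = l$b * 0, t = 0))
}

adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    for (i in seq_along(net)) {
        s <- state[[i]]
        s$t <- s$t + 1
        s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$W
        s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$W^2
        s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$b
        s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$b^2
        c1 <- 1 - beta1^s$t; c2 <- 1 - beta2^s$t
        net[[i]]$W <- net[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
        net[[i]]$b <- net[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
        state[[i]] <- s
    }
    list(net = net, state = state)
}

softmaxRows <- function(z) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
}

# mean categorical cross-entropy; y is an integer class index per row
crossEntropy <- function(logits, y) {
    p <- softmaxRows(logits)
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)))
}

# gradient of mean CE wrt logits
crossEntropyGrad <- function(logits, y) {
    p <- softmaxRows(logits)
    p[cbind(seq_len(nrow(p)), y)] <- p[cbind(seq_len(nrow(p)), y)] - 1
    p / nrow(p)
}
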