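## Minimal convolutional-network engine: forward passes cache what the
## hand-derived backward passes need, gradients accumulate into an
## environment keyed by layer id, and Adam updates walk the layer list.
## Image tensors are column-major arrays dim (H, W, C); conv weights are
## (k*k*Cin) x Cout matrices matching the im2col column order.

IN_EPS <- 1e-5

mkConv <- function(id, k, cin, cout, stride = 1L, pad = 0L,
                   padMode = c("zero", "reflect")) {
    list(type = "conv", id = id, k = as.integer(k), cin = cin, cout = cout,
         stride = as.integer(stride), pad = as.integer(pad),
         padMode = match.arg(padMode),
         W = matrix(0, k * k * cin, cout), b = numeric(cout))
}

## Transposed conv (stride-2 upsampling): weight shaped as the conv it is the
## adjoint of, i.e. (k*k*cout) x cin with cout the (larger) output width.
mkTConv <- function(id, k, cin, cout, stride = 2L, pad = 1L) {
    list(type = "tconv", id = id, k = as.integer(k), cin = cin, cout = cout,
         stride = as.integer(stride), pad = as.integer(pad),
         W = matrix(0, k * k * cout, cin), b = numeric(cout))
}

mkIN <- function(id, ch)
    list(type = "instnorm", id = id, ch = ch, gamma = rep(1, ch),
         beta = rep(0, ch))

mkAct <- function(id, kind) list(type = kind, id = id)

mkRes <- function(id, ch) {
    list(type = "res", id = id,
         conv1 = mkConv(paste0(id, ".c1"), 3, ch, ch, 1, 1, "reflect"),
         in1 = mkIN(paste0(id, ".n1"), ch),
         conv2 = mkConv(paste0(id, ".c2"), 3, ch, ch, 1, 1, "reflect"),
         in2 = mkIN(paste0(id, ".n2"), ch))
}

## Reflective padding (edge not repeated) and its adjoint.
padIdx <- function(n, p) c(rev(seq_len(p) + 1L), seq_len(n),
                           rev(seq(n - p, n - 1L)))

reflectPad <- function(x, p) {
    d <- dim(x)
    x[padIdx(d[1], p), padIdx(d[2], p), , drop = FALSE]
}

reflectPadBackward <- function(gxp, p, d) {
    H <- d[1]; W <- d[2]
    gh <- gxp[p + seq_len(H), , , drop = FALSE]  # core rows
    for (i in seq_len(p)) {
        gh[i + 1L, , ] <- gh[i + 1L, , ] + gxp[p + 1L - i, , ]
        gh[H - i, , ] <- gh[H - i, , ] + gxp[H + p + i, , ]
    }
    gx <- gh[, p + seq_len(W), , drop = FALSE]
    for (j in seq_len(p)) {
        gx[, j + 1L, ] <- gx[, j + 1L, ] + gh[, p + 1L - j, ]
        gx[, W - j, ] <- gx[, W - j, ] + gh[, W + p + j, ]
    }
    gx
}

convOutSize <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

convForward <- function(l, x) {
    d <- dim(x)
    if (l$padMode == "reflect" && l$pad > 0L) {
        xp <- reflectPad(x, l$pad); pad <- 0L
    } else {
        xp <- x; pad <- l$pad
    }
    dp <- dim(xp)
    cols <- cpp_im2col(xp, dp[1], dp[2], dp[3], l$k, l$stride, pad)
    y <- cols %*% l$W
    y <- y + rep(l$b, each = nrow(y))
    ho <- convOutSize(dp[1], l$k, l$stride, pad)
    wo <- convOutSize(dp[2], l$k, l$stride, pad)
    dim(y) <- c(ho, wo, l$cout)
    list(y = y, cache = list(cols = cols, dimIn = d, dimPad = dp, pad = pad))
}

convBackward <- function(l, cache, gy) {
    gm <- matrix(gy, ncol = l$cout)
    gW <- crossprod(cache$cols, gm)
    gb <- colSums(gm)
    gcols <- tcrossprod(gm, l$W)
    dp <- cache$dimPad
    gxp <- cpp_col2im(gcols, dp[1], dp[2], dp[3], l$k, l$stride, cache$pad)
    gx <- if (l$padMode == "reflect" && l$pad > 0L)
        reflectPadBackward(gxp, l$pad, cache$dimIn) else gxp
    list(gx = gx, grads = list(W = gW, b = gb))
}

tconvForward <- function(l, x) {
    d <- dim(x)
    xm <- matrix(x, ncol = l$cin)
    cols <- tcrossprod(xm, l$W)
    hb <- d[1] * l$stride; wb <- d[2] * l$stride
    y <- cpp_col2im(cols, hb, wb, l$cout, l$k, l$stride, l$pad)
    ym <- matrix(y, ncol = l$cout)
    ym <- ym + rep(l$b, each = nrow(ym))
    dim(ym) <- c(hb, wb, l$cout)
    list(y = ym, cache = list(xm = xm, dimIn = d, dimOut = c(hb, wb, l$cout)))
}

tconvBackward <- function(l, cache, gy) {
    do <- cache$dimOut
    gcols <- cpp_im2col(gy, do[1], do[2], do[3], l$k, l$stride, l$pad)
    gx <- gcols %*% l$W
    gW <- crossprod(gcols, cache$xm)
    gb <- colSums(matrix(gy, ncol = l$cout))
    dim(gx) <- cache$dimIn
    list(gx = gx, grads = list(W = gW, b = gb))
}

inForward <- function(l, x) {
    d <- dim(x)
    xm <- matrix(x, ncol = d[3])
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = nrow(xm))
    istd <- 1 / sqrt(colMeans(xc * xc) + IN_EPS)
    xhat <- xc * rep(istd, each = nrow(xm))
    y <- xhat * rep(l$gamma, each = nrow(xm)) +
        rep(l$beta, each = nrow(xm))
    dim(y) <- d
    list(y = y, cache = list(xhat = xhat, istd = istd, d = d))
}

inBackward <- function(l, cache, gy) {
    d <- cache$d; n <- d[1] * d[2]
    gm <- matrix(gy, ncol = d[3])
    ggamma <- colSums(gm * cache$xhat)
    gbeta <- colSums(gm)
    gxhat <- gm * rep(l$gamma, each = n)
    m1 <- colMeans(gxhat)
    m2 <- colMeans(gxhat * cache$xhat)
    gx <- (gxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
        rep(cache$istd, each = n)
    dim(gx) <- d
    list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

actForward <- function(l, x) {
    y <- switch(l$type,
        relu = pmax(x, 0),
        lrelu = pmax(x, 0) + 0.2 * pmin(x, 0),
        tanh = tanh(x))
    list(y = y, cache = if (l$type == "tanh") y else x)
}

actBackward <- function(l, cache, gy) {
    gx <- switch(l$type,
        relu = gy * (cache > 0),
        lrelu = gy * (0.2 + 0.8 * (cache > 0)),
        tanh = gy * (1 - cache * cache))
    list(gx = gx, grads = NULL)
}

layerForward <- function(l, x) {
    switch(l$type,
        conv = convForward(l, x),
        tconv = tconvForward(l, x),
        instnorm = inForward(l, x),
        relu = , lrelu = , tanh = actForward(l, x),
        softmax = {
            y <- channelSoftmax(x)
            list(y = y, cache = y)
        },
        res = {
            f1 <- convForward(l$conv1, x)
            f2 <- inForward(l$in1, f1$y)
            f3 <- actForward(list(type = "relu"), f2$y)
            f4 <- convForward(l$conv2, f3$y)
            f5 <- inForward(l$in2, f4$y)
            list(y = x + f5$y, cache = list(f1$cache, f2$cache, f3$cache,
                                            f4$cache, f5$cache))
        },
        stop("unknown layer type ", l$type))
}

addGrad <- function(gacc, id, grads) {
    if (is.null(grads) || is.null(gacc)) return(invisible())
    for (nm in names(grads)) {
        key <- paste0(id, ".", nm)
        cur <- gacc[[key]]
        gacc[[key]] <- if (is.null(cur)) grads[[nm]] else cur + grads[[nm]]
    }
    invisible()
}

layerBackward <- function(l, cache, gy, gacc) {
    if (l$type == "res") {
        b5 <- inBackward(l$in2, cache[[5]], gy)
        addGrad(gacc, l$in2$id, b5$grads)
        b4 <- convBackward(l$conv2, cache[[4]], b5$gx)
        addGrad(gacc, l$conv2$id, b4$grads)
        b3 <- actBackward(list(type = "relu"), cache[[3]], b4$gx)
        b2 <- inBackward(l$in1, cache[[2]], b3$gx)
        addGrad(gacc, l$in1$id, b2$grads)
        b1 <- convBackward(l$conv1, cache[[1]], b2$gx)
        addGrad(gacc, l$conv1$id, b1$grads)
        return(gy + b1$gx)  # skip connection
    }
    r <- switch(l$type,
        conv = convBackward(l, cache, gy),
        tconv = tconvBackward(l, cache, gy),
        instnorm = inBackward(l, cache, gy),
        relu = , lrelu = , tanh = actBackward(l, cache, gy),
        softmax = {
            y <- cache
            d <- dim(y)
            s <- rowSums(matrix(y * gy, ncol = d[3]))
            list(gx = y * (gy - array(s, d)), grads = NULL)
        })
    addGrad(gacc, l$id, r$grads)
    r$gx
}

seqForward <- function(layers, x) {
    caches <- vector("list", length(layers))
    for (i in seq_along(layers)) {
        f <- layerForward(layers[[i]], x)
        x <- f$y
        caches[[i]] <- f$cache
    }
    list(y = x, caches = caches)
}

seqBackward <- function(layers, caches, gy, gacc) {
    for (i in rev(seq_along(layers)))
        gy <- layerBackward(layers[[i]], caches[[i]], gy, gacc)
    gy
}

## Seeded zero-mean Gaussian weight init (scale 0.02), the convention of the
## pix2pix/cycleGAN family; instance-norm gain 1, bias 0.
initLayers <- function(layers, sd = 0.02) {
    lapply(layers, function(l) {
        if (l$type == "res") {
            l$conv1$W[] <- rnorm(length(l$conv1$W), 0, sd)
            l$conv2$W[] <- rnorm(length(l$conv2$W), 0, sd)
        } else if (!is.null(l$W)) {
            l$W[] <- rnorm(length(l$W), 0, sd)
        }
        l
    })
}

## Walk layers, apply Adam using gradients in gacc. state is an environment
## holding first/second moments per parameter key plus the step counter t.
adamStep <- function(layers, gacc, state, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
    t <- state$t
    upd <- function(obj, id, nm) {
        key <- paste0(id, ".", nm)
        g <- gacc[[key]]
        if (is.null(g)) return(obj)
        dim(g) <- dim(obj[[nm]])
        mkey <- paste0(key, ".m"); vkey <- paste0(key, ".v")
        m <- state[[mkey]]; v <- state[[vkey]]
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        state[[mkey]] <- m; state[[vkey]] <- v
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        obj[[nm]] <- obj[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        obj
    }
    lapply(layers, function(l) {
        if (l$type == "res") {
            for (part in c("conv1", "conv2"))
                for (nm in c("W", "b"))
                    l[[part]] <- upd(l[[part]], l[[part]]$id, nm)
            for (part in c("in1", "in2"))
                for (nm in c("gamma", "beta"))
                    l[[part]] <- upd(l[[part]], l[[part]]$id, nm)
        } else if (l$type %in% c("conv", "tconv")) {
            l <- upd(l, l$id, "W"); l <- upd(l, l$id, "b")
        } else if (l$type == "instnorm") {
            l <- upd(l, l$id, "gamma"); l <- upd(l, l$id, "beta")
        }
        l
    })
}

newAdamState <- function() {
    e <- new.env(parent = emptyenv())
    e$t <- 0L
    e
}

newGradAcc <- function() new.env(parent = emptyenv())

## Deterministic hash of all parameters (used to assert that discriminator
## updates never touch generator weights and vice versa).
paramChecksum <- function(layers) {
    s <- 0
    walk <- function(l) {
        for (nm in c("W", "b", "gamma", "beta"))
            if (!is.null(l[[nm]])) s <<- s + sum(l[[nm]] * seq_along(l[[nm]]))
        if (l$type == "res")
            for (part in c("conv1", "in1", "conv2", "in2")) walk(l[[part]])
    }
    for (l in layers) walk(l)
    s
}
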