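#' Generator configuration
#'
#' Describes the attention-guided generator: a shared downsampling encoder
#' (7x7 stride-1 stem, two 3x3 stride-2 convolutions, residual blocks at the
#' encoder output width), and two independent upsampling branches — a content
#' branch ending in a 7x7 convolution with \code{nMasks - 1} channels squashed
#' by tanh, and an attention branch ending in a 1x1 convolution with
#' \code{nMasks} channels through a channel softmax. With
#' \code{attention = FALSE} the generator emits a single tanh content image
#' directly (the cycleGAN-style baseline, which isolates the attention
#' mechanism as the only difference between modes).
#'
#' @param nMasks number of attention masks n (default 10; content masks are
#'   n - 1). Must be >= 2.
#' @param encoderChannels integer(3) channel plan of the encoder
#'   (default 64, 128, 256); decoder branches mirror the first two in reverse.
#' @param nResBlocks residual blocks at the bottleneck (default 9).
#' @param attention build the attention branch (default TRUE).
#' @param backgroundBias initial logit bias of the background attention
#'   channel (default 3). A freshly initialized generator then starts close
#'   to the identity map (background weight about 0.7 instead of 1/n), so
#'   training spends its budget on learning corrections rather than on
#'   rediscovering the input; the objective itself is unchanged.
#' @return a \code{generatorConfig} list.
#' @export
generatorConfig <- function(nMasks = 10L, encoderChannels = c(64L, 128L, 256L),
                            nResBlocks = 9L, attention = TRUE,
                            backgroundBias = 3) {
    stopifnot(nMasks >= 2L, length(encoderChannels) == 3L,
              all(encoderChannels >= 1L), nResBlocks >= 0L)
    structure(list(nMasks = as.integer(nMasks),
                   encoderChannels = as.integer(encoderChannels),
                   nResBlocks = as.integer(nResBlocks),
                   attention = isTRUE(attention),
                   backgroundBias = backgroundBias,
                   contentChannels = if (attention) nMasks - 1L else 1L,
                   attentionChannels = as.integer(nMasks)),
              class = "generatorConfig")
}

#' Discriminator configuration (patch-based, pix2pix style)
#'
#' A fully convolutional stack of 4x4 convolutions: \code{nLayers} stride-2
#' layers with doubling channel width, one stride-1 layer, and a final
#' stride-1 projection to one score channel. No normalization on the first
#' layer; leaky-ReLU slope 0.2 throughout; no global pooling — the output is
#' a patch score map. The default (base 64, 3 stride-2 layers) has the
#' classic 70x70 receptive field.
#'
#' @param baseChannels first-layer width (default 64).
#' @param nLayers number of stride-2 layers (default 3).
#' @return a \code{discriminatorConfig} list.
#' @export
discriminatorConfig <- function(baseChannels = 64L, nLayers = 3L) {
    stopifnot(baseChannels >= 1L, nLayers >= 1L)
    structure(list(baseChannels = as.integer(baseChannels),
                   nLayers = as.integer(nLayers)),
              class = "discriminatorConfig")
}

#' Channel-wise softmax producing attention masks
#'
#' Per pixel, channel i receives exp(A_i) / sum_c exp(A_c). Numerically
#' stabilized by subtracting the per-pixel maximum, so arbitrarily large
#' finite logits cannot overflow.
#'
#' @param logits 3D array (H, W, n) of finite values.
#' @return array of the same shape: non-negative, channels summing to 1.
#' @examples
#' a <- channelSoftmax(array(0, c(2, 2, 10)))
#' a[1, 1, ]  # uniform 0.1
#' @export
channelSoftmax <- function(logits) {
    d <- dim(logits)
    stopifnot(length(d) == 3L, all(is.finite(logits)))
    xm <- matrix(logits, ncol = d[3])
    mx <- xm[, 1]
    for (j in seq_len(d[3])[-1]) mx <- pmax(mx, xm[, j])
    e <- exp(xm - mx)
    p <- e / rowSums(e)
    dim(p) <- d
    p
}

#' Compose the generator output from masks and the input image
#'
#' out = sum_f content_f * attention_f + input * attention_background,
#' element-wise; the f-th content channel pairs with the f-th non-background
#' attention channel in order. Because the attention channels form a per-pixel
#' simplex and both content and input are bounded by [-1, 1], the output is a
#' convex combination of bounded terms and never leaves [-1, 1].
#'
#' @param masks a \linkS4class{MaskStack}.
#' @param input 2D matrix (or (H, W, 1) array) in [-1, 1], same spatial shape.
#' @return 2D matrix, the composed synthetic image.
#' @export
composeOutput <- function(masks, input) {
    stopifnot(is(masks, "MaskStack"))
    X <- if (length(dim(input)) == 3L) input[, , 1] else input
    da <- dim(masks@attention)
    if (!all(dim(X) == da[1:2])) stop("input/mask spatial shape mismatch")
    fg <- setdiff(seq_len(da[3]), masks@background)
    out <- X * masks@attention[, , masks@background]
    for (j in seq_along(fg))
        out <- out + masks@content[, , j] * masks@attention[, , fg[j]]
    out
}

## Backward of composeOutput: gradients for content, attention and input.
composeBackward <- function(masks, X, gout) {
    da <- dim(masks@attention)
    fg <- setdiff(seq_len(da[3]), masks@background)
    gc <- array(0, dim(masks@content))
    ga <- array(0, da)
    for (j in seq_along(fg)) {
        gc[, , j] <- gout * masks@attention[, , fg[j]]
        ga[, , fg[j]] <- gout * masks@content[, , j]
    }
    ga[, , masks@background] <- gout * X
    gx <- gout * masks@attention[, , masks@background]
    list(gcontent = gc, gattention = ga, gx = gx)
}

## Layer stacks -------------------------------------------------------------

buildEncoder <- function(cfg, prefix = "enc") {
    ch <- cfg$encoderChannels
    layers <- list(
        mkConv(paste0(prefix, 1), 7, 1, ch[1], 1, 3, "reflect"),
        mkIN(paste0(prefix, "1n"), ch[1]), mkAct("", "relu"),
        mkConv(paste0(prefix, 2), 3, ch[1], ch[2], 2, 1),
        mkIN(paste0(prefix, "2n"), ch[2]), mkAct("", "relu"),
        mkConv(paste0(prefix, 3), 3, ch[2], ch[3], 2, 1),
        mkIN(paste0(prefix, "3n"), ch[3]), mkAct("", "relu"))
    for (r in seq_len(cfg$nResBlocks))
        layers <- c(layers, list(mkRes(paste0(prefix, ".res", r), ch[3])))
    layers
}

buildBranch <- function(cfg, kind = c("content", "attention")) {
    kind <- match.arg(kind)
    ch <- cfg$encoderChannels
    p <- substr(kind, 1, 3)
    layers <- list(
        mkTConv(paste0(p, "up1"), 3, ch[3], ch[2]),
        mkIN(paste0(p, "up1n"), ch[2]), mkAct("", "relu"),
        mkTConv(paste0(p, "up2"), 3, ch[2], ch[1]),
        mkIN(paste0(p, "up2n"), ch[1]), mkAct("", "relu"))
    if (kind == "content")
        c(layers, list(mkConv(paste0(p, "head"), 7, ch[1],
                              cfg$contentChannels, 1, 3, "reflect"),
                       mkAct("", "tanh")))
    else
        c(layers, list(mkConv(paste0(p, "head"), 1, ch[1],
                              cfg$attentionChannels, 1, 0),
                       mkAct("", "softmax")))
}

#' Build an attention-guided generator with seeded Gaussian weights
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed for the N(0, 0.02^2) weight initialization.
#' @return a generator object (list of layer stacks).
#' @export
buildGenerator <- function(config = generatorConfig(), seed = 1L) {
    set.seed(seed)
    gen <- list(config = config,
                enc = initLayers(buildEncoder(config)),
                content = initLayers(buildBranch(config, "content")),
                attention = if (config$attention)
                    initLayers(buildBranch(config, "attention")) else NULL)
    if (config$attention && config$backgroundBias != 0) {
        ih <- length(gen$attention) - 1L  # attention head conv
        gen$attention[[ih]]$b[config$attentionChannels] <-
            config$backgroundBias
    }
    class(gen) <- "sctganGenerator"
    gen
}

#' Build a patch discriminator with seeded Gaussian weights
#'
#' @param config a \code{\link{discriminatorConfig}}.
#' @param seed RNG seed.
#' @return a discriminator object.
#' @export
buildDiscriminator <- function(config = discriminatorConfig(), seed = 1L) {
    set.seed(seed)
    b <- config$baseChannels
    layers <- list(mkConv("d1", 4, 1, b, 2, 1), mkAct("", "lrelu"))
    cin <- b
    for (i in seq_len(config$nLayers - 1L) + 1L) {
        cout <- b * min(2^(i - 1L), 8L)
        layers <- c(layers, list(mkConv(paste0("d", i), 4, cin, cout, 2, 1),
                                 mkIN(paste0("d", i, "n"), cout),
                                 mkAct("", "lrelu")))
        cin <- cout
    }
    cout <- b * min(2^config$nLayers, 8L)
    layers <- c(layers, list(
        mkConv("dpen", 4, cin, cout, 1, 1),
        mkIN("dpenn", cout), mkAct("", "lrelu"),
        mkConv("dout", 4, cout, 1, 1, 1)))
    disc <- list(config = config, layers = initLayers(layers))
    class(disc) <- "sctganDiscriminator"
    disc
}

## Internal generator forward/backward with tape ----------------------------

genForward <- function(gen, x) {
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    e <- seqForward(gen$enc, x)
    cf <- seqForward(gen$content, e$y)
    if (gen$config$attention) {
        af <- seqForward(gen$attention, e$y)
        masks <- maskStack(cf$y, af$y)
        out <- composeOutput(masks, x)
        tape <- list(enc = e$caches, content = cf$caches,
                     attention = af$caches, masks = masks, x = x[, , 1])
    } else {
        masks <- NULL
        out <- cf$y[, , 1]
        tape <- list(enc = e$caches, content = cf$caches, attention = NULL,
                     masks = NULL, x = x[, , 1])
    }
    list(out = out, masks = masks, tape = tape)
}

genBackward <- function(gen, tape, gout, gacc) {
    if (gen$config$attention) {
        cb <- composeBackward(tape$masks, tape$x, gout)
        gci <- seqBackward(gen$content, tape$content, cb$gcontent, gacc)
        gai <- seqBackward(gen$attention, tape$attention, cb$gattention, gacc)
        genc <- gci + gai
        gx0 <- cb$gx
    } else {
        g <- gout; dim(g) <- c(dim(gout), 1L)
        genc <- seqBackward(gen$content, tape$content, g, gacc)
        gx0 <- 0
    }
    gx <- seqBackward(gen$enc, tape$enc, genc, gacc)
    gx[, , 1] + gx0
}

#' Run the generator on one normalized slice
#'
#' @param gen a generator from \code{\link{buildGenerator}}.
#' @param image 2D matrix in [-1, 1] (any square size the stride plan
#'   divides; training uses 256 x 256).
#' @return list with \code{output} (2D matrix in [-1, 1]) and \code{masks}
#'   (a \linkS4class{MaskStack}, or NULL for a content-only generator).
#' @export
generatorForward <- function(gen, image) {
    f <- genForward(gen, image)
    list(output = f$out, masks = f$masks)
}

#' Run the patch discriminator on one normalized slice
#'
#' @param disc a discriminator from \code{\link{buildDiscriminator}}.
#' @param image 2D matrix in [-1, 1].
#' @return the patch score map as a 2D matrix (one score per
#'   receptive-field patch; no global pooling).
#' @export
discriminatorForward <- function(disc, image) {
    if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
    f <- seqForward(disc$layers, image)
    f$y[, , 1]
}

#' Mean patch score of a discriminator score map
#'
#' The scalar judgment for a whole image: the arithmetic mean over all
#' patch scores.
#'
#' @param scores 2D score map (or any non-empty numeric array).
#' @return scalar mean.
#' @export
patchMean <- function(scores) {
    if (length(scores) == 0L) stop("empty score map")
    mean(scores)
}

#' Force the background attention channel to one
#'
#' Sets the attention head to constant logits with an overwhelming background
#' channel, so the softmax yields exactly 1 for the background mask and 0 for
#' every foreground mask; the composition then reproduces the input
#' bit-exactly. Useful for identity-path diagnostics.
#'
#' @param gen an attention generator.
#' @return the modified generator.
#' @export
forceBackgroundAttention <- function(gen) {
    stopifnot(gen$config$attention)
    ih <- length(gen$attention) - 1L  # attention head conv
    gen$attention[[ih]]$W[] <- 0
    b <- numeric(gen$config$attentionChannels)
    b[gen$config$attentionChannels] <- 400  # exp(-400) underflows to 0
    gen$attention[[ih]]$b <- b
    gen
}

#' Analytic output size of the discriminator score map
#'
#' Chains the convolution arithmetic floor((n + 2p - k)/s) + 1 through the
#' configured stack.
#'
#' @param config a \code{\link{discriminatorConfig}}.
#' @param inputSize input side length.
#' @return integer side length of the score map.
#' @export
discriminatorOutputSize <- function(config, inputSize) {
    n <- inputSize
    for (i in seq_len(config$nLayers)) n <- (n + 2L - 4L) %/% 2L + 1L
    n <- (n + 2L - 4L) %/% 1L + 1L  # penultimate stride-1
    n <- (n + 2L - 4L) %/% 1L + 1L  # score projection
    as.integer(n)
}

#' Export a mask stack as NIfTI volumes for inspection
#'
#' Writes the content channels and the attention channels as two 3D NIfTI
#' files (channels along the third axis).
#'
#' @param masks a \linkS4class{MaskStack}.
#' @param pathPrefix output path prefix; \code{<prefix>_content.nii.gz} and
#'   \code{<prefix>_attention.nii.gz} are written.
#' @return the two paths, invisibly.
#' @export
writeMaskStack <- function(masks, pathPrefix) {
    stopifnot(is(masks, "MaskStack"))
    paths <- paste0(pathPrefix, c("_content.nii.gz", "_attention.nii.gz"))
    img1 <- RNifti::asNifti(masks@content)
    RNifti::writeNifti(img1, paths[1])
    img2 <- RNifti::asNifti(masks@attention)
    RNifti::writeNifti(img2, paths[2])
    invisible(paths)
}
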