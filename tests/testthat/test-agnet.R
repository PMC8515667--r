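test_that("channelSoftmax forms a per-pixel simplex with the closed form", {
    u <- channelSoftmax(array(0, c(2, 2, 10)))
    expect_equal(as.numeric(u), rep(0.1, 40))

    lg <- array(0, c(1, 1, 3))
    lg[1, 1, ] <- c(log(2), log(1), log(1))
    expect_equal(as.numeric(channelSoftmax(lg)), c(0.5, 0.25, 0.25))

    set.seed(2)
    x <- array(rnorm(100 * 100 * 7, sd = 5), c(100, 100, 7))
    p <- channelSoftmax(x)
    expect_true(all(p >= 0))
    expect_equal(as.numeric(apply(p, c(1, 2), sum)), rep(1, 1e4),
                 tolerance = 1e-12)
    # huge logits: stabilized, no overflow
    big <- channelSoftmax(array(c(700, 0, -700), c(1, 1, 3)))
    expect_true(all(is.finite(big)))
    expect_equal(sum(big), 1)
})

test_that("composeOutput matches a per-pixel brute-force oracle", {
    set.seed(3)
    for (rep in 1:25) {
        ms <- randomMaskStack(4, 4, 10)
        x <- matrix(runif(16, -1, 1), 4, 4)
        out <- composeOutput(ms, x)
        oracle <- matrix(0, 4, 4)
        for (i in 1:4) for (j in 1:4) {
            acc <- x[i, j] * ms@attention[i, j, 10]
            for (f in 1:9)
                acc <- acc + ms@content[i, j, f] * ms@attention[i, j, f]
            oracle[i, j] <- acc
        }
        expect_equal(out, oracle, tolerance = 1e-12)
        expect_true(all(abs(out) <= 1 + 1e-12))
    }
})

test_that("background attention of one reproduces the input bit-exactly", {
    set.seed(4)
    att <- array(0, c(5, 5, 10)); att[, , 10] <- 1
    ms <- maskStack(array(runif(5 * 5 * 9, -1, 1), c(5, 5, 9)), att)
    x <- matrix(runif(25, -1, 1), 5, 5)
    expect_identical(composeOutput(ms, x), x)
})

test_that("compose obeys the uniform-attention algebra", {
    n <- 10L
    att <- array(1 / n, c(3, 3, n))
    cont <- array(0.4, c(3, 3, n - 1L))
    x <- matrix(-0.2, 3, 3)
    out <- composeOutput(maskStack(cont, att), x)
    expect_equal(out, matrix(((n - 1) * 0.4 + (-0.2)) / n, 3, 3))
})

test_that("generator output is bounded, well-shaped and deterministic", {
    cfg <- generatorConfig(nMasks = 10L, encoderChannels = c(3L, 4L, 6L),
                           nResBlocks = 2L)
    gen <- buildGenerator(cfg, seed = 5L)
    x <- matrix(runif(32 * 32, -1, 1), 32, 32)
    r1 <- generatorForward(gen, x)
    expect_equal(dim(r1$output), dim(x))
    expect_equal(dim(attentionMasks(r1$masks))[3], 10L)
    expect_equal(dim(contentMasks(r1$masks))[3], 9L)
    expect_equal(backgroundIndex(r1$masks), 10L)
    expect_true(all(abs(r1$output) <= 1))
    r2 <- generatorForward(gen, x)
    expect_identical(r1$output, r2$output)  # repeated passes bit-identical
})

test_that("attention channels form a simplex for arbitrary random weights", {
    set.seed(6)
    x <- matrix(runif(16 * 16, -1, 1), 16, 16)
    for (s in 1:10) {
        gen <- buildGenerator(tinyGenConfig(nMasks = 10L), seed = s)
        r <- generatorForward(gen, x)
        a <- attentionMasks(r$masks)
        expect_true(all(a >= 0))
        expect_lt(max(abs(apply(a, c(1, 2), sum) - 1)), 1e-5)
        expect_true(all(abs(r$output) <= 1))
    }
})

test_that("forcing background attention makes the generator the identity", {
    gen <- forceBackgroundAttention(buildGenerator(tinyGenConfig(), seed = 8))
    x <- matrix(runif(16 * 16, -1, 1), 16, 16)
    r <- generatorForward(gen, x)
    expect_identical(r$output, x)
    expect_identical(attentionMasks(r$masks)[, , 4], matrix(1, 16, 16))
})

test_that("discriminator score map size follows the convolution arithmetic", {
    cfg <- tinyDiscConfig()
    disc <- buildDiscriminator(cfg, seed = 2)
    for (size in c(32L, 64L)) {
        s <- discriminatorForward(disc, matrix(0.1, size, size))
        expect_equal(nrow(s), discriminatorOutputSize(cfg, size))
        expect_equal(ncol(s), discriminatorOutputSize(cfg, size))
    }
    # analytic chain for the default 70x70-receptive-field stack
    expect_equal(discriminatorOutputSize(discriminatorConfig(), 256L), 30L)
})

test_that("patch scores shift with the input on interior patches", {
    # translation equivariance of the fully convolutional scoring stack
    # (instance normalization excluded: its whole-image statistics are not
    # translation invariant at borders)
    ns <- asNamespace("sctgan")
    set.seed(9)
    layers <- ns$initLayers(list(
        ns$mkConv("a", 4, 1, 3, 2, 1), ns$mkAct("", "lrelu"),
        ns$mkConv("b", 4, 3, 4, 2, 1), ns$mkAct("", "lrelu"),
        ns$mkConv("c", 4, 4, 1, 1, 1)))
    fwd <- function(img) {
        dim(img) <- c(dim(img), 1L)
        ns$seqForward(layers, img)$y[, , 1]
    }
    x <- matrix(runif(40 * 40, -1, 1), 40, 40)
    shift <- 4L  # one patch stride (2 x 2)
    xs <- matrix(0, 40, 40)
    xs[(shift + 1):40, ] <- x[1:(40 - shift), ]
    s0 <- fwd(x); s1 <- fwd(xs)
    n <- nrow(s0)
    # rows whose receptive field avoids both shift borders
    interior <- 4:(n - 2)
    expect_equal(s1[interior, ], s0[interior - 1L, ], tolerance = 1e-10)
})

test_that("constant-zero weights give a constant score map", {
    disc <- buildDiscriminator(tinyDiscConfig(), seed = 4)
    disc$layers <- lapply(disc$layers, function(l) {
        if (!is.null(l$W)) l$W[] <- 0
        l
    })
    s <- discriminatorForward(disc, matrix(runif(32 * 32, -1, 1), 32, 32))
    expect_equal(max(s) - min(s), 0)
})

test_that("patchMean reduces a score map to its arithmetic mean", {
    expect_equal(patchMean(matrix(0.7, 5, 5)), 0.7)
    expect_equal(patchMean(c(0, 1)), 0.5)
    set.seed(10)
    m <- matrix(rnorm(30), 5, 6)
    expect_equal(patchMean(m), sum(m) / length(m))
    expect_error(patchMean(numeric(0)), "empty")
})

test_that("mask stacks export to NIfTI channel volumes", {
    ms <- randomMaskStack(6, 6, 4)
    p <- writeMaskStack(ms, tempfile())
    expect_true(all(file.exists(p)))
    back <- RNifti::readNifti(p[2])
    expect_equal(array(as.vector(back), dim(back)), ms@attention,
                 tolerance = 1e-6)
})
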