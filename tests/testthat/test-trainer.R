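# Training uses deliberately tiny networks and datasets here; the scaled
# benchmark lives in test-acceptance.R.

tinyTrainConfig <- function(mode = "aggan", epochs = 1L, seed = 1L, ...)
    trainingConfig(mode = mode, epochs = epochs,
                   decayStart = epochs, seed = seed, sliceSize = 32L,
                   generator = tinyGenConfig(nMasks = 4L),
                   discriminator = tinyDiscConfig(), ...)

tinyDataset <- function(n = 2L, seed = 3L, nz = 2L, dir = tempfile())
    makeDataset(dir, n, tinySpec(nz = nz), artifactSpec(), seed = seed,
                testFraction = 0)

test_that("the learning-rate schedule is constant then linearly decaying", {
    cfg <- trainingConfig()
    expect_equal(lrSchedule(0, cfg), 1e-4)
    expect_equal(lrSchedule(49, cfg), 1e-4)
    expect_equal(lrSchedule(50, cfg), 1e-4)   # decay start
    expect_equal(lrSchedule(75, cfg), 5e-5)   # linear midpoint
    expect_equal(lrSchedule(100, cfg), 0)
    expect_error(lrSchedule(101, cfg), "epoch")
    expect_error(lrSchedule(-1, cfg), "epoch")
})

test_that("epoch shuffles are seeded bijections, independent per pool", {
    p1 <- shuffleUnpaired(10, 7, epoch = 1, seed = 42)
    p2 <- shuffleUnpaired(10, 7, epoch = 1, seed = 42)
    expect_identical(p1, p2)                       # reproducible
    expect_setequal(p1$a, 1:10)                    # bijection
    expect_setequal(p1$b, 1:7)
    p3 <- shuffleUnpaired(10, 7, epoch = 2, seed = 42)
    expect_false(identical(p1$a, p3$a))            # fresh each epoch
    pp <- shuffleUnpaired(6, 6, epoch = 1, seed = 42, paired = TRUE)
    expect_identical(pp$a, pp$b)                   # pairing preserved
    expect_error(shuffleUnpaired(5, 6, 1, 1, paired = TRUE), "equal")
    expect_error(shuffleUnpaired(0, 6, 1, 1), "empty")
})

test_that("one epoch on a 4-slice dataset runs 4 iterations and checkpoints", {
    man <- tinyDataset(n = 2L, nz = 2L)  # 2 volumes x 2 slices per pool
    out <- tempfile()
    mod <- trainTranslation(tinyTrainConfig(epochs = 1L), man, outDir = out)
    expect_equal(nrow(mod$log), 4L)
    expect_equal(length(dir(out, pattern = "checkpoint.*rds")), 1L)
    # the log carries every adversarial, cycle and identity term
    need <- c("L_GAN_D_CT", "L_GAN_G_CBCT_CT", "L_GAN_D_CBCT",
              "L_GAN_G_CT_CBCT", "L_cycle_CBCT", "L_cycle_CT",
              "L_idt_CT", "L_idt_CBCT", "L_GAN", "L_cycle", "L_idt",
              "L_total")
    expect_true(all(need %in% names(mod$log)))
    expect_true(all(is.finite(as.matrix(mod$log))))
    # totals recombine exactly
    expect_equal(mod$log$L_total,
                 mod$log$L_GAN + 10 * mod$log$L_cycle + 5 * mod$log$L_idt)
})

test_that("identical seeds reproduce identical loss logs and weights", {
    man <- tinyDataset(n = 2L, nz = 2L)
    ns <- asNamespace("sctgan")
    m1 <- trainTranslation(tinyTrainConfig(epochs = 2L, seed = 5L), man)
    m2 <- trainTranslation(tinyTrainConfig(epochs = 2L, seed = 5L), man)
    expect_identical(m1$log, m2$log)
    expect_identical(ns$paramChecksum(m1$genA$enc),
                     ns$paramChecksum(m2$genA$enc))
    m3 <- trainTranslation(tinyTrainConfig(epochs = 2L, seed = 6L), man)
    expect_false(identical(m1$log, m3$log))
})

test_that("discriminator updates never modify generator weights and vice versa", {
    ns <- asNamespace("sctgan")
    cfg <- tinyTrainConfig()
    gen <- buildGenerator(cfg$generator, seed = 1)
    disc <- buildDiscriminator(cfg$discriminator, seed = 2)
    genSum <- ns$paramChecksum(c(gen$enc, gen$content, gen$attention))
    st <- ns$newAdamState()
    set.seed(3)
    real <- matrix(runif(32^2, -1, 1), 32, 32)
    fake <- matrix(runif(32^2, -1, 1), 32, 32)
    r <- ns$discStep(disc, st, real, fake, lr = 1e-3, cfg)
    # discriminator changed, generator untouched
    expect_false(ns$paramChecksum(r$disc$layers) ==
                 ns$paramChecksum(disc$layers))
    expect_identical(ns$paramChecksum(c(gen$enc, gen$content,
                                        gen$attention)), genSum)
    # generator-side Adam with its own gradients leaves the disc untouched
    discSum <- ns$paramChecksum(r$disc$layers)
    f <- ns$genForward(gen, real)
    gacc <- ns$newGradAcc()
    ns$genBackward(gen, f$tape, matrix(1 / 32^2, 32, 32), gacc)
    gen2 <- ns$genAdam(gen, gacc, ns$newAdamState(), 1e-3, cfg)
    expect_false(ns$paramChecksum(c(gen2$enc, gen2$content,
                                    gen2$attention)) == genSum)
    expect_identical(ns$paramChecksum(r$disc$layers), discSum)
})

test_that("baseline modes train through the same loop", {
    man <- tinyDataset(n = 2L, nz = 2L)
    mc <- trainTranslation(tinyTrainConfig(mode = "cyclegan"), man)
    expect_null(mc$genA$attention)  # attention branch disabled
    expect_equal(nrow(mc$log), 4L)
    mp <- trainTranslation(tinyTrainConfig(mode = "pix2pix"), man)
    expect_true("L_L1_paired" %in% names(mp$log))
    expect_null(mp$genB)
    # pix2pix refuses unpaired data
    man2 <- makeDataset(tempfile(), 2, tinySpec(nz = 2L), artifactSpec(),
                        seed = 4L, paired = FALSE, testFraction = 0)
    expect_error(trainTranslation(tinyTrainConfig(mode = "pix2pix"), man2),
                 "paired")
})

test_that("synthesizeVolume preserves geometry and the identity path", {
    ph <- generatePhantom(tinySpec(seed = 8L))
    cfg <- tinyTrainConfig()
    model <- list(config = cfg,
                  genA = forceBackgroundAttention(
                      buildGenerator(cfg$generator, seed = 1)))
    out <- synthesizeVolume(ph$ct, model)
    expect_equal(dim(out), dim(ph$ct))
    expect_equal(spacing(out), spacing(ph$ct))
    expect_equal(origin(out), origin(ph$ct))
    expect_true(all(voxels(out) >= -1000 & voxels(out) <= 1500))
    # identity-forced generator: output equals the input up to the
    # normalize/resize round trip (32 -> 32 here, so only normalization)
    expect_equal(voxels(out), voxels(ph$ct), tolerance = 1e-9)
    out2 <- synthesizeVolume(ph$ct, model)
    expect_identical(voxels(out), voxels(out2))
    expect_error(synthesizeVolume(ph$ct, list(config = cfg)), "corrupt")
})

test_that("checkpoints round-trip through disk", {
    man <- tinyDataset(n = 2L, nz = 2L)
    mod <- trainTranslation(tinyTrainConfig(), man)
    f <- tempfile(fileext = ".rds")
    saveCheckpoint(mod, f)
    back <- loadCheckpoint(f)
    ns <- asNamespace("sctgan")
    expect_identical(ns$paramChecksum(back$genA$enc),
                     ns$paramChecksum(mod$genA$enc))
    bad <- tempfile(fileext = ".rds")
    saveRDS(list(x = 1), bad)
    expect_error(loadCheckpoint(bad), "corrupt")
})
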