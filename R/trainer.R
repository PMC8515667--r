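#' Training configuration
#'
#' Mirrors the published regimen: Adam with initial learning rate 1e-4,
#' momenta beta1 = 0.5 / beta2 = 0.999, batch size 1, 100 epochs with the
#' learning rate held constant for the first 50 and then decayed linearly to
#' zero, slices shuffled independently per pool each epoch.
#'
#' @param mode "aggan" (attention generator, unpaired), "cyclegan"
#'   (identical loop with the attention branch disabled) or "pix2pix"
#'   (paired conditional baseline).
#' @param epochs total epochs (default 100).
#' @param decayStart epoch at which linear decay begins (default 50).
#' @param lr0 initial Adam learning rate (default 1e-4).
#' @param beta1,beta2 Adam momenta (defaults 0.5, 0.999).
#' @param batchSize images per update (default 1).
#' @param seed master seed for weight init and shuffling.
#' @param sliceSize training resolution (default 256).
#' @param generator a \code{\link{generatorConfig}}; its attention flag is
#'   forced off for the baseline modes.
#' @param discriminator a \code{\link{discriminatorConfig}}.
#' @param weights a \code{\link{lossWeights}}.
#' @param reduce patch reduction mode for the adversarial penalties
#'   ("image" or "patch"); see \code{\link{lsganDLoss}}.
#' @param fakeBuffer size of the historical fake-image pool for
#'   discriminator updates (0 = disabled, the default).
#' @param checkpointEvery checkpoint cadence in epochs.
#' @return a \code{trainingConfig} list.
#' @export
trainingConfig <- function(mode = c("aggan", "cyclegan", "pix2pix"),
                           epochs = 100L, decayStart = 50L, lr0 = 1e-4,
                           beta1 = 0.5, beta2 = 0.999, batchSize = 1L,
                           seed = 1L, sliceSize = 256L,
                           generator = generatorConfig(),
                           discriminator = discriminatorConfig(),
                           weights = lossWeights(),
                           reduce = c("image", "patch"), fakeBuffer = 0L,
                           checkpointEvery = epochs) {
    mode <- match.arg(mode)
    stopifnot(decayStart <= epochs, lr0 > 0, epochs >= 1, batchSize >= 1)
    if (mode != "aggan")
        generator <- generatorConfig(nMasks = generator$nMasks,
                                     encoderChannels = generator$encoderChannels,
                                     nResBlocks = generator$nResBlocks,
                                     attention = FALSE)
    structure(list(mode = mode, epochs = as.integer(epochs),
                   decayStart = as.integer(decayStart), lr0 = lr0,
                   beta1 = beta1, beta2 = beta2,
                   batchSize = as.integer(batchSize),
                   seed = as.integer(seed), sliceSize = as.integer(sliceSize),
                   generator = generator, discriminator = discriminator,
                   weights = weights, reduce = match.arg(reduce),
                   fakeBuffer = as.integer(fakeBuffer),
                   checkpointEvery = as.integer(checkpointEvery)),
              class = "trainingConfig")
}

#' Learning-rate schedule
#'
#' Constant at \code{lr0} before \code{decayStart}, then linear to exactly 0
#' at \code{epochs}.
#'
#' @param epoch epoch in [0, epochs].
#' @param config a \code{\link{trainingConfig}}.
#' @return the learning rate.
#' @examples
#' cfg <- trainingConfig()
#' lrSchedule(0, cfg)    # 1e-4
#' lrSchedule(75, cfg)   # 5e-5
#' lrSchedule(100, cfg)  # 0
#' @export
lrSchedule <- function(epoch, config) {
    if (epoch < 0 || epoch > config$epochs)
        stop("epoch must lie in [0, ", config$epochs, "]")
    if (epoch < config$decayStart) return(config$lr0)
    span <- config$epochs - config$decayStart
    if (span == 0) return(0)
    config$lr0 * (config$epochs - epoch) / span
}

#' Per-epoch slice shuffling
#'
#' Unpaired training draws independent seeded permutations of the CBCT and
#' CT slice pools each epoch; paired training uses one shared permutation so
#' pairs stay aligned. Reproducible across runs for the same seed.
#'
#' @param nA,nB pool sizes (CBCT, CT).
#' @param epoch epoch number (1-based).
#' @param seed master seed.
#' @param paired use a single shared permutation (requires nA == nB).
#' @return list with permutations \code{a} and \code{b}.
#' @export
shuffleUnpaired <- function(nA, nB, epoch, seed, paired = FALSE) {
    if (nA < 1 || nB < 1) stop("empty slice pool")
    set.seed((seed %% 1000003L) * 1021L + epoch)
    if (paired) {
        if (nA != nB) stop("paired mode requires equal pool sizes")
        p <- sample.int(nA)
        list(a = p, b = p)
    } else {
        list(a = sample.int(nA), b = sample.int(nB))
    }
}

## Load all training slices for one role into a (size, size, n) array.
loadSlicePool <- function(manifest, role, split, sliceSize) {
    rows <- manifest[manifest$role == role & manifest$split == split, ]
    if (nrow(rows) == 0L) stop("no ", role, " volumes in split ", split)
    pools <- lapply(rows$path, function(p) {
        slices(volumeToSlices(readVolume(p), targetSize = sliceSize))
    })
    arr <- array(0, c(sliceSize, sliceSize, sum(vapply(pools, function(x)
        dim(x)[3], integer(1)))))
    k <- 0L
    for (p in pools) {
        n <- dim(p)[3]
        arr[, , k + seq_len(n)] <- p
        k <- k + n
    }
    arr
}

## Gradient of the adversarial penalty with respect to a score map.
scoreGrad <- function(s, target, reduce) {
    n <- length(s)
    if (reduce == "image") array((mean(s) - target) / n, dim(s))
    else (s - target) / n
}

## One backward pass through a discriminator for the generator update:
## parameter gradients are discarded, only the input gradient is used.
discInputGrad <- function(disc, image, target, reduce) {
    x <- image; dim(x) <- c(dim(image), 1L)
    f <- seqForward(disc$layers, x)
    s <- f$y[, , 1]
    gs <- scoreGrad(s, target, reduce)
    dim(gs) <- c(dim(gs), 1L)
    gx <- seqBackward(disc$layers, f$caches, gs, NULL)
    list(score = s, gx = gx[, , 1],
         loss = if (reduce == "image") (mean(s) - target)^2 / 2
                else mean((s - target)^2) / 2)
}

## Discriminator LSGAN update on one (real, fake) pair. Returns the loss and
## the updated discriminator.
discStep <- function(disc, state, real, fake, lr, cfg) {
    gacc <- newGradAcc()
    xr <- real; dim(xr) <- c(dim(real), 1L)
    xf <- fake; dim(xf) <- c(dim(fake), 1L)
    fr <- seqForward(disc$layers, xr)
    ff <- seqForward(disc$layers, xf)
    sr <- fr$y[, , 1]; sf <- ff$y[, , 1]
    loss <- lsganDLoss(list(sr), list(sf), cfg$reduce)
    gr <- scoreGrad(sr, 1, cfg$reduce)
    gf <- scoreGrad(sf, 0, cfg$reduce)
    dim(gr) <- c(dim(sr), 1L); dim(gf) <- c(dim(sf), 1L)
    seqBackward(disc$layers, fr$caches, gr, gacc)
    seqBackward(disc$layers, ff$caches, gf, gacc)
    state$t <- state$t + 1L
    disc$layers <- adamStep(disc$layers, gacc, state, lr, cfg$beta1, cfg$beta2)
    list(disc = disc, loss = loss)
}

## Apply Adam to all three generator stacks with one shared state.
genAdam <- function(gen, gacc, state, lr, cfg) {
    state$t <- state$t + 1L
    gen$enc <- adamStep(gen$enc, gacc, state, lr, cfg$beta1, cfg$beta2)
    gen$content <- adamStep(gen$content, gacc, state, lr, cfg$beta1, cfg$beta2)
    if (!is.null(gen$attention))
        gen$attention <- adamStep(gen$attention, gacc, state, lr,
                                  cfg$beta1, cfg$beta2)
    gen
}

derivedSeed <- function(seed, k) (seed %% 2100000000L) + k

#' Train a CBCT-to-CT translation model
#'
#' Runs the full adversarial training loop for the configured mode. In the
#' unpaired modes every iteration executes both cycles
#' (CBCT -> sCT -> rCBCT and CT -> sCBCT -> rCT), updates the generators
#' jointly against the total objective (adversarial + weighted cycle +
#' weighted identity), then updates each discriminator on a (real, fake)
#' pair; the paired mode trains a single generator against the conditional
#' adversarial + L1 objective. One epoch visits max(pool sizes) slice pairs;
#' the smaller pool wraps around. Fully reproducible given the config seed.
#'
#' @param config a \code{\link{trainingConfig}}.
#' @param data a dataset manifest data.frame (from \code{\link{makeDataset}}
#'   / \code{\link{readManifest}}) or the path to one.
#' @param outDir optional directory for checkpoints and the loss log CSV.
#' @param verbose print per-epoch progress.
#' @return a model list with the generators, discriminators, loss log
#'   (one row per iteration, every adversarial/cycle/identity term), and the
#'   config.
#' @export
trainTranslation <- function(config, data, outDir = NULL, verbose = FALSE) {
    stopifnot(inherits(config, "trainingConfig"))
    manifest <- if (is.character(data)) readManifest(data) else data
    paired <- config$mode == "pix2pix"
    if (paired && any(is.na(manifest$pair_id)))
        stop("pix2pix mode requires a paired dataset manifest")
    poolA <- loadSlicePool(manifest, "cbct", "train", config$sliceSize)
    poolB <- loadSlicePool(manifest, "ct", "train", config$sliceSize)
    nA <- dim(poolA)[3]; nB <- dim(poolB)[3]
    if (paired && nA != nB) stop("paired mode requires aligned pools")

    genA <- buildGenerator(config$generator, derivedSeed(config$seed, 11L))
    genB <- if (!paired)
        buildGenerator(config$generator, derivedSeed(config$seed, 12L))
    discCT <- buildDiscriminator(config$discriminator,
                                 derivedSeed(config$seed, 13L))
    discCBCT <- if (!paired)
        buildDiscriminator(config$discriminator, derivedSeed(config$seed, 14L))
    stGA <- newAdamState(); stGB <- newAdamState()
    stDA <- newAdamState(); stDB <- newAdamState()

    nIter <- max(nA, nB)
    if (paired) nIter <- nA
    w <- config$weights
    logRows <- vector("list", config$epochs * nIter)
    li <- 0L
    if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                     showWarnings = FALSE)

    for (epoch in seq_len(config$epochs)) {
        lr <- lrSchedule(epoch - 1L, config)
        perm <- shuffleUnpaired(nA, nB, epoch, config$seed, paired)
        t0 <- Sys.time()
        for (it in seq_len(nIter)) {
            xA <- poolA[, , perm$a[(it - 1L) %% nA + 1L]]
            xB <- poolB[, , perm$b[(it - 1L) %% nB + 1L]]
            li <- li + 1L
            if (paired) {
                row <- iterPix2pix(config, w, lr, xA, xB,
                                   environment())
            } else {
                row <- iterCycle(config, w, lr, xA, xB, environment())
            }
            if (!all(is.finite(unlist(row))))
                stop("non-finite loss at epoch ", epoch, ", iteration ", it,
                     "; aborting")
            logRows[[li]] <- c(epoch = epoch, iteration = it, lr = lr, row)
        }
        if (verbose)
            message(sprintf("epoch %d/%d (%.1fs): total %.4f", epoch,
                            config$epochs,
                            as.numeric(Sys.time() - t0, units = "secs"),
                            logRows[[li]][["L_total"]]))
        if (!is.null(outDir) && (epoch %% config$checkpointEvery == 0L ||
                                 epoch == config$epochs)) {
            model <- list(mode = config$mode, config = config, genA = genA,
                          genB = genB, discCT = discCT, discCBCT = discCBCT,
                          epoch = epoch)
            saveCheckpoint(model, file.path(outDir,
                sprintf("checkpoint_epoch%03d.rds", epoch)))
        }
    }
    log <- as.data.frame(do.call(rbind, logRows))
    if (!is.null(outDir))
        utils::write.csv(log, file.path(outDir, "training_log.csv"),
                         row.names = FALSE)
    model <- list(mode = config$mode, config = config, genA = genA,
                  genB = genB, discCT = discCT, discCBCT = discCBCT,
                  log = log, epoch = config$epochs)
    class(model) <- "sctganModel"
    model
}

## One unpaired (aggan / cyclegan) iteration; mutates the trainer
## environment env (networks, Adam states) and returns the loss-log row.
iterCycle <- function(cfg, w, lr, xA, xB, env) {
    genA <- env$genA; genB <- env$genB
    npix <- length(xA)
    ## forward both cycles + identities
    fA <- genForward(genA, xA)          # sCT
    fB <- genForward(genB, xB)          # sCBCT
    rA <- genForward(genB, fA$out)      # rCBCT
    rB <- genForward(genA, fB$out)      # rCT
    iA <- genForward(genA, xB)          # identity CT
    iB <- genForward(genB, xA)          # identity CBCT

    advA <- discInputGrad(env$discCT, fA$out, 1, cfg$reduce)
    advB <- discInputGrad(env$discCBCT, fB$out, 1, cfg$reduce)

    cycA <- mean(abs(rA$out - xA)); cycB <- mean(abs(rB$out - xB))
    idtCT <- mean(abs(iA$out - xB)); idtCBCT <- mean(abs(iB$out - xA))

    gaccGA <- newGradAcc(); gaccGB <- newGradAcc()
    ## cycle CBCT: |G_B(G_A(xA)) - xA| -> through G_B then G_A
    gyRA <- w$cycle * sign(rA$out - xA) / npix
    gSCT <- advA$gx + genBackward(genB, rA$tape, gyRA, gaccGB)
    genBackward(genA, fA$tape, gSCT, gaccGA)
    ## cycle CT: through G_A then G_B
    gyRB <- w$cycle * sign(rB$out - xB) / npix
    gSCBCT <- advB$gx + genBackward(genA, rB$tape, gyRB, gaccGA)
    genBackward(genB, fB$tape, gSCBCT, gaccGB)
    ## identities
    genBackward(genA, iA$tape, w$idt * sign(iA$out - xB) / npix, gaccGA)
    genBackward(genB, iB$tape, w$idt * sign(iB$out - xA) / npix, gaccGB)

    env$genA <- genAdam(genA, gaccGA, env$stGA, lr, cfg)
    env$genB <- genAdam(genB, gaccGB, env$stGB, lr, cfg)

    ## discriminators (generator outputs detached)
    fakeCT <- pickFake(env, "bufCT", fA$out, cfg)
    fakeCBCT <- pickFake(env, "bufCBCT", fB$out, cfg)
    dA <- discStep(env$discCT, env$stDA, xB, fakeCT, lr, cfg)
    dB <- discStep(env$discCBCT, env$stDB, xA, fakeCBCT, lr, cfg)
    env$discCT <- dA$disc; env$discCBCT <- dB$disc

    rep <- lossReport(ganDCT = dA$loss, ganGCBCTCT = advA$loss,
                      ganDCBCT = dB$loss, ganGCTCBCT = advB$loss,
                      cycleCBCT = cycA, cycleCT = cycB,
                      idtCT = idtCT, idtCBCT = idtCBCT, m = 1L)
    c(L_GAN_D_CT = rep$ganDCT, L_GAN_G_CBCT_CT = rep$ganGCBCTCT,
      L_GAN_D_CBCT = rep$ganDCBCT, L_GAN_G_CT_CBCT = rep$ganGCTCBCT,
      L_cycle_CBCT = rep$cycleCBCT, L_cycle_CT = rep$cycleCT,
      L_idt_CT = rep$idtCT, L_idt_CBCT = rep$idtCBCT,
      L_GAN = rep$L_GAN, L_cycle = rep$L_cycle, L_idt = rep$L_idt,
      L_total = totalLoss(rep, w))
}

## Optional historical fake pool (off by default).
pickFake <- function(env, key, fake, cfg) {
    if (cfg$fakeBuffer <= 0L) return(fake)
    buf <- env[[key]]
    if (is.null(buf)) buf <- list()
    if (length(buf) < cfg$fakeBuffer) {
        buf[[length(buf) + 1L]] <- fake
        env[[key]] <- buf
        return(fake)
    }
    if (runif(1) > 0.5) {
        j <- sample.int(length(buf), 1L)
        out <- buf[[j]]
        buf[[j]] <- fake
        env[[key]] <- buf
        out
    } else fake
}

## One paired conditional (pix2pix baseline) iteration.
iterPix2pix <- function(cfg, w, lr, xA, xB, env) {
    genA <- env$genA
    npix <- length(xA)
    fA <- genForward(genA, xA)
    adv <- discInputGrad(env$discCT, fA$out, 1, cfg$reduce)
    l1 <- mean(abs(fA$out - xB))
    gaccG <- newGradAcc()
    gOut <- adv$gx + w$l1Paired * sign(fA$out - xB) / npix
    genBackward(genA, fA$tape, gOut, gaccG)
    env$genA <- genAdam(genA, gaccG, env$stGA, lr, cfg)
    dA <- discStep(env$discCT, env$stDA, xB, fA$out, lr, cfg)
    env$discCT <- dA$disc
    c(L_GAN_D_CT = dA$loss, L_GAN_G_CBCT_CT = adv$loss,
      L_GAN_D_CBCT = 0, L_GAN_G_CT_CBCT = 0,
      L_cycle_CBCT = 0, L_cycle_CT = 0, L_idt_CT = 0, L_idt_CBCT = 0,
      L_GAN = dA$loss + adv$loss, L_cycle = 0, L_idt = 0,
      L_L1_paired = l1,
      L_total = adv$loss + dA$loss + w$l1Paired * l1)
}

#' Synthesize a CT volume from a CBCT volume
#'
#' Clips and normalizes the input, cuts it into training-resolution axial
#' slices, runs the CBCT-to-CT generator on each slice, and reassembles the
#' outputs on the input geometry. Output HU always lie in [-1000, 1500].
#'
#' @param cbct an \linkS4class{HUVolume}.
#' @param model a trained model from \code{\link{trainTranslation}} or a
#'   checkpoint loaded with \code{\link{loadCheckpoint}}.
#' @return the synthetic CT as an \linkS4class{HUVolume} with the input's
#'   spacing, origin and shape.
#' @export
synthesizeVolume <- function(cbct, model) {
    stopifnot(is(cbct, "HUVolume"))
    if (is.null(model$genA)) stop("corrupt checkpoint: no generator")
    size <- model$config$sliceSize
    st <- volumeToSlices(cbct, targetSize = size)
    out <- st@slices
    for (k in seq_len(dim(out)[3]))
        out[, , k] <- genForward(model$genA, st@slices[, , k])$out
    st@slices <- pmin(pmax(out, -1), 1)
    slicesToVolume(st)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry a schema version, the full configuration and all
#' network weights.
#'
#' @param model a model list.
#' @param path file path.
#' @return \code{saveCheckpoint}: the path invisibly;
#'   \code{loadCheckpoint}: the model.
#' @export
saveCheckpoint <- function(model, path) {
    saveRDS(list(schema = 1L, model = model), path)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
    x <- readRDS(path)
    if (is.null(x$schema) || x$schema != 1L)
        stop("unsupported or corrupt checkpoint: ", path)
    x$model
}
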