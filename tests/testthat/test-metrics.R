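test_that("MAE matches its definition and a brute-force oracle", {
    a <- randomHUVolume(c(6L, 5L, 4L), seed = 1)
    expect_equal(maeHU(a, a), 0)
    # uniform offset
    aa <- HUVolume(array(100, c(4, 4, 2)))
    expect_equal(maeHU(aa, HUVolume(array(110, c(4, 4, 2)))), 10)
    set.seed(2)
    t2 <- HUVolume(voxels(a) + array(rnorm(120, 0, 40), dim(a)),
                   spacing = spacing(a))
    oracle <- 0
    for (i in seq_along(voxels(a)))
        oracle <- oracle + abs(voxels(t2)[i] - voxels(a)[i])
    expect_equal(maeHU(a, t2), oracle / 120, tolerance = 1e-9)
    # masked evaluation and error paths
    msk <- array(FALSE, dim(a)); msk[1:3, 1, 1] <- TRUE
    expect_equal(maeHU(a, t2, msk), mean(abs(voxels(t2) - voxels(a))[msk]))
    expect_error(maeHU(a, t2, array(FALSE, dim(a))), "empty")
    expect_error(maeHU(a, randomHUVolume(c(3L, 3L, 3L))), "geometries")
})

test_that("MAE satisfies the triangle inequality", {
    a <- randomHUVolume(c(5L, 5L, 3L), seed = 3)
    b <- randomHUVolume(c(5L, 5L, 3L), seed = 4)
    c3 <- randomHUVolume(c(5L, 5L, 3L), seed = 5)
    expect_lte(maeHU(a, c3), maeHU(a, b) + maeHU(b, c3) + 1e-12)
})

test_that("SSIM is 1 for identical volumes and has the constant closed form", {
    v <- randomHUVolume(c(14L, 14L, 2L), seed = 6)
    expect_equal(ssimHU(v, v), 1)
    a <- 200; b <- 300; L <- 2500; C1 <- (0.01 * L)^2
    va <- HUVolume(array(a, c(12L, 12L, 2L)))
    vb <- HUVolume(array(b, c(12L, 12L, 2L)))
    expect_equal(ssimHU(va, vb), (2 * a * b + C1) / (a^2 + b^2 + C1),
                 tolerance = 1e-12)
    # symmetry
    w <- HUVolume(voxels(v) + array(rnorm(392, 0, 30), dim(v)),
                  spacing = spacing(v))
    expect_equal(ssimHU(v, w), ssimHU(w, v))
    expect_gt(ssimHU(v, v), ssimHU(v, w))
})

test_that("PSNR follows 20 log10(range / RMSE) and is consistent with MAE", {
    v <- HUVolume(array(0, c(6L, 6L, 2L)))
    off <- HUVolume(array(25, c(6L, 6L, 2L)))
    expect_equal(psnrHU(v, off), 40)  # 20 log10(2500 / 25)
    expect_equal(psnrHU(v, v), Inf)
    a <- randomHUVolume(c(6L, 6L, 3L), seed = 7)
    set.seed(8)
    t2 <- HUVolume(voxels(a) + array(rnorm(108, 0, 20), dim(a)),
                   spacing = spacing(a))
    mse <- mean((voxels(t2) - voxels(a))^2)
    expect_equal(psnrHU(a, t2), 20 * log10(2500 / sqrt(mse)),
                 tolerance = 1e-12)
    # uniform offsets: PSNR = 20 log10(range / |d|)
    for (d in c(5, 50, 400)) {
        vd <- HUVolume(voxels(v) + d)
        expect_equal(psnrHU(v, vd), 20 * log10(2500 / d))
        expect_equal(maeHU(v, vd), d)
    }
})

test_that("roiStats returns per-label means and population SDs", {
    vox <- array(0, c(4L, 4L, 1L))
    roi <- array(0L, c(4L, 4L, 1L))
    vox[1:2, 1, 1] <- c(0, 2);  roi[1:2, 1, 1] <- 1L  # lung: {0, 2}
    vox[3:4, 1, 1] <- 7;        roi[3:4, 1, 1] <- 2L  # bone: constant
    vox[1:2, 2, 1] <- c(-5, 5); roi[1:2, 2, 1] <- 3L
    st <- roiStats(HUVolume(vox), roi)
    expect_equal(st$mean[st$roi == "lung"], 1)
    expect_equal(st$sd[st$roi == "lung"], 1)     # population SD of {0, 2}
    expect_equal(st$mean[st$roi == "bone"], 7)
    expect_equal(st$sd[st$roi == "bone"], 0)
    expect_error(roiStats(HUVolume(vox), array(0L, c(4L, 4L, 1L))),
                 "no voxels")
})

test_that("huHistogram counts match a sort-and-count oracle", {
    v <- randomHUVolume(c(8L, 8L, 3L), seed = 9)
    h <- huHistogram(v, binWidth = 100)
    expect_equal(sum(h$counts), length(voxels(v)))
    oracle <- integer(length(h$edges) - 1L)
    for (x in sort(as.numeric(voxels(v)))) {
        j <- max(which(h$edges <= x)); j <- min(j, length(oracle))
        oracle[j] <- oracle[j] + 1L
    }
    expect_equal(h$counts, oracle)
    hc <- huHistogram(HUVolume(array(250, c(3, 3, 1))), binWidth = 50)
    expect_equal(sum(hc$counts > 0), 1L)  # constant volume: one bin
    expect_error(huHistogram(v, binWidth = 0), "positive")
    expect_error(huHistogram(v, range = c(0, 10)), "cover")
})

test_that("paired Wilcoxon matches exact sign enumeration at small n", {
    # n = 6 strictly positive differences: one-sided exact p = 1 / 64
    b <- c(10, 12, 9, 14, 11, 13)
    a <- b + c(1, 2, 0.5, 3, 1.5, 2.5)
    r <- pairedWilcoxon(a, b, alternative = "greater")
    # oracle: enumerate all 2^6 sign assignments of the ranked differences
    d <- abs(a - b); rk <- rank(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    Vnull <- signs %*% rk
    pOracle <- mean(Vnull >= sum(rk))
    expect_equal(pOracle, 1 / 64)
    expect_equal(r$p, pOracle, tolerance = 1e-12)
    expect_equal(r$statistic, 21)
    expect_true(r$significant)
    # two-sided p unchanged when the samples swap roles
    r1 <- pairedWilcoxon(a, b); r2 <- pairedWilcoxon(b, a)
    expect_equal(r1$p, r2$p)
    # identical samples: no signal
    rd <- pairedWilcoxon(b, b)
    expect_true(rd$degenerate)
    expect_false(rd$significant)
})

test_that("evaluateVolumes and cohortTable aggregate per-volume metrics", {
    ph <- generatePhantom(tinySpec(seed = 10L))
    cb <- simulateCBCT(ph$ct, artifactSpec(seed = 2L), roi = ph$roi)
    m <- evaluateVolumes(ph$ct, cb, roi = ph$roi)
    expect_gt(m$mae, 0)
    expect_lt(m$ssim, 1)
    expect_true(is.finite(m$psnr))
    expect_equal(m$dataRange, 2500)
    expect_equal(nrow(m$roi), 3L)
    tab <- cohortTable(list(m, m), ids = c("a", "b"))
    expect_equal(nrow(tab), 4L)  # 2 volumes + mean + sd rows
    expect_equal(tab$mae[tab$id == "mean"], m$mae)
    expect_equal(tab$mae[tab$id == "sd"], 0)
})
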