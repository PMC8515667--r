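test_that("generatePhantom is deterministic and hits the tissue HU targets", {
    ph1 <- generatePhantom(phantomSpec(seed = 11L))
    ph2 <- generatePhantom(phantomSpec(seed = 11L))
    expect_identical(voxels(ph1$ct), voxels(ph2$ct))
    expect_identical(ph1$roi, ph2$roi)
    expect_false(identical(voxels(ph1$ct),
                           voxels(generatePhantom(phantomSpec(seed = 12L))$ct)))

    spec <- phantomSpec(seed = 1L)
    ph <- generatePhantom(spec)
    st <- roiStats(ph$ct, ph$roi)
    for (tis in c("lung", "bone", "soft")) {
        row <- st[st$roi == tis, ]
        tol <- 2 * spec@huSD[tis] / sqrt(row$n)
        expect_lt(abs(row$mean - spec@huMean[tis]), tol)
    }
    expect_true(all(voxels(ph$ct) >= -1000 & voxels(ph$ct) <= 1500))
})

test_that("ROI label counts match direct voxel-membership enumeration", {
    spec <- tinySpec(seed = 3L, jitter = 0)  # jitter off: analytic geometry
    ph <- generatePhantom(spec)
    nx <- spec@shape[1]; ny <- spec@shape[2]
    xi <- (seq_len(nx) - (nx + 1) / 2) / nx
    yi <- (seq_len(ny) - (ny + 1) / 2) / ny
    counts <- c(lung = 0L, bone = 0L, soft = 0L)
    a <- spec@bodyAxes[1]; b <- spec@bodyAxes[2]
    ribA <- seq(22.5, 337.5, by = 45) * pi / 180
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
        x <- xi[i]; y <- yi[j]
        inBody <- (x / a)^2 + (y / b)^2 <= 1
        inLung <- ((x - spec@lungCenters[1, 1]) / spec@lungAxes[1])^2 +
                  ((y - spec@lungCenters[1, 2]) / spec@lungAxes[2])^2 <= 1 ||
                  ((x - spec@lungCenters[2, 1]) / spec@lungAxes[1])^2 +
                  ((y - spec@lungCenters[2, 2]) / spec@lungAxes[2])^2 <= 1
        inBone <- x^2 + (y + 0.625 * b)^2 <= spec@spineRadius^2
        for (th in ribA)
            inBone <- inBone ||
                ((x - 0.90 * a * cos(th))^2 + (y - 0.90 * b * sin(th))^2 <=
                 spec@ribRadius^2)
        if (inBone) counts["bone"] <- counts["bone"] + 1L
        else if (inLung) counts["lung"] <- counts["lung"] + 1L
        else if (inBody) counts["soft"] <- counts["soft"] + 1L
    }
    nz <- spec@shape[3]
    expect_identical(sum(ph$roi == 1L), counts[["lung"]] * nz)
    expect_identical(sum(ph$roi == 2L), counts[["bone"]] * nz)
    expect_identical(sum(ph$roi == 3L), counts[["soft"]] * nz)
})

test_that("a zero-amplitude artifact spec is the bit-exact identity", {
    ph <- generatePhantom(tinySpec(seed = 2L))
    cbct <- simulateCBCT(ph$ct, zeroArtifactSpec(), roi = ph$roi)
    expect_identical(voxels(cbct), voxels(ph$ct))
})

test_that("the lung-shift component moves the lung ROI mean by its amplitude", {
    ph <- generatePhantom(tinySpec(seed = 4L))
    spec <- zeroArtifactSpec()
    spec@lungShift <- -145
    cbct <- simulateCBCT(ph$ct, spec, roi = ph$roi)
    before <- mean(voxels(ph$ct)[ph$roi == 1L])
    after <- mean(voxels(cbct)[ph$roi == 1L])
    # oracle: recompute the shifted-and-clipped ROI mean directly
    oracle <- mean(pmin(pmax(voxels(ph$ct)[ph$roi == 1L] - 145, -1000),
                        1500))
    expect_equal(after, oracle, tolerance = 1e-12)
    expect_equal(after - before, -145, tolerance = 1)  # clip bias is tiny
    # everything outside the lungs untouched
    expect_identical(voxels(cbct)[ph$roi != 1L], voxels(ph$ct)[ph$roi != 1L])
})

test_that("artifact components are additive and independently switchable", {
    ph <- generatePhantom(tinySpec(seed = 5L))
    full <- simulateCBCT(ph$ct, artifactSpec(seed = 9L), roi = ph$roi,
                         returnComponents = TRUE)
    expect_identical(full$composite, Reduce(`+`, full$components))
    expect_equal(voxels(full$cbct),
                 pmin(pmax(voxels(ph$ct) + full$composite, -1000), 1500))
    # zeroing one component leaves the others' randomness untouched
    noStreak <- artifactSpec(seed = 9L); noStreak@streakAmp <- 0
    part <- simulateCBCT(ph$ct, noStreak, roi = ph$roi,
                         returnComponents = TRUE)
    expect_identical(part$components$noise, full$components$noise)
    expect_identical(part$components$shading, full$components$shading)
    expect_true(all(part$components$streaks == 0))
})

test_that("default artifacts depress the phantom lung mean to the CBCT level", {
    ph <- generatePhantom(phantomSpec(seed = 1L))
    cbct <- simulateCBCT(ph$ct, artifactSpec(seed = 1L), roi = ph$roi)
    lungMean <- mean(voxels(cbct)[ph$roi == 1L])
    expect_lt(abs(lungMean - (-899.7)), 25)
})

test_that("makeDataset writes the expected files, splits and manifest", {
    dir <- tempfile()
    man <- makeDataset(dir, 5, tinySpec(), artifactSpec(), seed = 7L)
    expect_equal(nrow(man), 15L)  # 5 x (ct, cbct, roi)
    expect_true(all(file.exists(man$path)))
    expect_true(file.exists(file.path(dir, "manifest.tsv")))
    expect_setequal(unique(man$split), c("train", "test"))
    expect_true(all(table(man$pair_id) == 3L))
    expect_error(makeDataset(dir, 2, tinySpec(), artifactSpec()),
                 "not empty")

    # unpaired manifests carry no pair linkage
    dir2 <- tempfile()
    man2 <- makeDataset(dir2, 3, tinySpec(), artifactSpec(), seed = 7L,
                        paired = FALSE)
    expect_true(all(is.na(man2$pair_id)))

    # same seed: identical manifests and voxel data
    dir3 <- tempfile()
    man3 <- makeDataset(dir3, 5, tinySpec(), artifactSpec(), seed = 7L)
    expect_identical(man$id, man3$id)
    expect_identical(man$seed, man3$seed)
    expect_equal(voxels(readVolume(man$path[1])),
                 voxels(readVolume(man3$path[1])))
})

test_that("synthesizeDose produces a peaked, symmetric, non-negative field", {
    dg <- synthesizeDose(c(21L, 21L, 9L), spacing = c(2, 2, 2),
                         targetCenter = c(20, 20, 8), targetRadius = 8)
    d <- voxels(dg)
    expect_true(all(d >= 0))
    peak <- d[11, 11, 5]
    expect_equal(peak, 5000 * 1.05)
    expect_true(all(d <= peak))
    # radial symmetry: equidistant voxels share the dose
    expect_equal(d[11 + 3, 11, 5], d[11 - 3, 11, 5])
    expect_equal(d[11, 11 + 3, 5], d[11, 11 - 3, 5])
    expect_error(synthesizeDose(c(8L, 8L, 4L), targetCenter = c(99, 0, 0),
                                targetRadius = 2), "outside")
})
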