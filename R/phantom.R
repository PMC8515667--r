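## Digital thorax phantom: aligned CT/CBCT pairs with known ROI labels, the
## test bed for training and every downstream metric. Geometry is defined in
## normalized in-plane coordinates (fractions of the field of view) so one
## spec scales across grid sizes; tissue HU values are drawn as white
## Gaussian noise around per-tissue means.

## ROI label codes used throughout the package.
ROI_AIR  <- 0L
ROI_LUNG <- 1L
ROI_BONE <- 2L
ROI_SOFT <- 3L

## Jittered copy of the phantom anatomy parameters; draws from the current
## RNG stream.
jitterAnatomy <- function(spec) {
    j <- spec@jitter
    rf <- function(n) runif(n, 1 - j, 1 + j)
    list(bodyAxes = spec@bodyAxes * rf(2),
         lungAxes1 = spec@lungAxes * rf(2),
         lungAxes2 = spec@lungAxes * rf(2),
         lungCenters = spec@lungCenters * matrix(rf(4), 2, 2),
         spineRadius = spec@spineRadius, ribRadius = spec@ribRadius)
}

## 2D region masks in normalized coordinates. Returns logical matrices.
phantomMasks2D <- function(spec, anat) {
    nx <- spec@shape[1]; ny <- spec@shape[2]
    xi <- (seq_len(nx) - (nx + 1) / 2) / nx
    yi <- (seq_len(ny) - (ny + 1) / 2) / ny
    X <- matrix(xi, nx, ny); Y <- matrix(yi, nx, ny, byrow = TRUE)
    a <- anat$bodyAxes[1]; b <- anat$bodyAxes[2]
    body <- (X / a)^2 + (Y / b)^2 <= 1
    inEllipse <- function(cx, cy, ax, ay)
        ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
    lung <- inEllipse(anat$lungCenters[1, 1], anat$lungCenters[1, 2],
                      anat$lungAxes1[1], anat$lungAxes1[2]) |
            inEllipse(anat$lungCenters[2, 1], anat$lungCenters[2, 2],
                      anat$lungAxes2[1], anat$lungAxes2[2])
    spineC <- c(0, -0.625 * b)
    bone <- (X - spineC[1])^2 + (Y - spineC[2])^2 <= anat$spineRadius^2
    ribAngles <- seq(22.5, 337.5, by = 45) * pi / 180
    for (th in ribAngles) {
        cx <- 0.90 * a * cos(th); cy <- 0.90 * b * sin(th)
        bone <- bone | ((X - cx)^2 + (Y - cy)^2 <= anat$ribRadius^2)
    }
    list(body = body, lung = lung, bone = bone)
}

#' Generate a digital thorax phantom CT with ROI labels
#'
#' Builds a deterministic (seeded) CT-like volume: an elliptical soft-tissue
#' body containing two lung ellipses, a spinal column and eight rib
#' cross-sections, surrounded by air at -1000 HU. Tissue voxels are
#' \code{huMean + huSD * N(0, 1)}; the result is clipped to [-1000, 1500] HU.
#' Anatomy is perturbed by the spec's relative \code{jitter} (drawn from the
#' seed) so repeated volumes with different seeds differ like patients do.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a list with elements \code{ct} (\linkS4class{HUVolume}) and
#'   \code{roi} (integer 3D array; 0 air, 1 lung, 2 bone, 3 soft tissue).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' mean(voxels(ph$ct)[ph$roi == 1])  # close to the -755 HU lung mean
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    set.seed(spec@seed)
    anat <- jitterAnatomy(spec)
    m <- phantomMasks2D(spec, anat)
    if (any(m$lung & m$bone) || any(m$lung & !m$body) || any(m$bone & !m$body))
        stop("degenerate phantom geometry: ROIs overlap or leave the body")
    if (!any(m$lung) || !any(m$bone) || !any(m$body & !m$lung & !m$bone))
        stop("degenerate phantom geometry: empty ROI")
    label2d <- matrix(ROI_AIR, spec@shape[1], spec@shape[2])
    label2d[m$body] <- ROI_SOFT
    label2d[m$lung] <- ROI_LUNG
    label2d[m$bone] <- ROI_BONE
    nz <- spec@shape[3]
    roi <- array(rep(label2d, nz), spec@shape)
    vox <- array(-1000, spec@shape)
    for (tis in c("lung", "bone", "soft")) {
        code <- switch(tis, lung = ROI_LUNG, bone = ROI_BONE, soft = ROI_SOFT)
        idx <- which(roi == code)
        vox[idx] <- spec@huMean[tis] + spec@huSD[tis] * rnorm(length(idx))
    }
    vox <- pmin(pmax(vox, -1000), 1500)
    list(ct = HUVolume(vox, spacing = spec@spacing), roi = roi)
}

## World-coordinate helpers for artifact fields (mm, in-plane).
planeCoords <- function(shape, spacing) {
    x <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing[1]
    y <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing[2]
    list(X = matrix(x, shape[1], shape[2]),
         Y = matrix(y, shape[1], shape[2], byrow = TRUE))
}

#' Simulate a low-dose CBCT from a CT volume
#'
#' Applies the additive artifact model of \linkS4class{ArtifactSpec} to a CT
#' volume: lung HU depression, radial cupping, per-slice streaks, one-sided
#' shading and white noise, followed by a clip to [-1000, 1500] HU. Each
#' component draws from its own derived seed, so zeroing one amplitude never
#' changes the randomness of the others, and a zero-valued spec returns the
#' input bit-exactly.
#'
#' @param ct an \linkS4class{HUVolume}.
#' @param spec an \linkS4class{ArtifactSpec}.
#' @param roi integer label array as produced by \code{\link{generatePhantom}};
#'   required when \code{lungShift != 0} (identifies the lung ROI) and used to
#'   restrict cupping/shading to the body.
#' @param returnComponents if TRUE also return the individual additive fields.
#' @return an \linkS4class{HUVolume}, or (with \code{returnComponents}) a list
#'   with \code{cbct}, \code{components} (named list of delta arrays) and
#'   \code{composite} (their sum, before clipping).
#' @export
simulateCBCT <- function(ct, spec, roi = NULL, returnComponents = FALSE) {
    stopifnot(is(ct, "HUVolume"), is(spec, "ArtifactSpec"))
    shape <- dim(ct@voxels)
    if (spec@lungShift != 0 && is.null(roi))
        stop("roi labels are required when lungShift is non-zero")
    body <- if (is.null(roi)) array(TRUE, shape) else roi != ROI_AIR
    comp <- list()

    comp$lung <- array(0, shape)
    if (spec@lungShift != 0)
        comp$lung[roi == ROI_LUNG] <- spec@lungShift

    comp$cupping <- array(0, shape)
    if (spec@cuppingAmp != 0) {
        pc <- planeCoords(shape, ct@spacing)
        bodyAny <- apply(body, c(1, 2), any)
        aEff <- max(abs(pc$X[bodyAny])); bEff <- max(abs(pc$Y[bodyAny]))
        rr <- sqrt((pc$X / aEff)^2 + (pc$Y / bEff)^2)
        rr <- pmin(rr / spec@cuppingWidth, 1)
        field <- -spec@cuppingAmp / 2 * (1 - cos(pi * rr))
        comp$cupping <- array(rep(field, shape[3]), shape) * body
    }

    comp$streaks <- array(0, shape)
    if (spec@streakCount > 0L && spec@streakAmp != 0) {
        set.seed(spec@seed %% 2100000000L + 1L)
        pc <- planeCoords(shape, ct@spacing)
        for (k in seq_len(shape[3])) {
            sl <- matrix(0, shape[1], shape[2])
            for (s in seq_len(spec@streakCount)) {
                th <- runif(1, 0, 2 * pi)
                sgn <- sample(c(-1, 1), 1)
                d <- -sin(th) * pc$X + cos(th) * pc$Y
                sl <- sl + sgn * spec@streakAmp *
                    exp(-d^2 / (2 * spec@streakWidth^2))
            }
            comp$streaks[, , k] <- sl
        }
    }

    comp$shading <- array(0, shape)
    if (spec@shadingAmp != 0) {
        set.seed(spec@seed %% 2100000000L + 2L)
        phi <- runif(1, 0, 2 * pi)
        pc <- planeCoords(shape, ct@spacing)
        proj <- cos(phi) * pc$X + sin(phi) * pc$Y
        proj <- (proj - min(proj)) / (max(proj) - min(proj))
        comp$shading <- array(rep(-spec@shadingAmp * proj, shape[3]),
                              shape) * body
    }

    comp$noise <- array(0, shape)
    if (spec@noiseSD > 0) {
        set.seed(spec@seed %% 2100000000L + 3L)
        comp$noise <- array(rnorm(prod(shape), 0, spec@noiseSD), shape)
    }

    composite <- Reduce(`+`, comp)
    vox <- pmin(pmax(ct@voxels + composite, -1000), 1500)
    cbct <- HUVolume(vox, spacing = ct@spacing, origin = ct@origin)
    if (returnComponents)
        list(cbct = cbct, components = comp, composite = composite)
    else cbct
}

#' Generate an aligned synthetic CT/CBCT dataset on disk
#'
#' Writes \code{n} phantom CT volumes, their simulated CBCT counterparts and
#' ROI label volumes as NIfTI files plus a plain-text manifest, split into
#' training and test subsets. Per-volume anatomy jitter and artifact
#' randomness are derived from \code{seed}, so the whole dataset is
#' reproducible bit-for-bit.
#'
#' @param outDir output directory (created if needed).
#' @param n number of volume pairs (>= 1).
#' @param phantom a \linkS4class{PhantomSpec} template.
#' @param artifacts an \linkS4class{ArtifactSpec} template.
#' @param seed integer master seed.
#' @param paired if TRUE the manifest links CT_i to CBCT_i via \code{pair_id};
#'   if FALSE the two pools are listed without linkage.
#' @param testFraction fraction of volumes held out as the test split.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest as a data.frame (columns id, role, split, path, seed,
#'   pair_id), invisibly also written to \code{outDir/manifest.tsv}.
#' @export
makeDataset <- function(outDir, n, phantom = phantomSpec(),
                        artifacts = artifactSpec(), seed = 1L,
                        paired = TRUE, testFraction = 0.2,
                        overwrite = FALSE) {
    stopifnot(n >= 1)
    if (dir.exists(outDir) && length(dir(outDir)) > 0 && !overwrite)
        stop("output directory ", outDir,
             " is not empty; use overwrite = TRUE")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    vseeds <- sample.int(.Machine$integer.max - 1L, n)
    aseeds <- sample.int(.Machine$integer.max - 1L, n)
    nTest <- if (n > 1 && testFraction > 0)
        max(1L, round(n * testFraction)) else 0L
    splits <- c(rep("train", n - nTest), rep("test", nTest))
    rows <- list()
    for (i in seq_len(n)) {
        ps <- phantom; ps@seed <- vseeds[i]
        as <- artifacts; as@seed <- aseeds[i]
        ph <- generatePhantom(ps)
        cbct <- simulateCBCT(ph$ct, as, roi = ph$roi)
        paths <- file.path(outDir, sprintf("vol%03d_%s.nii.gz", i,
                                           c("ct", "cbct", "roi")))
        writeVolume(ph$ct, paths[1])
        writeVolume(cbct, paths[2])
        writeVolume(HUVolume(ph$roi * 1.0, spacing = ps@spacing), paths[3])
        pid <- if (paired) sprintf("pair%03d", i) else NA_character_
        rows[[i]] <- data.frame(
            id = sprintf("vol%03d_%s", i, c("ct", "cbct", "roi")),
            role = c("ct", "cbct", "roi"), split = splits[i],
            path = basename(paths),
            seed = c(vseeds[i], aseeds[i], vseeds[i]),
            pair_id = c(pid, pid, pid), stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$path <- file.path(outDir, manifest$path)
    manifest
}

#' Read a dataset manifest written by makeDataset
#' @param path the manifest file or its directory.
#' @return data.frame with absolute paths.
#' @export
readManifest <- function(path) {
    if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
    if (!file.exists(path)) stop("manifest not found: ", path)
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    m$path <- file.path(dirname(path), m$path)
    m
}

#' Synthesize a smooth radially symmetric dose grid
#'
#' Test input for gamma analysis: a dose field peaking at the target center
#' with value \code{prescription * (1 + hotspot)}, a plateau decaying to the
#' prescription at the target radius, and a Gaussian falloff outside. The
#' field is non-negative, deterministic and radially symmetric about the
#' target center.
#'
#' @param shape integer(3) grid dimensions.
#' @param spacing,origin grid geometry (mm).
#' @param targetCenter numeric(3) world coordinates of the target (mm).
#' @param targetRadius target radius in mm.
#' @param prescription prescription dose in cGy (default 5000).
#' @param hotspot relative peak excess at the center (default 0.05).
#' @param falloff Gaussian falloff sigma outside the target, mm.
#' @return a \linkS4class{DoseGrid}.
#' @export
synthesizeDose <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           targetCenter, targetRadius, prescription = 5000,
                           hotspot = 0.05, falloff = 20) {
    shape <- as.integer(shape)
    upper <- origin + (shape - 1L) * spacing
    if (any(targetCenter < origin) || any(targetCenter > upper))
        stop("target center lies outside the dose grid")
    ax <- lapply(1:3, function(a)
        origin[a] + (seq_len(shape[a]) - 1) * spacing[a] - targetCenter[a])
    r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
    dose <- ifelse(r <= targetRadius,
        prescription * (1 + hotspot * (0.5 + 0.5 * cos(pi * r / targetRadius))),
        prescription * exp(-(r - targetRadius)^2 / (2 * falloff^2)))
    DoseGrid(array(dose, shape), spacing = spacing, origin = origin)
}
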