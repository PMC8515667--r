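# Shared fixtures: everything is generated in code at test time.

# Small thorax phantom for fast tests.
tinySpec <- function(seed = 1L, jitter = 0.05, nz = 3L)
    phantomSpec(shape = c(32L, 32L, nz), spacing = c(12, 12, 10),
                seed = seed, jitter = jitter)

# Tiny generator/discriminator configurations: full architecture shape,
# minimal widths.
tinyGenConfig <- function(nMasks = 4L, attention = TRUE)
    generatorConfig(nMasks = nMasks, encoderChannels = c(2L, 3L, 4L),
                    nResBlocks = 1L, attention = attention)

tinyDiscConfig <- function() discriminatorConfig(baseChannels = 4L,
                                                 nLayers = 2L)

randomHUVolume <- function(dim = c(6L, 5L, 4L), seed = 1L,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    set.seed(seed)
    HUVolume(array(runif(prod(dim), -1000, 1500), dim),
             spacing = spacing, origin = origin)
}

# Random simplex mask stack for composition tests.
randomMaskStack <- function(h = 4L, w = 4L, n = 10L) {
    att <- array(runif(h * w * n), c(h, w, n))
    s <- apply(att, c(1, 2), sum)
    att <- att / array(s, c(h, w, n))
    maskStack(array(runif(h * w * (n - 1), -1, 1), c(h, w, n - 1L)), att)
}

# Vectorized trilinear interpolation oracle used by gamma tests (independent
# of the C++ implementation path).
trilinearR <- function(vol, px, py, pz, spacing, origin) {
    d <- dim(vol)
    fx <- (px - origin[1]) / spacing[1]
    fy <- (py - origin[2]) / spacing[2]
    fz <- (pz - origin[3]) / spacing[3]
    x0 <- pmin(pmax(floor(fx), 0), max(d[1] - 2, 0))
    y0 <- pmin(pmax(floor(fy), 0), max(d[2] - 2, 0))
    z0 <- pmin(pmax(floor(fz), 0), max(d[3] - 2, 0))
    dx <- fx - x0; dy <- fy - y0; dz <- fz - z0
    nx <- as.integer(d[1] > 1); ny <- as.integer(d[2] > 1)
    nz <- as.integer(d[3] > 1)
    at <- function(i, j, k) vol[cbind(i + 1, j + 1, k + 1)]
    c00 <- at(x0, y0, z0) * (1 - dx) + at(x0 + nx, y0, z0) * dx
    c10 <- at(x0, y0 + ny, z0) * (1 - dx) + at(x0 + nx, y0 + ny, z0) * dx
    c01 <- at(x0, y0, z0 + nz) * (1 - dx) + at(x0 + nx, y0, z0 + nz) * dx
    c11 <- at(x0, y0 + ny, z0 + nz) * (1 - dx) +
        at(x0 + nx, y0 + ny, z0 + nz) * dx
    (c00 * (1 - dy) + c10 * dy) * (1 - dz) +
        (c01 * (1 - dy) + c11 * dy) * dz
}

# Full-search gamma oracle over an explicit offset set (no early exit).
gammaOracle <- function(ref, ev, dta, doseDiffPct, step, radius) {
    k <- floor(radius / step + 1e-9)
    s <- (-k:k) * step
    off <- as.matrix(expand.grid(s, s, s))
    off <- off[rowSums(off^2) <= radius^2 + 1e-9, , drop = FALSE]
    dd <- doseDiffPct / 100 * max(voxels(ref))
    d <- dim(voxels(ref))
    rd <- as.numeric(voxels(ref))
    ax <- lapply(1:3, function(a)
        origin(ref)[a] + (seq_len(d[a]) - 1) * spacing(ref)[a])
    pos <- cbind(rep(ax[[1]], times = d[2] * d[3]),
                 rep(rep(ax[[2]], each = d[1]), times = d[3]),
                 rep(ax[[3]], each = d[1] * d[2]))
    lo <- origin(ev) - 1e-9
    hi <- origin(ev) + (dim(voxels(ev)) - 1) * spacing(ev) + 1e-9
    g <- numeric(length(rd))
    for (i in seq_along(rd)) {
        q1 <- pos[i, 1] + off[, 1]
        q2 <- pos[i, 2] + off[, 2]
        q3 <- pos[i, 3] + off[, 3]
        ok <- q1 >= lo[1] & q1 <= hi[1] & q2 >= lo[2] & q2 <= hi[2] &
            q3 >= lo[3] & q3 <= hi[3]
        de <- trilinearR(voxels(ev), q1[ok], q2[ok], q3[ok],
                         spacing(ev), origin(ev))
        g2 <- rowSums(off[ok, , drop = FALSE]^2) / dta^2 +
            (de - rd[i])^2 / dd^2
        g[i] <- sqrt(min(g2))
    }
    dim(g) <- d
    g
}
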