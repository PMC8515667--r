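## Image-quality evaluation in HU: MAE, slice-wise Gaussian-window SSIM,
## PSNR, ROI statistics, histograms and paired Wilcoxon comparisons.

checkSameGeometry <- function(a, b) {
    if (!identical(dim(a@voxels), dim(b@voxels)) ||
        max(abs(a@spacing - b@spacing)) > 1e-6 ||
        max(abs(a@origin - b@origin)) > 1e-6)
        stop("volume geometries do not match")
}

#' Mean absolute error between two volumes (HU)
#'
#' @param reference,test \linkS4class{HUVolume}s on identical geometry.
#' @param mask optional logical array restricting the evaluation region.
#' @return mean |test - reference| in HU.
#' @export
maeHU <- function(reference, test, mask = NULL) {
    checkSameGeometry(reference, test)
    d <- abs(test@voxels - reference@voxels)
    if (is.null(mask)) return(mean(d))
    if (!any(mask)) stop("empty evaluation mask")
    mean(d[mask])
}

gaussKernel <- function(size, sigma) {
    x <- seq_len(size) - (size + 1) / 2
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

## Band matrix applying a 1D kernel over valid positions (no padding).
bandMatrix <- function(n, kernel) {
    k <- length(kernel)
    nv <- n - k + 1L
    if (nv < 1L) stop("image smaller than the SSIM window (", k, ")")
    B <- matrix(0, nv, n)
    for (i in seq_len(nv)) B[i, i + seq_len(k) - 1L] <- kernel
    B
}

ssimSlice <- function(X, Y, C1, C2, kernel) {
    Bh <- bandMatrix(nrow(X), kernel)
    Bw <- bandMatrix(ncol(X), kernel)
    mux <- Bh %*% X %*% t(Bw)
    muy <- Bh %*% Y %*% t(Bw)
    sxx <- Bh %*% (X * X) %*% t(Bw) - mux * mux
    syy <- Bh %*% (Y * Y) %*% t(Bw) - muy * muy
    sxy <- Bh %*% (X * Y) %*% t(Bw) - mux * muy
    num <- (2 * mux * muy + C1) * (2 * sxy + C2)
    den <- (mux^2 + muy^2 + C1) * (sxx + syy + C2)
    mean(num / den)
}

#' Structural similarity index between two volumes
#'
#' Computed slice-wise on axial planes with an 11x11 Gaussian window
#' (sigma 1.5) over the valid interior, using the standard stabilizing
#' constants C1 = (K1 L)^2, C2 = (K2 L)^2 with L the declared data range,
#' then averaged over slices. The default data range is 2500 HU (the clipped
#' CT dynamic range).
#'
#' @param reference,test \linkS4class{HUVolume}s on identical geometry.
#' @param dataRange dynamic range L (default 2500 HU).
#' @param windowSize,windowSigma Gaussian window parameters (11, 1.5).
#' @param K1,K2 stabilizing constants (0.01, 0.03).
#' @return SSIM in [-1, 1]; 1 for identical volumes.
#' @export
ssimHU <- function(reference, test, dataRange = 2500, windowSize = 11L,
                   windowSigma = 1.5, K1 = 0.01, K2 = 0.03) {
    checkSameGeometry(reference, test)
    C1 <- (K1 * dataRange)^2
    C2 <- (K2 * dataRange)^2
    kernel <- gaussKernel(windowSize, windowSigma)
    vals <- vapply(seq_len(dim(reference@voxels)[3]), function(k)
        ssimSlice(reference@voxels[, , k], test@voxels[, , k], C1, C2,
                  kernel), numeric(1))
    mean(vals)
}

#' Peak signal-to-noise ratio between two volumes (dB)
#'
#' 20 log10(L / sqrt(MSE)) with L the declared data range (default 2500 HU).
#' Identical volumes (MSE = 0) yield \code{Inf}.
#'
#' @inheritParams ssimHU
#' @return PSNR in dB, possibly infinite.
#' @export
psnrHU <- function(reference, test, dataRange = 2500) {
    checkSameGeometry(reference, test)
    mse <- mean((test@voxels - reference@voxels)^2)
    if (mse == 0) return(Inf)
    20 * log10(dataRange / sqrt(mse))
}

#' Per-ROI HU mean and standard deviation
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param roi integer label array (same shape).
#' @param labels named integer vector of requested ROI labels
#'   (default lung = 1, bone = 2, soft = 3).
#' @return data.frame with columns roi, label, mean, sd (population SD), n.
#' @export
roiStats <- function(vol, roi, labels = c(lung = 1L, bone = 2L, soft = 3L)) {
    stopifnot(identical(dim(vol@voxels), dim(roi)))
    out <- lapply(seq_along(labels), function(i) {
        v <- vol@voxels[roi == labels[i]]
        if (length(v) == 0L)
            stop("ROI label ", labels[i], " (", names(labels)[i],
                 ") has no voxels")
        data.frame(roi = names(labels)[i], label = labels[i],
                   mean = mean(v),
                   sd = sqrt(mean((v - mean(v))^2)), n = length(v))
    })
    do.call(rbind, out)
}

#' HU histogram of a volume
#'
#' Uniform bins over a stated range; counts sum to the voxel count.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param binWidth bin width in HU (> 0).
#' @param range numeric(2) covering all voxel values.
#' @return list with \code{edges} (length nbins + 1) and \code{counts}.
#' @export
huHistogram <- function(vol, binWidth = 25, range = c(-1000, 1500)) {
    if (binWidth <= 0) stop("bin width must be positive")
    x <- vol@voxels
    if (min(x) < range[1] || max(x) > range[2])
        stop("histogram range does not cover the data")
    edges <- seq(range[1], range[2] + binWidth * 0.999999, by = binWidth)
    if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    list(edges = edges,
         counts = tabulate(idx, nbins = length(edges) - 1L))
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Standard signed-rank test on paired differences: exact null enumeration
#' for small samples without ties, normal approximation with tie/zero
#' corrections otherwise. All-zero differences are flagged degenerate (the
#' test carries no signal).
#'
#' @param a,b equal-length paired samples.
#' @param alpha significance level (default 0.05).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list with \code{statistic} (V), \code{p}, \code{significant} and
#'   \code{degenerate}.
#' @export
pairedWilcoxon <- function(a, b, alpha = 0.05, alternative = "two.sided") {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    if (all(d == 0))
        return(list(statistic = NA_real_, p = NA_real_, significant = FALSE,
                    degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              alternative = alternative))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         significant = wt$p.value < alpha, degenerate = FALSE)
}

#' Full image-quality report for one volume pair
#'
#' @param reference,test \linkS4class{HUVolume}s on identical geometry.
#' @param roi optional label array for ROI statistics.
#' @param dataRange dynamic range used by SSIM/PSNR; recorded in the report.
#' @return a \code{trialMetrics} list: mae, ssim, psnr, roi (data.frame or
#'   NULL), histogram, dataRange.
#' @export
evaluateVolumes <- function(reference, test, roi = NULL, dataRange = 2500) {
    res <- list(mae = maeHU(reference, test),
                ssim = ssimHU(reference, test, dataRange = dataRange),
                psnr = psnrHU(reference, test, dataRange = dataRange),
                roi = if (!is.null(roi)) roiStats(test, roi) else NULL,
                histogram = huHistogram(test),
                dataRange = dataRange)
    class(res) <- "trialMetrics"
    res
}

#' Cohort table of per-volume metrics with a mean +/- SD summary row
#'
#' @param metricsList list of \code{trialMetrics} (one per volume).
#' @param ids optional volume identifiers.
#' @return data.frame with one row per volume plus a "summary" row; the
#'   summary SD is across volumes, not voxels.
#' @export
cohortTable <- function(metricsList, ids = seq_along(metricsList)) {
    df <- data.frame(
        id = as.character(ids),
        mae = vapply(metricsList, `[[`, numeric(1), "mae"),
        ssim = vapply(metricsList, `[[`, numeric(1), "ssim"),
        psnr = vapply(metricsList, `[[`, numeric(1), "psnr"))
    num <- df[, c("mae", "ssim", "psnr")]
    rbind(df,
          data.frame(id = "mean", mae = mean(num$mae), ssim = mean(num$ssim),
                     psnr = mean(num$psnr)),
          data.frame(id = "sd", mae = stats::sd(num$mae),
                     ssim = stats::sd(num$ssim), psnr = stats::sd(num$psnr)))
}
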