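## 3D gamma-index dose comparison: per reference voxel, the minimum combined
## spatial (distance-to-agreement) and dosimetric discrepancy over candidate
## positions in the evaluated distribution.

gammaOffsets <- function(step, radius) {
    k <- floor(radius / step + 1e-9)
    s <- (-k:k) * step
    off <- as.matrix(expand.grid(x = s, y = s, z = s))
    n2 <- rowSums(off^2)
    keep <- n2 <= radius^2 + 1e-9
    off <- off[keep, , drop = FALSE]
    n2 <- n2[keep]
    ord <- order(n2)
    list(offsets = off[ord, , drop = FALSE], norm2 = n2[ord])
}

worldPositions <- function(vol) {
    d <- dim(vol@voxels)
    ax <- lapply(1:3, function(a)
        vol@origin[a] + (seq_len(d[a]) - 1) * vol@spacing[a])
    cbind(rep(ax[[1]], times = d[2] * d[3]),
          rep(rep(ax[[2]], each = d[1]), times = d[3]),
          rep(ax[[3]], each = d[1] * d[2]))
}

#' 3D gamma-index map
#'
#' For every reference voxel r, Gamma(r) is the minimum over candidate
#' positions r' (a regular sub-voxel grid of world-space offsets within the
#' search radius, evaluated dose obtained by trilinear interpolation) of
#' sqrt(|r' - r|^2 / dta^2 + (D_e(r') - D_r(r))^2 / dD^2). With the default
#' global normalization dD is \code{doseDiff}% of the maximum reference
#' dose; with local normalization it is \code{doseDiff}% of the local
#' reference dose. Candidates are visited in order of increasing distance,
#' so the spatial term bounds the remaining search exactly (the result
#' equals an exhaustive search over the same candidate set). The two grids
#' may differ in geometry; candidate positions outside the evaluated grid
#' are skipped.
#'
#' @param reference,evaluated \linkS4class{DoseGrid}s.
#' @param criteria a \linkS4class{GammaCriteria}.
#' @param stepFactor candidate grid step as a fraction of dta (default 0.1).
#' @param radiusFactor search radius as a multiple of dta (default 3).
#' @param step,radius explicit overrides in mm (take precedence; a shared
#'   candidate grid across criteria makes passing rates exactly nested).
#' @return 3D array of gamma values on the reference grid, with the criteria
#'   and search parameters attached as attributes.
#' @export
gammaIndexMap <- function(reference, evaluated, criteria,
                          stepFactor = 0.1, radiusFactor = 3,
                          step = NULL, radius = NULL) {
    stopifnot(is(reference, "DoseGrid"), is(evaluated, "DoseGrid"),
              is(criteria, "GammaCriteria"))
    maxref <- max(reference@voxels)
    if (maxref <= 0) stop("reference distribution has zero maximum dose")
    if (is.null(step)) step <- stepFactor * criteria@dta
    if (is.null(radius)) radius <- radiusFactor * criteria@dta
    refdose <- as.numeric(reference@voxels)
    deltaD <- if (criteria@normalization == "global")
        rep(criteria@doseDiff / 100 * maxref, length(refdose))
    else criteria@doseDiff / 100 * refdose
    grid <- gammaOffsets(step, radius)
    g <- cpp_gamma_search(refdose, worldPositions(reference),
                          as.numeric(evaluated@voxels),
                          dim(evaluated@voxels), evaluated@spacing,
                          evaluated@origin, grid$offsets, grid$norm2,
                          criteria@dta, deltaD)
    dim(g) <- dim(reference@voxels)
    attr(g, "criteria") <- criteria
    attr(g, "search") <- c(step = step, radius = radius)
    g
}

#' Gamma passing rate
#'
#' 100 * #(above-threshold voxels with Gamma <= 1) / #(above-threshold
#' voxels); the low-dose threshold is the criteria's percentage of the
#' maximum reference dose.
#'
#' @param gammaValues array from \code{\link{gammaIndexMap}}.
#' @param reference the reference \linkS4class{DoseGrid}.
#' @param criteria the \linkS4class{GammaCriteria} used.
#' @return passing rate in percent.
#' @export
gammaPassingRate <- function(gammaValues, reference, criteria) {
    thr <- criteria@threshold / 100 * max(reference@voxels)
    keep <- reference@voxels >= thr
    if (!any(keep)) stop("no voxels above the low-dose threshold")
    100 * mean(gammaValues[keep] <= 1 + 1e-9)
}

#' Passing rates under several criteria on a shared candidate grid
#'
#' Computes gamma maps for each criteria set using one candidate grid (step
#' from the smallest dta, radius from the largest), which makes the rates
#' exactly nested: loosening from 1 mm/1% to 2 mm/2% to 3 mm/3% can only
#' raise the passing rate.
#'
#' @param reference,evaluated \linkS4class{DoseGrid}s.
#' @param criteriaList list of \linkS4class{GammaCriteria}.
#' @param stepFactor,radiusFactor search parameters, interpreted against the
#'   smallest/largest dta in the list.
#' @return data.frame with columns dta, doseDiff, threshold, passingRate.
#' @export
gammaPassingRates <- function(reference, evaluated, criteriaList,
                              stepFactor = 0.1, radiusFactor = 3) {
    dtas <- vapply(criteriaList, function(cr) cr@dta, numeric(1))
    step <- stepFactor * min(dtas)
    radius <- radiusFactor * max(dtas)
    rows <- lapply(criteriaList, function(cr) {
        g <- gammaIndexMap(reference, evaluated, cr, step = step,
                           radius = radius)
        data.frame(dta = cr@dta, doseDiff = cr@doseDiff,
                   threshold = cr@threshold,
                   passingRate = gammaPassingRate(g, reference, cr))
    })
    do.call(rbind, rows)
}

#' Relative dose-difference map
#'
#' (evaluated - reference) / max(reference), signed, on the reference grid.
#'
#' @param reference,evaluated \linkS4class{DoseGrid}s on identical geometry.
#' @return 3D array of signed fractional differences.
#' @export
relativeDoseDifference <- function(reference, evaluated) {
    checkSameGeometry(reference, evaluated)
    maxref <- max(reference@voxels)
    if (maxref <= 0) stop("reference distribution has zero maximum dose")
    (evaluated@voxels - reference@voxels) / maxref
}
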