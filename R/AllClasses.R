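#' @import methods
#' @importFrom stats rnorm runif sd quantile
#' @useDynLib sctgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' HUVolume: a 3D scalar grid in Hounsfield units
#'
#' Container for an axis-aligned CT-like volume. Voxels are stored column-major
#' with dimensions (x, y, z); the axial plane is the (x, y) plane orthogonal to
#' z. Physical position of voxel (i, j, k) (0-based) is
#' \code{origin + c(i, j, k) * spacing} in mm.
#'
#' @slot voxels 3D numeric array of HU values, all finite.
#' @slot spacing numeric(3), voxel spacing in mm (x, y, z), strictly positive.
#' @slot origin numeric(3), world coordinate of voxel (0, 0, 0) in mm.
#'
#' @examples
#' v <- HUVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2.5))
#' spacing(v)
#' @export
setClass("HUVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"),
    prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("HUVolume", function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
        msg <- c(msg, "voxels must be a 3D array")
    if (!all(is.finite(object@voxels)))
        msg <- c(msg, "all voxel values must be finite")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite numbers")
    if (length(msg)) msg else TRUE
})

#' @param voxels 3D numeric array (HU).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world position of the first voxel in mm.
#' @rdname HUVolume-class
#' @export
HUVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("HUVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' DoseGrid: a 3D radiation dose distribution
#'
#' Same geometry conventions as \linkS4class{HUVolume}; values are absorbed
#' dose in cGy and must be non-negative.
#'
#' @slot voxels 3D numeric array of dose values (cGy).
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @export
setClass("DoseGrid", contains = "HUVolume")

setValidity("DoseGrid", function(object) {
    if (any(object@voxels < 0)) "dose values must be non-negative" else TRUE
})

#' @param voxels 3D non-negative numeric array (cGy).
#' @param spacing,origin geometry, as for \code{HUVolume}.
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("DoseGrid", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' SliceStack: normalized axial slices of a volume at training resolution
#'
#' Slices live in [-1, 1] at a square training resolution, together with the
#' reassembly metadata (original in-plane grid and geometry) needed by
#' \code{\link{slicesToVolume}}.
#'
#' @slot slices 3D array (size, size, nSlices) with values in [-1, 1].
#' @slot origDim integer(3), the source volume dimensions.
#' @slot spacing,origin source volume geometry (mm).
#' @slot indices integer vector of 1-based axial slice indices.
#' @export
setClass("SliceStack",
    representation(slices = "array", origDim = "integer", spacing = "numeric",
                   origin = "numeric", indices = "integer"))

setValidity("SliceStack", function(object) {
    msg <- character()
    d <- dim(object@slices)
    if (length(d) != 3L) msg <- c(msg, "slices must be a 3D array")
    if (max(abs(object@slices)) > 1 + 1e-12)
        msg <- c(msg, "slice values must lie in [-1, 1]")
    if (length(d) == 3L && d[3] != length(object@indices))
        msg <- c(msg, "one index per slice required")
    if (anyDuplicated(object@indices))
        msg <- c(msg, "slice indices must be unique")
    if (length(msg)) msg else TRUE
})

#' MaskStack: content and attention masks of the attention-guided generator
#'
#' The generator emits n - 1 candidate content images (bounded to [-1, 1]) and
#' n attention masks forming a per-pixel simplex (non-negative, summing to 1
#' across channels). One designated background channel preserves the input
#' image in the composition.
#'
#' @slot content 3D array (H, W, n - 1), values in [-1, 1].
#' @slot attention 3D array (H, W, n), per-pixel channel simplex.
#' @slot background integer, 1-based index of the background attention channel.
#' @export
setClass("MaskStack",
    representation(content = "array", attention = "array",
                   background = "integer"))

setValidity("MaskStack", function(object) {
    msg <- character()
    dc <- dim(object@content); da <- dim(object@attention)
    if (length(dc) != 3L || length(da) != 3L)
        return("content and attention must be 3D arrays")
    if (any(dc[1:2] != da[1:2]))
        msg <- c(msg, "content and attention spatial shapes must agree")
    if (da[3] != dc[3] + 1L)
        msg <- c(msg, "attention must have one more channel than content")
    if (min(object@attention) < -1e-8)
        msg <- c(msg, "attention masks must be non-negative")
    s <- rowSums(matrix(object@attention, prod(da[1:2]), da[3]))
    if (max(abs(s - 1)) > 1e-6)
        msg <- c(msg, "attention channels must sum to 1 per pixel")
    if (max(abs(object@content)) > 1 + 1e-8)
        msg <- c(msg, "content masks must lie in [-1, 1]")
    if (object@background < 1L || object@background > da[3])
        msg <- c(msg, "background index out of range")
    if (length(msg)) msg else TRUE
})

#' @param content (H, W, n-1) array in [-1, 1].
#' @param attention (H, W, n) array, per-pixel simplex over channels.
#' @param background 1-based background channel index (default: last).
#' @rdname MaskStack-class
#' @export
maskStack <- function(content, attention,
                      background = dim(attention)[3]) {
    new("MaskStack", content = content, attention = attention,
        background = as.integer(background))
}

#' PhantomSpec: geometry and tissue statistics of the digital thorax phantom
#'
#' Defaults emulate a thoracic CT: an elliptical body of soft tissue holding
#' two lungs, a spinal column and rib cross-sections, with per-tissue mean HU
#' taken from CT measurements of a thorax phantom (lung -755, bone 716.2, soft
#' tissue -27.5 HU). Geometry fields are fractions of the in-plane field of
#' view so the same spec scales across grid sizes.
#'
#' @slot shape integer(3) grid dimensions (x, y, z).
#' @slot spacing numeric(3) mm.
#' @slot bodyAxes numeric(2), body ellipse semi-axes as FOV fractions.
#' @slot lungAxes numeric(2), per-lung ellipse semi-axes (FOV fractions).
#' @slot lungCenters 2x2 matrix of lung center offsets (FOV fractions).
#' @slot spineRadius,ribRadius numeric, bone site radii (FOV fractions).
#' @slot huMean,huSD named numeric(3) for lung, bone, soft tissue (HU).
#' @slot jitter numeric, relative anatomy perturbation between volumes.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
    representation(shape = "integer", spacing = "numeric",
                   bodyAxes = "numeric", lungAxes = "numeric",
                   lungCenters = "matrix", spineRadius = "numeric",
                   ribRadius = "numeric", huMean = "numeric", huSD = "numeric",
                   jitter = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape[1:2] < 8L) ||
        object@shape[3] < 1L)
        msg <- c(msg, "shape must be (nx >= 8, ny >= 8, nz >= 1)")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    need <- c("lung", "bone", "soft")
    if (!all(need %in% names(object@huMean)) ||
        !all(need %in% names(object@huSD)))
        msg <- c(msg, "huMean and huSD need entries lung, bone, soft")
    else {
        if (any(object@huMean[need] < -1000) || any(object@huMean[need] > 1500))
            msg <- c(msg, "tissue HU means must lie in [-1000, 1500]")
        if (any(object@huSD[need] < 0)) msg <- c(msg, "huSD must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @param shape,spacing,bodyAxes,lungAxes,lungCenters,spineRadius,ribRadius
#'   geometry; see slot documentation.
#' @param huMean,huSD named numeric(3) tissue HU statistics.
#' @param jitter relative anatomy perturbation applied per volume (default 5%).
#' @param seed RNG seed.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(shape = c(64L, 64L, 6L), spacing = c(6, 6, 10),
                        bodyAxes = c(0.44, 0.32),
                        lungAxes = c(0.13, 0.18),
                        lungCenters = rbind(c(-0.185, -0.02), c(0.185, -0.02)),
                        spineRadius = 0.05, ribRadius = 0.02,
                        huMean = c(lung = -755, bone = 716.2, soft = -27.5),
                        huSD = c(lung = 45, bone = 80, soft = 30),
                        jitter = 0.05, seed = 1L) {
    new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
        bodyAxes = bodyAxes, lungAxes = lungAxes, lungCenters = lungCenters,
        spineRadius = spineRadius, ribRadius = ribRadius,
        huMean = huMean, huSD = huSD, jitter = jitter, seed = as.integer(seed))
}

#' ArtifactSpec: additive CBCT artifact model
#'
#' Each component is independently switchable and additive in HU before the
#' final clip to [-1000, 1500]: a uniform HU shift inside the lungs (scatter
#'-driven HU depression), a radial cupping field (raised-cosine darkening
#' towards the body edge), angularly narrow streaks, a one-sided directional
#' shading field, and white Gaussian noise. A zero-valued spec is the identity
#' transform. Defaults are calibrated so the default phantom's lung mean lands
#' near -900 HU, matching CBCT measurements of the same phantom.
#'
#' @slot lungShift numeric, HU added inside the lung ROI (negative darkens).
#' @slot cuppingAmp numeric, HU amplitude of the radial cupping field.
#' @slot cuppingWidth numeric, radial profile width (fraction of body radius).
#' @slot streakCount integer, streaks per axial slice.
#' @slot streakAmp numeric, HU amplitude of streaks (signs alternate randomly).
#' @slot streakWidth numeric, streak Gaussian half-width in mm.
#' @slot shadingAmp numeric, HU amplitude of one-sided directional shading.
#' @slot noiseSD numeric, white Gaussian noise SD in HU.
#' @slot seed integer RNG seed.
#' @export
setClass("ArtifactSpec",
    representation(lungShift = "numeric", cuppingAmp = "numeric",
                   cuppingWidth = "numeric", streakCount = "integer",
                   streakAmp = "numeric", streakWidth = "numeric",
                   shadingAmp = "numeric", noiseSD = "numeric",
                   seed = "integer"))

setValidity("ArtifactSpec", function(object) {
    vals <- c(object@lungShift, object@cuppingAmp, object@cuppingWidth,
              object@streakAmp, object@streakWidth, object@shadingAmp,
              object@noiseSD)
    if (!all(is.finite(vals))) return("all amplitudes must be finite")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (object@streakCount < 0L) return("streakCount must be >= 0")
    TRUE
})

#' @param lungShift,cuppingAmp,cuppingWidth,streakCount,streakAmp,streakWidth,
#'   shadingAmp,noiseSD artifact amplitudes; see slot documentation.
#' @param seed RNG seed.
#' @rdname ArtifactSpec-class
#' @export
artifactSpec <- function(lungShift = -83, cuppingAmp = 80, cuppingWidth = 1,
                         streakCount = 10L, streakAmp = 50, streakWidth = 6,
                         shadingAmp = 40, noiseSD = 20, seed = 1L) {
    new("ArtifactSpec", lungShift = lungShift, cuppingAmp = cuppingAmp,
        cuppingWidth = cuppingWidth, streakCount = as.integer(streakCount),
        streakAmp = streakAmp, streakWidth = streakWidth,
        shadingAmp = shadingAmp, noiseSD = noiseSD, seed = as.integer(seed))
}

#' Zero-amplitude artifact spec (identity transform)
#' @param seed RNG seed (unused by the identity transform).
#' @export
zeroArtifactSpec <- function(seed = 1L) {
    artifactSpec(lungShift = 0, cuppingAmp = 0, streakCount = 0L,
                 streakAmp = 0, shadingAmp = 0, noiseSD = 0, seed = seed)
}

#' GammaCriteria: acceptance criteria for gamma-index analysis
#'
#' @slot dta distance-to-agreement in mm (> 0).
#' @slot doseDiff dose-difference criterion as percent of the normalization
#'   dose (> 0).
#' @slot threshold low-dose threshold: reference voxels below this percent of
#'   the maximum reference dose are excluded from the passing rate.
#' @slot normalization "global" (percent of maximum reference dose) or
#'   "local" (percent of the local reference dose).
#' @export
setClass("GammaCriteria",
    representation(dta = "numeric", doseDiff = "numeric",
                   threshold = "numeric", normalization = "character"))

setValidity("GammaCriteria", function(object) {
    msg <- character()
    if (object@dta <= 0) msg <- c(msg, "dta must be > 0")
    if (object@doseDiff <= 0) msg <- c(msg, "doseDiff must be > 0")
    if (object@threshold < 0 || object@threshold >= 100)
        msg <- c(msg, "threshold must lie in [0, 100)")
    if (!object@normalization %in% c("global", "local"))
        msg <- c(msg, "normalization must be 'global' or 'local'")
    if (length(msg)) msg else TRUE
})

#' @param dta mm; @param doseDiff percent; @param threshold percent of max
#'   reference dose; @param normalization "global" or "local".
#' @rdname GammaCriteria-class
#' @export
gammaCriteria <- function(dta, doseDiff, threshold = 10,
                          normalization = "global") {
    new("GammaCriteria", dta = dta, doseDiff = doseDiff,
        threshold = threshold, normalization = normalization)
}
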