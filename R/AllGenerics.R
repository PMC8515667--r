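#' @rdname HUVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname HUVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname HUVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname HUVolume-class
#' @export
setMethod("voxels", "HUVolume", function(x) x@voxels)

#' @rdname HUVolume-class
#' @export
setMethod("spacing", "HUVolume", function(x) x@spacing)

#' @rdname HUVolume-class
#' @export
setMethod("origin", "HUVolume", function(x) x@origin)

#' @rdname HUVolume-class
#' @export
setMethod("dim", "HUVolume", function(x) dim(x@voxels))

setMethod("show", "HUVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n",
                class(object), d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    cat(sprintf("  value range [%.1f, %.1f], origin (%s) mm\n",
                min(object@voxels), max(object@voxels),
                paste(format(object@origin, digits = 3), collapse = ", ")))
})

#' @rdname SliceStack-class
#' @param x a SliceStack.
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname SliceStack-class
#' @export
setMethod("slices", "SliceStack", function(x) x@slices)

#' @rdname SliceStack-class
#' @export
setMethod("length", "SliceStack", function(x) dim(x@slices)[3])

setMethod("show", "SliceStack", function(object) {
    d <- dim(object@slices)
    cat(sprintf(
        "SliceStack: %d normalized axial slices at %d x %d (source %s)\n",
        d[3], d[1], d[2], paste(object@origDim, collapse = " x ")))
})

#' @rdname MaskStack-class
#' @param x a MaskStack.
#' @export
setGeneric("contentMasks", function(x) standardGeneric("contentMasks"))

#' @rdname MaskStack-class
#' @export
setGeneric("attentionMasks", function(x) standardGeneric("attentionMasks"))

#' @rdname MaskStack-class
#' @export
setGeneric("backgroundIndex", function(x) standardGeneric("backgroundIndex"))

#' @rdname MaskStack-class
#' @export
setMethod("contentMasks", "MaskStack", function(x) x@content)

#' @rdname MaskStack-class
#' @export
setMethod("attentionMasks", "MaskStack", function(x) x@attention)

#' @rdname MaskStack-class
#' @export
setMethod("backgroundIndex", "MaskStack", function(x) x@background)

setMethod("show", "MaskStack", function(object) {
    da <- dim(object@attention)
    cat(sprintf(
        "MaskStack: %d content + %d attention channels at %d x %d (background channel %d)\n",
        dim(object@content)[3], da[3], da[1], da[2], object@background))
})

setMethod("show", "GammaCriteria", function(object) {
    cat(sprintf("GammaCriteria: %g mm / %g%% (%s normalization, %g%% low-dose threshold)\n",
                object@dta, object@doseDiff, object@normalization,
                object@threshold))
})
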