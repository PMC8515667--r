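#' Read a CT-like volume from disk
#'
#' Reads a NIfTI file (.nii or .nii.gz) into an \linkS4class{HUVolume},
#' populating spacing from the header pixdim and origin from the stored
#' transform. Only axis-aligned volumes are supported; direction cosines
#' beyond axis alignment are rejected.
#'
#' @param path path to a NIfTI file.
#' @param formatHint "auto", "nifti" or "dicom". DICOM series are not
#'   supported by this build; convert series to NIfTI first.
#' @param dose if TRUE return a \linkS4class{DoseGrid} instead.
#' @return an \linkS4class{HUVolume} (or \linkS4class{DoseGrid}).
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, formatHint = c("auto", "nifti", "dicom"),
                       dose = FALSE) {
    formatHint <- match.arg(formatHint)
    if (formatHint == "auto") {
        formatHint <- if (dir.exists(path)) "dicom" else "nifti"
    }
    if (formatHint == "dicom")
        stop("DICOM series reading is not supported; convert the series '",
             path, "' to NIfTI first")
    if (!file.exists(path)) stop("volume file not found: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
        stop("expected a 3D volume in '", path, "', got ",
             length(dim(arr)), " dimensions")
    m <- RNifti::xform(img)
    offdiag <- m[1:3, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6))
        stop("volume '", path, "' is not axis-aligned; ",
             "oblique direction cosines are not supported")
    sp <- RNifti::pixdim(img)[1:3]
    org <- m[1:3, 4]
    cls <- if (dose) DoseGrid else HUVolume
    cls(arr * 1.0, spacing = abs(sp), origin = org)
}

#' Write a volume to a NIfTI file
#'
#' @param vol an \linkS4class{HUVolume} or \linkS4class{DoseGrid}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "HUVolume"))
    img <- RNifti::asNifti(vol@voxels)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(c(vol@spacing, 1))
    m[1:3, 4] <- vol@origin
    m <- structure(m, code = 2L)
    RNifti::qform(img) <- m
    RNifti::sform(img) <- m
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Clip HU values and scale to the network domain [-1, 1]
#'
#' Values are clipped to [-1000, 1500] HU (the thoracic CT dynamic range; a
#' few pixels above 1500 HU are saturated) and affinely mapped to [-1, 1]:
#' x -> ((clip(x) + 1000) / 2500) * 2 - 1. The map is monotone and idempotent
#' after the first application of the clip.
#'
#' @param x an \linkS4class{HUVolume} or a numeric array/vector in HU.
#' @return numeric object of the same shape with values in [-1, 1].
#' @examples
#' clipAndScale(c(-1000, 250, 1500, 2000))  # -1, 0, 1, 1
#' @export
clipAndScale <- function(x) {
    if (is(x, "HUVolume")) x <- x@voxels
    stopifnot(all(is.finite(x)))
    (pmin(pmax(x, -1000), 1500) + 1000) / 2500 * 2 - 1
}

#' Map network-domain values back to Hounsfield units
#'
#' Exact inverse of \code{\link{clipAndScale}} on [-1000, 1500]:
#' y -> (y + 1) / 2 * 2500 - 1000.
#'
#' @param y numeric values in [-1, 1].
#' @return values in [-1000, 1500] HU, same shape.
#' @export
inverseScale <- function(y) {
    if (any(y < -1 - 1e-9) || any(y > 1 + 1e-9))
        stop("inverseScale input must lie in [-1, 1]")
    (pmin(pmax(y, -1), 1) + 1) / 2 * 2500 - 1000
}

## Bilinear in-plane resize with anti-aliasing when downscaling.
resizePlane <- function(x, w, h) {
    if (nrow(x) == w && ncol(x) == h) return(x)
    EBImage::resize(x, w = w, h = h, filter = "bilinear",
                    antialias = (w < nrow(x) || h < ncol(x)))
}

#' Cut a volume into normalized axial training slices
#'
#' Axial planes (orthogonal to the stored z axis) are extracted in index
#' order, resized to a square training resolution by bilinear interpolation
#' (anti-aliased when downscaling), and bundled with reassembly metadata. An
#' \linkS4class{HUVolume} input is passed through \code{\link{clipAndScale}}
#' first; a plain array input must already lie in [-1, 1].
#'
#' @param vol an \linkS4class{HUVolume}, or a normalized 3D array.
#' @param targetSize square training resolution (default 256).
#' @param spacing,origin geometry when \code{vol} is a plain array.
#' @return a \linkS4class{SliceStack}.
#' @export
volumeToSlices <- function(vol, targetSize = 256L,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is(vol, "HUVolume")) {
        spacing <- vol@spacing; origin <- vol@origin
        arr <- array(clipAndScale(vol@voxels), dim(vol@voxels))
    } else {
        arr <- vol
        if (max(abs(arr)) > 1 + 1e-9)
            stop("plain-array input to volumeToSlices must lie in [-1, 1]")
    }
    d <- dim(arr)
    if (any(d == 0L)) stop("empty volume")
    out <- array(0, c(targetSize, targetSize, d[3]))
    for (k in seq_len(d[3]))
        out[, , k] <- resizePlane(arr[, , k], targetSize, targetSize)
    out <- pmin(pmax(out, -1), 1)  # guard against interpolation overshoot
    new("SliceStack", slices = out, origDim = as.integer(d),
        spacing = as.numeric(spacing), origin = as.numeric(origin),
        indices = seq_len(d[3]))
}

#' Reassemble normalized slices into an HU volume
#'
#' Slices are resized back to the original in-plane grid (bilinear), stacked
#' in ascending slice-index order, and mapped to HU through
#' \code{\link{inverseScale}}; output values therefore always lie in
#' [-1000, 1500] HU. The slice index set must be exactly 1..n.
#'
#' @param stack a \linkS4class{SliceStack}.
#' @return an \linkS4class{HUVolume} with the source geometry.
#' @export
slicesToVolume <- function(stack) {
    stopifnot(is(stack, "SliceStack"))
    d <- stack@origDim
    idx <- stack@indices
    if (!setequal(idx, seq_len(d[3])))
        stop("slice indices must cover 1..", d[3], " exactly; missing: ",
             paste(setdiff(seq_len(d[3]), idx), collapse = ", "))
    vox <- array(0, d)
    for (j in seq_along(idx)) {
        plane <- resizePlane(stack@slices[, , j], d[1], d[2])
        vox[, , idx[j]] <- pmin(pmax(plane, -1), 1)
    }
    HUVolume(array(inverseScale(vox), d), spacing = stack@spacing,
             origin = stack@origin)
}
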