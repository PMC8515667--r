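#' Loss weights for the adversarial training objective
#'
#' @param cycle weight of the cycle-consistency term (default 10).
#' @param idt weight of the identity term (default 5).
#' @param l1Paired weight of the paired L1 term in the conditional baseline
#'   (default 100).
#' @return a \code{lossWeights} list.
#' @export
lossWeights <- function(cycle = 10, idt = 5, l1Paired = 100) {
    stopifnot(cycle >= 0, idt >= 0, l1Paired >= 0)
    structure(list(cycle = cycle, idt = idt, l1Paired = l1Paired),
              class = "lossWeights")
}

## Normalize score inputs: a numeric vector of already-reduced judgments, a
## single score map, or a list of score maps. reduce = "image" applies
## patchMean per image BEFORE the squared penalty (one judgment per image);
## reduce = "patch" penalizes each patch and averages the penalties.
scoreTerms <- function(scores, target, reduce) {
    maps <- if (is.numeric(scores) && is.null(dim(scores))) as.list(scores)
            else if (is.list(scores)) scores else list(scores)
    vapply(maps, function(s) {
        if (reduce == "image") (patchMean(s) - target)^2
        else mean((s - target)^2)
    }, numeric(1))
}

#' Least-squares discriminator loss
#'
#' (1 / 2m) * sum_i [ (D(real_i) - 1)^2 + D(fake_i)^2 ], where each D(.) is
#' the mean patch score of an image. Zero exactly when the discriminator
#' scores every real image 1 and every fake image 0.
#'
#' @param realScores,fakeScores equal-length collections of patch score maps
#'   (lists of matrices), or numeric vectors of already-reduced scores.
#' @param reduce "image" (mean patch score per image, then the squared
#'   penalty) or "patch" (squared penalty per patch, then the mean).
#' @return non-negative scalar.
#' @examples
#' lsganDLoss(1, 0)         # perfect discriminator: 0
#' lsganDLoss(0.8, 0.3)     # 0.065
#' @export
lsganDLoss <- function(realScores, fakeScores, reduce = c("image", "patch")) {
    reduce <- match.arg(reduce)
    tr <- scoreTerms(realScores, 1, reduce)
    tf <- scoreTerms(fakeScores, 0, reduce)
    if (length(tr) != length(tf))
        stop("real and fake score collections must have equal length")
    m <- length(tr)
    if (m == 0L) stop("empty score collection (m = 0)")
    sum(tr + tf) / (2 * m)
}

#' Least-squares generator adversarial loss
#'
#' (1 / 2m) * sum_i (D(fake_i) - 1)^2: zero exactly when the generator fools
#' the discriminator into scoring every fake 1.
#'
#' @inheritParams lsganDLoss
#' @param fakeScores scores of generated images.
#' @return non-negative scalar.
#' @examples
#' lsganGLoss(1)            # 0
#' lsganGLoss(c(0.4, 0.4))  # 0.18
#' @export
lsganGLoss <- function(fakeScores, reduce = c("image", "patch")) {
    reduce <- match.arg(reduce)
    tf <- scoreTerms(fakeScores, 1, reduce)
    m <- length(tf)
    if (m == 0L) stop("empty score collection (m = 0)")
    sum(tf) / (2 * m)
}

## Shared L1 form: per-image pixel mean of |a - b|, then batch mean. The
## pixel mean (not sum) keeps the loss resolution-independent.
l1Batch <- function(a, b) {
    la <- if (is.list(a)) a else list(a)
    lb <- if (is.list(b)) b else list(b)
    if (length(la) != length(lb)) stop("batch length mismatch")
    if (length(la) == 0L) stop("empty batch (m = 0)")
    terms <- mapply(function(x, y) {
        if (!identical(dim(x), dim(y))) stop("image shape mismatch")
        mean(abs(x - y))
    }, la, lb)
    mean(terms)
}

#' Cycle-consistency loss
#'
#' (1/m) * sum_i mean |recovered_i - original_i|: the round-trip translation
#' must recover the input, which is what makes unpaired training
#' well-posed.
#'
#' @param recovered,original images (matrices/arrays) or lists thereof.
#' @return non-negative scalar; 0 iff recovered == original.
#' @export
l1CycleLoss <- function(recovered, original) l1Batch(recovered, original)

#' Identity loss
#'
#' Same functional form as \code{\link{l1CycleLoss}}, applied to a generator
#' fed an image from its own target domain: G_CBCT-CT(CT) should change CT
#' as little as possible.
#'
#' @param mapped,original images or lists of images.
#' @return non-negative scalar.
#' @export
l1IdentityLoss <- function(mapped, original) l1Batch(mapped, original)

#' Per-iteration loss report
#'
#' Collects all eight per-term scalars plus the derived totals: the
#' adversarial total (sum of both discriminator and both generator
#' adversarial terms), the cycle total and the identity total.
#'
#' @param ganDCT,ganGCBCTCT,ganDCBCT,ganGCTCBCT adversarial terms.
#' @param cycleCBCT,cycleCT cycle-consistency terms.
#' @param idtCT,idtCBCT identity terms.
#' @param m batch size.
#' @return a \code{lossReport} list including \code{L_GAN}, \code{L_cycle},
#'   \code{L_idt}.
#' @export
lossReport <- function(ganDCT, ganGCBCTCT, ganDCBCT, ganGCTCBCT,
                       cycleCBCT, cycleCT, idtCT, idtCBCT, m = 1L) {
    terms <- c(ganDCT, ganGCBCTCT, ganDCBCT, ganGCTCBCT,
               cycleCBCT, cycleCT, idtCT, idtCBCT)
    if (any(terms < 0)) stop("loss terms must be non-negative")
    structure(list(
        ganDCT = ganDCT, ganGCBCTCT = ganGCBCTCT, ganDCBCT = ganDCBCT,
        ganGCTCBCT = ganGCTCBCT, cycleCBCT = cycleCBCT, cycleCT = cycleCT,
        idtCT = idtCT, idtCBCT = idtCBCT, m = m,
        L_GAN = ganDCT + ganGCBCTCT + ganDCBCT + ganGCTCBCT,
        L_cycle = cycleCBCT + cycleCT,
        L_idt = idtCT + idtCBCT), class = "lossReport")
}

#' Total training objective
#'
#' L = L_GAN + lambda_cycle * L_cycle + lambda_idt * L_idt.
#'
#' @param report a \code{\link{lossReport}} (or any list with fields
#'   \code{L_GAN}, \code{L_cycle}, \code{L_idt}).
#' @param weights a \code{\link{lossWeights}}.
#' @return scalar total loss.
#' @export
totalLoss <- function(report, weights = lossWeights()) {
    for (f in c("L_GAN", "L_cycle", "L_idt"))
        if (is.null(report[[f]])) stop("loss report missing term ", f)
    report$L_GAN + weights$cycle * report$L_cycle + weights$idt * report$L_idt
}

#' Paired conditional-GAN generator loss (baseline mode)
#'
#' Least-squares adversarial term plus a strongly weighted L1 term against
#' the paired target: lsganG(fake scores) + lambda_L1 * mean |fake - target|.
#'
#' @param fakeScores discriminator scores of the generated images.
#' @param fakeImage,targetImage the generated image(s) and the aligned paired
#'   target(s).
#' @param weights a \code{\link{lossWeights}}; uses \code{l1Paired}.
#' @param reduce patch reduction mode, as in \code{\link{lsganGLoss}}.
#' @return non-negative scalar; zero iff the discriminator is fooled exactly
#'   and the fake equals the target.
#' @export
pairedCGANLoss <- function(fakeScores, fakeImage, targetImage,
                           weights = lossWeights(),
                           reduce = c("image", "patch")) {
    lsganGLoss(fakeScores, match.arg(reduce)) +
        weights$l1Paired * l1Batch(fakeImage, targetImage)
}
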