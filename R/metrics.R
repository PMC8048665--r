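#' @include tissue-table.R utils-image.R
NULL

#' Demeaned normalised RMSE (x100)
#'
#' Whole-brain RMSE after subtracting each volume's mean within the mask,
#' normalised by the demeaned ground-truth norm and multiplied by 100.
#'
#' @param recon,truth numeric arrays on the same grid
#' @param mask logical array
#' @return scalar score
#' @export
nrmse <- function(recon, truth, mask) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty mask")
    r <- recon[m] - mean(recon[m])
    t <- truth[m] - mean(truth[m])
    den <- sqrt(sum(t^2))
    if (den == 0) stop("ground truth is constant over the mask")
    100 * sqrt(sum((r - t)^2)) / den
}

#' Detrended normalised RMSE (x100)
#'
#' The slope of a linear fit (with intercept) of reconstructed against
#' ground-truth voxel values over the ROI is estimated; the reconstruction
#' is divided by that slope, so proportionality errors (measured separately
#' by the linear-slope metric) do not inflate the RMSE. The demeaned
#' normalised RMSE of the rescaled reconstruction is then returned (x100).
#' A non-positive fitted slope is flagged: the score is computed without
#' detrending and `attr(, "detrended")` is FALSE.
#'
#' @param recon,truth numeric arrays
#' @param roiMask logical ROI (gray/white-matter "tissue", 1-voxel-dilated
#'   veins "blood", or the six-nuclei deep gray-matter mask)
#' @return scalar score with attribute `detrended`
#' @export
rmseDetrended <- function(recon, truth, roiMask) {
    m <- as.logical(roiMask)
    if (length(unique(truth[m])) < 2) stop("ROI needs >= 2 distinct truth values")
    fit <- stats::lm.fit(cbind(1, truth[m]), recon[m])
    s <- fit$coefficients[2]
    detrended <- is.finite(s) && s > 0
    r <- if (detrended) recon / s else recon
    out <- nrmse(r, truth, m)
    attr(out, "detrended") <- detrended
    out
}

#' Deviation of the deep gray-matter calibration slope from unity
#'
#' The mean reconstructed value of each of the six deep gray-matter regions
#' is regressed (through the origin by default) on the prescribed mean
#' susceptibility of that region; the score is |slope - 1|.
#'
#' @param recon numeric array
#' @param dgmMasks named list of >= 2 logical region masks
#' @param prescribedMeans numeric vector of prescribed chi means, same
#'   order/names as `dgmMasks`
#' @param intercept fit an intercept as well (default FALSE)
#' @return scalar score
#' @export
deviationFromLinearSlope <- function(recon, dgmMasks, prescribedMeans,
                                     intercept = FALSE) {
    if (length(dgmMasks) < 2) stop("at least two regions are required")
    if (length(prescribedMeans) != length(dgmMasks))
        stop("one prescribed mean per region is required")
    means <- vapply(dgmMasks, function(m) mean(recon[as.logical(m)]), numeric(1))
    s <- if (intercept) {
        stats::lm.fit(cbind(1, prescribedMeans), means)$coefficients[2]
    } else {
        sum(means * prescribedMeans) / sum(prescribedMeans^2)
    }
    abs(unname(s) - 1)
}

## Hollow rectangular prism around the calcification: bounding box expanded
## by `inner` voxels (inner shell boundary) and by `inner + width` voxels
## (outer boundary); the ROI is the set difference, clipped to the grid.
calcStreakROI <- function(calcMask, inner = 2L, width = 6L) {
    d <- dim(calcMask)
    ix <- which(array(as.logical(calcMask), dim = d), arr.ind = TRUE)
    if (nrow(ix) == 0) stop("empty calcification mask")
    lo <- apply(ix, 2, min); hi <- apply(ix, 2, max)
    boxMask <- function(lo, hi) {
        lo <- pmax(lo, 1L); hi <- pmin(hi, d)
        m <- array(FALSE, dim = d)
        m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
        m
    }
    innerBox <- boxMask(lo - inner, hi + inner)
    outerBox <- boxMask(lo - inner - width, hi + inner + width)
    roi <- outerBox & !innerBox
    if (!any(roi)) stop("calcification shell ROI is empty (structure at the volume edge?)")
    roi
}

#' Streaking-artifact score around the calcification
#'
#' SD of the difference between reconstruction and ground truth over a
#' hollow rectangular prism: inner boundary two voxels outside the
#' calcification bounding box, outer boundary six voxels further, clipped to
#' the brain mask. Multiplied by 100 like the other RMSE-type metrics.
#'
#' @param recon,truth numeric arrays
#' @param calcMask logical calcification mask (single connected component)
#' @param brainMask logical brain mask the shell is intersected with
#' @return scalar score
#' @export
calcStreak <- function(recon, truth, calcMask, brainMask = NULL) {
    roi <- calcStreakROI(calcMask)
    if (!is.null(brainMask)) roi <- roi & as.logical(brainMask)
    if (!any(roi)) stop("calcification shell ROI empty after brain-mask clipping")
    100 * stats::sd((recon - truth)[roi])
}

#' Volumetric susceptibility moment of the calcification
#'
#' Integral of the reconstructed susceptibility over the calcification
#' region (the mask plus a small dilation, capturing susceptibility spread
#' by the reconstruction), in ppm mm^3. Robust where the perturber itself
#' has no signal.
#'
#' @param recon numeric array (ppm)
#' @param calcRegion logical region (calcification dilated by ~2 voxels)
#' @param spacing mm per axis
#' @return signed moment, ppm mm^3
#' @export
calcMoment <- function(recon, calcRegion, spacing = c(1, 1, 1)) {
    sum(recon[as.logical(calcRegion)]) * prod(spacing)
}

#' Score a reconstruction with the full challenge metric suite
#'
#' @param recon a [SusceptibilityVolume-class] or numeric array (ppm)
#' @param truth ground-truth [SusceptibilityVolume-class] or array (ppm)
#' @param masks named list of logical arrays: `brain`, `tissue` (GM+WM),
#'   `blood` (1-voxel-dilated veins), `dgm` (six-nuclei union),
#'   `dgm_regions` (named list of the six per-nucleus masks), `calc`
#'   (calcification), `calc_region` (calcification dilated by 2)
#' @param prescribedMeans named numeric of prescribed chi means for the six
#'   nuclei (defaults to the Model 1 table values)
#' @param spacing mm per axis
#' @return a [MetricReport-class]
#' @export
scoreReconstruction <- function(recon, truth, masks,
                                prescribedMeans = NULL,
                                spacing = c(1, 1, 1)) {
    if (methods::is(recon, "SusceptibilityVolume")) {
        spacing <- voxelSpacing(recon); recon <- chiData(recon)
    }
    if (methods::is(truth, "SusceptibilityVolume")) truth <- chiData(truth)
    if (is.null(prescribedMeans)) {
        tb <- paramTable(tissueTable("model1"))
        prescribedMeans <- stats::setNames(
            tb$chi_mean[match(DGM_LABELS, tb$name)], DGM_LABELS)
    }
    regions <- masks$dgm_regions[names(prescribedMeans)]
    truthMoment <- calcMoment(truth, masks$calc_region, spacing)
    moment <- calcMoment(recon, masks$calc_region, spacing)
    vals <- c(
        nRMSE = nrmse(recon, truth, masks$brain),
        rmse_detrend_tissue = as.numeric(rmseDetrended(recon, truth, masks$tissue)),
        rmse_detrend_blood = as.numeric(rmseDetrended(recon, truth, masks$blood)),
        rmse_detrend_dgm = as.numeric(rmseDetrended(recon, truth, masks$dgm)),
        deviation_from_linear_slope =
            deviationFromLinearSlope(recon, regions, prescribedMeans),
        calc_streak = calcStreak(recon, truth, masks$calc, masks$brain),
        calc_moment = moment,
        calc_moment_dev = moment - truthMoment)
    methods::new("MetricReport", values = vals, masks = masks)
}
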