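#' @include utils-image.R accessors.R
NULL

#' k-space dipole kernel
#'
#' Unit field response of a point susceptibility source along B0, with the
#' Lorentz-sphere correction, on the discrete frequency lattice:
#' D(k) = 1/3 - k_z^2 / |k|^2. The k = 0 sample is set to 0, fixing the
#' (physically arbitrary) mean field offset to zero.
#'
#' @param shape integer length-3 grid size
#' @param spacing mm per axis
#' @param b0Axis array axis along B0 (default 3)
#' @return numeric 3-D array in FFT ordering
#' @export
dipoleKernel <- function(shape, spacing = c(1, 1, 1), b0Axis = 3L) {
    if (any(spacing <= 0)) stop("spacing must be positive")
    kx <- fftFreq(shape[1], spacing[1])
    ky <- fftFreq(shape[2], spacing[2])
    kz <- fftFreq(shape[3], spacing[3])
    k1 <- array(kx, dim = shape)
    k2 <- aperm(array(ky, dim = shape[c(2, 1, 3)]), c(2, 1, 3))
    k3 <- aperm(array(kz, dim = shape[c(3, 1, 2)]), c(2, 3, 1))
    k2sum <- k1^2 + k2^2 + k3^2
    kb <- switch(b0Axis, k1, k2, k3)
    D <- 1 / 3 - kb^2 / k2sum
    D[k2sum == 0] <- 0
    D
}

#' Forward field from a susceptibility distribution
#'
#' Frequency-shift map by k-space multiplication with the dipole kernel. The
#' volume is zero padded by `padFactor` along each axis before the FFT to
#' suppress circular-convolution aliasing, then cropped back to the original
#' field of view. Output is in ppm of B0.
#'
#' @param chi a [SusceptibilityVolume-class] (ppm)
#' @param padFactor zero-padding factor per axis (default 2)
#' @param B0 Tesla (stored on the result for unit conversion)
#' @param b0Axis array axis along B0
#' @return a [FieldMap-class] in ppm
#' @export
fieldFromChi <- function(chi, padFactor = 2, B0 = 7, b0Axis = 3L) {
    x <- chiData(chi)
    d <- dim(x)
    dp <- as.integer(round(d * padFactor))
    xp <- zeroPad(x, dp)
    D <- dipoleKernel(dp, voxelSpacing(chi), b0Axis = b0Axis)
    f <- Re(stats::fft(D * stats::fft(xp), inverse = TRUE)) / prod(dp)
    methods::new("FieldMap", values = cropTo(f, d), unit = "ppm",
                 B0 = B0, spacing = voxelSpacing(chi))
}

## Legendre polynomials P0..P3 on [-1, 1].
legendreP <- function(x, n) {
    switch(n + 1L,
        rep(1, length(x)),
        x,
        (3 * x^2 - 1) / 2,
        (5 * x^3 - 3 * x) / 2,
        stop("order > 3 not supported"))
}

## Design matrix of Legendre products with total degree <= maxOrder, on
## per-axis coordinates normalised to [-1, 1].
legendreBasis <- function(shape, voxels, maxOrder = 3L) {
    norm1 <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else rep(0, length(i))
    xs <- norm1(voxels[, 1], shape[1])
    ys <- norm1(voxels[, 2], shape[2])
    zs <- norm1(voxels[, 3], shape[3])
    cols <- list()
    for (i in 0:maxOrder) for (j in 0:(maxOrder - i)) for (k in 0:(maxOrder - i - j))
        cols[[length(cols) + 1L]] <- legendreP(xs, i) * legendreP(ys, j) * legendreP(zs, k)
    do.call(cbind, cols)
}

#' Simulated shimming by Legendre-polynomial field fitting
#'
#' Least-squares fit of products of Legendre polynomials (all terms of total
#' order 0..`maxOrder`, default third order) to the field over the brain
#' mask, coordinates normalised to \[-1, 1\] per axis; the fitted component is
#' subtracted everywhere. The residual is orthogonal to the basis over the
#' mask.
#'
#' @param field a [FieldMap-class]
#' @param mask logical array (shim volume)
#' @param maxOrder highest total polynomial order (<= 3)
#' @return a [FieldMap-class] in the unit of the input
#' @export
simulateShim <- function(field, mask, maxOrder = 3L) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty shim mask")
    d <- dim(field@values)
    vox <- which(array(m, dim = d), arr.ind = TRUE)
    X <- legendreBasis(d, vox, maxOrder)
    if (nrow(X) < ncol(X)) stop("shim mask too small for the polynomial basis")
    fit <- stats::lm.fit(X, field@values[m])
    if (any(is.na(fit$coefficients))) stop("rank-deficient shim basis over the mask")
    allVox <- which(array(TRUE, dim = d), arr.ind = TRUE)
    Xall <- legendreBasis(d, allVox, maxOrder)
    shim <- array(Xall %*% fit$coefficients, dim = d)
    methods::new("FieldMap", values = field@values - shim, unit = field@unit,
                 B0 = field@B0, spacing = field@spacing)
}

#' White-matter microstructure frequency shift
#'
#' TE-independent first-order correction for fiber-orientation effects at
#' 7 T, applied only inside the white-matter mask. Under the default parsing
#' the shifted frequency is
#' `dw = dw_chi - (5 * (sin^2 theta - 2/3) * FA_norm + 3)` rad/s, with
#' `FA_norm = FA / 0.59` (optic-nerve average anisotropy). The grouping of
#' this empirical expression is not settled; an alternative literal
#' left-to-right parsing `dw = dw_chi - 5 sin^2 theta - (2/3) FA_norm - 3`
#' is selectable.
#'
#' @param field a [FieldMap-class] (susceptibility-induced frequency)
#' @param FA fractional anisotropy array
#' @param theta fiber-to-B0 angle array, radians
#' @param wmMask logical white-matter mask
#' @param parsing `"grouped"` (default) or `"literal"`
#' @param faRef FA normalisation constant (default 0.59)
#' @return a [FieldMap-class] in the unit of the input
#' @export
microstructureShift <- function(field, FA, theta, wmMask,
                                parsing = c("grouped", "literal"),
                                faRef = 0.59) {
    parsing <- match.arg(parsing)
    m <- as.logical(wmMask)
    outside <- (!m) & (abs(FA) > 0)
    if (any(outside))
        warning("FA values outside the white-matter mask are ignored")
    faNorm <- FA / faRef
    corr <- switch(parsing,
        grouped = 5 * (sin(theta)^2 - 2 / 3) * faNorm + 3,
        literal = 5 * sin(theta)^2 + (2 / 3) * faNorm + 3)
    w <- fieldData(field, "rad_s")
    w[m] <- w[m] - corr[m]
    methods::new("FieldMap",
                 values = convertFieldUnit(w, "rad_s", field@unit, field@B0),
                 unit = field@unit, B0 = field@B0, spacing = field@spacing)
}
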