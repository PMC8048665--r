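#' @include forward-field.R
NULL

#' Dipole inversion by thresholded k-space division
#'
#' Direct inversion chi(k) = F(k) / D(k), with the division clamped near the
#' zero cone of the dipole kernel: where |D(k)| <= t the divisor is replaced
#' by t * sign(D(k)) (sign-preserving amplitude clamp). The result is
#' re-masked to the brain.
#'
#' @param localField a [FieldMap-class] (brain-masked local field)
#' @param mask logical brain mask
#' @param threshold clamp level t on D, in (0, 2/3]
#' @param b0Axis array axis along B0
#' @return a [SusceptibilityVolume-class] (ppm, local mode conventions not
#'   enforced: the raw masked estimate is returned as `whole_head` storage)
#' @export
invertTKD <- function(localField, mask, threshold = 0.2, b0Axis = 3L) {
    if (threshold <= 0 || threshold > 2 / 3)
        stop("threshold must lie in (0, 2/3]")
    f <- fieldData(localField, "ppm")
    d <- dim(f)
    D <- dipoleKernel(d, localField@spacing, b0Axis = b0Axis)
    Dinv <- ifelse(abs(D) > threshold, D,
                   threshold * ifelse(D >= 0, 1, -1))
    chiK <- stats::fft(f) / Dinv
    chi <- Re(stats::fft(chiK, inverse = TRUE)) / prod(d)
    m <- array(as.logical(mask), dim = d)
    chi[!m] <- 0
    methods::new("SusceptibilityVolume", chi = chi, mode = "whole_head",
                 brainMask = m, spacing = localField@spacing)
}

#' Closed-form L2-regularised dipole inversion
#'
#' chi(k) = D(k) F(k) / (D(k)^2 + lambda |G(k)|^2) with G the spectrum of
#' the discrete first-difference gradient operator,
#' |G(k)|^2 = sum_axes 4 sin^2(pi k_a / n_a). As lambda tends to 0 the
#' estimate approaches plain division away from the dipole cone; large
#' lambda shrinks the estimate to zero.
#'
#' @param localField a [FieldMap-class]
#' @param mask logical brain mask
#' @param lambda regularisation weight (> 0)
#' @param b0Axis array axis along B0
#' @return a [SusceptibilityVolume-class] (ppm)
#' @export
invertL2 <- function(localField, mask, lambda = 0.05, b0Axis = 3L) {
    if (lambda <= 0) stop("lambda must be positive")
    f <- fieldData(localField, "ppm")
    d <- dim(f)
    D <- dipoleKernel(d, localField@spacing, b0Axis = b0Axis)
    g2axis <- function(n) 4 * sin(pi * (0:(n - 1)) / n)^2
    G2 <- array(g2axis(d[1]), dim = d) +
        aperm(array(g2axis(d[2]), dim = d[c(2, 1, 3)]), c(2, 1, 3)) +
        aperm(array(g2axis(d[3]), dim = d[c(3, 1, 2)]), c(2, 3, 1))
    chiK <- D * stats::fft(f) / (D^2 + lambda * G2)
    chiK[D^2 + lambda * G2 == 0] <- 0
    chi <- Re(stats::fft(chiK, inverse = TRUE)) / prod(d)
    m <- array(as.logical(mask), dim = d)
    chi[!m] <- 0
    methods::new("SusceptibilityVolume", chi = chi, mode = "whole_head",
                 brainMask = m, spacing = localField@spacing)
}
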