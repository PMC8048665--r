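#' @include accessors.R utils-image.R
NULL

#' Construct an acquisition protocol
#'
#' @param TR repetition time, seconds
#' @param TE echo times, seconds (ascending)
#' @param flipAngle degrees
#' @param targetSpacing target resolution for downsampling, mm (NA = native)
#' @param peakSNR peak signal-to-noise ratio (Inf = noiseless)
#' @return a [Protocol-class]
#' @export
protocolSpec <- function(TR, TE, flipAngle, targetSpacing = NA_real_, peakSNR = Inf) {
    methods::new("Protocol", TR = TR, TE = TE, flipAngle = flipAngle,
                 targetSpacing = targetSpacing, peakSNR = peakSNR)
}

#' Named protocol presets
#'
#' `"P1"` targets cortical gray/white contrast (TR 16 ms, five echoes
#' 4..36 ms, flip 23 deg), `"P2"` deep gray-matter quantification (TR 40 ms,
#' echoes 4/12 ms, flip 8 deg), `"challenge"` is the QSM-challenge protocol
#' (TR 50 ms, echoes 4/12/20/28 ms, flip 15 deg).
#'
#' @param name preset name
#' @return a [Protocol-class]
#' @export
protocolPreset <- function(name = c("challenge", "P1", "P2")) {
    name <- match.arg(name)
    switch(name,
        challenge = protocolSpec(0.050, c(4, 12, 20, 28) * 1e-3, 15),
        P1 = protocolSpec(0.016, seq(4, 36, by = 8) * 1e-3, 23),
        P2 = protocolSpec(0.040, c(4, 12) * 1e-3, 8))
}

#' Steady-state spoiled gradient-echo signal
#'
#' Complex multi-echo stack from the steady-state expression
#' `S = M0 sin(a) (1 - E1) / (1 - cos(a) E1) exp(-TE R2* + i (phi0 + TE dw))`
#' with `E1 = exp(-TR R1)` and dw the frequency shift in rad/s.
#'
#' @param params a [ParameterMaps-class]
#' @param field a [FieldMap-class] (converted internally to rad/s)
#' @param phi0 transceiver phase array, radians (or scalar 0)
#' @param protocol a [Protocol-class]
#' @param B0 Tesla
#' @param provenance named list recorded on the series
#' @return an [EchoSeries-class]
#' @export
greSignal <- function(params, field, phi0 = 0, protocol, B0 = 7,
                      provenance = list()) {
    if (any(params@R1 < 0) || any(params@R2star < 0))
        stop("negative relaxation rates")
    a <- protocol@flipAngle * pi / 180
    E1 <- exp(-protocol@TR * params@R1)
    ss <- params@M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
    dw <- fieldData(field, "rad_s")
    echoes <- lapply(protocol@TE, function(TE)
        ss * exp(-TE * params@R2star) * exp(1i * (phi0 + TE * dw)))
    methods::new("EchoSeries", echoes = echoes, protocol = protocol,
                 B0 = B0, spacing = params@spacing, provenance = provenance)
}

#' Seeded second-order polynomial transceiver phase
#'
#' Random 3-D polynomial of total order <= 2 (coefficients drawn from a
#' seeded standard normal), rescaled so that the peak-to-peak range over the
#' brain mask equals 2 pi.
#'
#' @param shape grid size
#' @param mask logical brain mask
#' @param seed integer seed
#' @param order total polynomial order (default 2)
#' @return phase array, radians
#' @export
transceiverPhase <- function(shape, mask, seed = 1L, order = 2L) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty brain mask")
    norm1 <- function(n) if (n > 1) seq(-1, 1, length.out = n) else 0
    xs <- array(norm1(shape[1]), dim = shape)
    ys <- aperm(array(norm1(shape[2]), dim = shape[c(2, 1, 3)]), c(2, 1, 3))
    zs <- aperm(array(norm1(shape[3]), dim = shape[c(3, 1, 2)]), c(2, 3, 1))
    set.seed(seed)
    phi <- array(0, dim = shape)
    for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
        phi <- phi + stats::rnorm(1) * xs^i * ys^j * zs^k
    ptp <- diff(range(phi[m]))
    if (ptp == 0) {
        warning("degenerate (constant) phase polynomial; rescaling skipped")
        return(phi)
    }
    phi * (2 * pi / ptp)
}

#' Add complex Gaussian noise at a prescribed peak SNR
#'
#' The per-channel noise SD is `max(|S|) / peakSNR` measured on the first
#' echo; i.i.d. Gaussian noise is added to the real and imaginary channels
#' of every echo. `peakSNR = Inf` is the identity.
#'
#' @param series an [EchoSeries-class]
#' @param peakSNR peak signal-to-noise ratio
#' @param seed integer seed
#' @param perEcho if TRUE, the SD is computed per echo instead of from the
#'   first echo
#' @return a noisy [EchoSeries-class]
#' @export
addNoise <- function(series, peakSNR = 100, seed = 1L, perEcho = FALSE) {
    if (peakSNR <= 0) stop("peakSNR must be positive")
    if (!is.finite(peakSNR)) return(series)
    set.seed(seed)
    sigma1 <- max(Mod(series@echoes[[1]])) / peakSNR
    echoes <- lapply(series@echoes, function(e) {
        sigma <- if (perEcho) max(Mod(e)) / peakSNR else sigma1
        n <- length(e)
        e + complex(real = stats::rnorm(n, sd = sigma),
                    imaginary = stats::rnorm(n, sd = sigma))
    })
    prov <- series@provenance
    prov$noise_seed <- seed
    prov$peak_snr <- peakSNR
    methods::new("EchoSeries", echoes = echoes, protocol = series@protocol,
                 B0 = series@B0, spacing = series@spacing, provenance = prov)
}

#' Fourier-crop downsampling
#'
#' Mimics Cartesian k-space sampling at a lower resolution: the spectrum is
#' cropped to the target matrix around the DC sample and inverse transformed.
#' The spectrum is rescaled by the matrix-size ratio so mean image intensity
#' (the DC level) is preserved.
#'
#' @param volume numeric or complex 3-D array
#' @param sourceSpacing mm per axis
#' @param targetSpacing mm per axis (>= source per axis)
#' @return list with `data` (array, complex iff the input was) and `spacing`
#' @export
fourierDownsample <- function(volume, sourceSpacing, targetSpacing) {
    d <- dim(volume)
    targetSpacing <- rep(targetSpacing, length.out = 3)
    sourceSpacing <- rep(sourceSpacing, length.out = 3)
    if (any(targetSpacing < sourceSpacing - 1e-12))
        stop("target spacing must be >= source spacing")
    nt <- pmax(1L, as.integer(round(d * sourceSpacing / targetSpacing)))
    if (any(nt > d)) stop("target matrix larger than source")
    X <- fftshift3(stats::fft(volume))
    ctr <- floor(d / 2) + 1L
    start <- ctr - floor(nt / 2)
    Xc <- X[start[1]:(start[1] + nt[1] - 1),
            start[2]:(start[2] + nt[2] - 1),
            start[3]:(start[3] + nt[3] - 1), drop = FALSE]
    out <- stats::fft(ifftshift3(Xc), inverse = TRUE) / prod(d)
    if (!is.complex(volume)) out <- Re(out)
    list(data = out, spacing = d * sourceSpacing / nt)
}

#' Downsample a whole echo series
#'
#' Applies [fourierDownsample()] to each complex echo volume jointly in
#' magnitude and phase.
#'
#' @param series an [EchoSeries-class]
#' @param targetSpacing mm
#' @return an [EchoSeries-class] on the coarser grid
#' @export
downsampleEchoes <- function(series, targetSpacing) {
    res <- lapply(series@echoes, fourierDownsample,
                  sourceSpacing = series@spacing, targetSpacing = targetSpacing)
    methods::new("EchoSeries", echoes = lapply(res, `[[`, "data"),
                 protocol = series@protocol, B0 = series@B0,
                 spacing = res[[1]]$spacing, provenance = series@provenance)
}

## One-sided local total variation: the smaller of the sums of |first
## differences| over the K samples to the left and to the right of each
## sample, so the measure on one side of an edge is not polluted by the
## edge jump itself. `x` is an n x m matrix of lines.
localTV <- function(x, K = 3L) {
    n <- nrow(x)
    dv <- abs(x[-1, , drop = FALSE] - x[-n, , drop = FALSE])
    cs <- rbind(0, apply(dv, 2, cumsum))
    j <- seq_len(n)
    left <- cs[pmin(j - 1, n - 1) + 1L, , drop = FALSE] -
        cs[pmax(j - K, 1L), , drop = FALSE]
    right <- cs[pmin(j + K - 1L, n - 1L) + 1L, , drop = FALSE] -
        cs[pmin(j, n - 1L), , drop = FALSE]
    left[1, ] <- Inf
    right[n, ] <- Inf
    pmin(left, right)
}

## Subvoxel-shifted copies of all lines along one axis, via an FFT phase
## ramp. A voxel is replaced only where some shift reduces its one-sided
## local TV below `tvGate` times the unshifted value -- the decisive drop
## that marks alignment with a ringing null; elsewhere the sample is kept,
## which leaves smooth data untouched and makes the operation idempotent.
unringAxis <- function(vol, axis, shifts, K = 3L, tvGate = 0.3) {
    d <- dim(vol)
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(vol, perm)
    n <- d[axis]
    dim(x) <- c(n, prod(d[-axis]))
    Xf <- stats::mvfft(x)
    k <- fftFreq(n, 1)
    bestVal <- x
    bestTV <- tvGate * localTV(x, K)
    for (s in shifts[shifts != 0]) {
        ramp <- exp(-2i * pi * k * s)
        xs <- Re(stats::mvfft(Xf * ramp, inverse = TRUE)) / n
        tv <- localTV(xs, K)
        ## interpolate the shifted samples back to the original positions
        if (s >= 0) {
            nxt <- xs[c(2:n, n), , drop = FALSE]
            corr <- (1 - s) * xs + s * nxt
        } else {
            prv <- xs[c(1, 1:(n - 1)), , drop = FALSE]
            corr <- (1 + s) * xs - s * prv
        }
        upd <- tv < bestTV
        bestVal[upd] <- corr[upd]
        bestTV[upd] <- tv[upd]
    }
    dim(bestVal) <- c(n, d[perm[2]], d[perm[3]])
    aperm(bestVal, order(perm))
}

#' Gibbs-ringing suppression by local subvoxel shifts
#'
#' For each 1-D line along each axis, candidate subvoxel shifts in
#' \[-0.5, 0.5\] are generated by FFT phase ramps; per voxel the shift
#' minimising the local total variation is chosen (ringing passes through a
#' null at the optimal shift), the shifted sample is interpolated back to
#' the voxel centre, and the three axis results are averaged. Intended for
#' the Fourier-cropped ground-truth susceptibility volume, whose sharp
#' air/bone edges ring severely; simulated complex data keep their ringing.
#'
#' @param vol numeric 3-D array (or a 1-D vector, processed as one line)
#' @param axes axes to process and average over (default 1:3)
#' @param nShifts number of candidate shifts (default 21)
#' @return array of the same shape
#' @export
gibbsSuppress <- function(vol, axes = 1:3, nShifts = 21L) {
    if (is.null(dim(vol))) {
        v <- array(vol, dim = c(length(vol), 1L, 1L))
        return(as.vector(gibbsSuppress(v, axes = 1L, nShifts = nShifts)))
    }
    shifts <- seq(-0.5, 0.5, length.out = nShifts)
    acc <- array(0, dim = dim(vol))
    for (axis in axes) acc <- acc + unringAxis(vol, axis, shifts)
    acc / length(axes)
}
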