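#' @include accessors.R utils-image.R
NULL

## Unwrapping quality: inverse variance of the wrapped phase gradient over
## the 6-neighbourhood. High where the phase is locally smooth.
phaseQuality <- function(wrapped, mask) {
    d <- dim(wrapped)
    wrapToPi <- function(x) atan2(sin(x), cos(x))
    s1 <- array(0, dim = d); s2 <- array(0, dim = d); cnt <- array(0, dim = d)
    for (axis in 1:3) for (by in c(-1L, 1L)) {
        nb <- shiftArr(wrapped, axis, by, fill = NA_real_)
        ok <- !is.na(nb) & shiftArr(mask, axis, by, fill = FALSE) & mask
        g <- wrapToPi(nb - wrapped)
        g[!ok] <- 0
        s1 <- s1 + g
        s2 <- s2 + g^2
        cnt <- cnt + ok
    }
    v <- array(0, dim = d)
    pos <- cnt > 1
    v[pos] <- pmax(0, s2[pos] / cnt[pos] - (s1[pos] / cnt[pos])^2)
    1 / (v + 1e-8)
}

#' Spatial phase unwrapping by quality-guided region growing
#'
#' Grows the unwrapped region from a seed (the highest-magnitude voxel in
#' the mask), admitting voxels in order of decreasing quality (inverse local
#' phase-gradient variance) and unwrapping each against the neighbour it was
#' reached from. Output minus input is an integer multiple of 2 pi
#' everywhere in the mask; the seed keeps its wrapped value, fixing the
#' global 2 pi offset.
#'
#' @param wrapped phase array in (-pi, pi]
#' @param magnitude magnitude array used to pick the seed (and, with `mask`
#'   absent, to define the reliability mask as magnitude > 0)
#' @param mask optional logical array restricting the unwrap
#' @return list with `phase` (unwrapped array) and `mask`
#' @export
unwrapSpatial <- function(wrapped, magnitude, mask = NULL) {
    d <- dim(wrapped)
    if (is.null(mask)) mask <- magnitude > 0
    mask <- array(as.logical(mask), dim = d)
    if (!any(mask)) stop("empty reliability mask")
    q <- phaseQuality(wrapped, mask)
    mag <- magnitude
    mag[!mask] <- -Inf
    seed <- which.max(mag)
    out <- .unwrap_rg_cpp(as.double(wrapped), as.double(q), mask,
                          as.integer(d), as.integer(seed - 1L))
    phase <- array(out, dim = d)
    phase[!mask] <- wrapped[!mask]
    list(phase = phase, mask = mask)
}

#' Unwrap a multi-echo series via echo differences
#'
#' Phase differences between consecutive echoes are unwrapped spatially and
#' integrated across echoes on top of the (unwrapped) first-echo phase,
#' yielding per-echo unwrapped phase volumes. Working on differences keeps
#' the per-step phase excursions small.
#'
#' @param series an [EchoSeries-class]
#' @param mask logical brain mask
#' @return list with `phase` (list of unwrapped per-echo arrays) and `mask`
#' @export
unwrapEchoes <- function(series, mask) {
    n <- nEchoes(series)
    mag1 <- Mod(echoData(series, 1))
    first <- unwrapSpatial(Arg(echoData(series, 1)), mag1, mask)
    phases <- vector("list", n)
    phases[[1]] <- first$phase
    if (n > 1) for (j in seq_len(n - 1)) {
        dphi <- Arg(echoData(series, j + 1) * Conj(echoData(series, j)))
        magm <- sqrt(Mod(echoData(series, j + 1)) * Mod(echoData(series, j)))
        u <- unwrapSpatial(dphi, magm, mask)
        phases[[j + 1]] <- phases[[j]] + u$phase
    }
    list(phase = phases, mask = first$mask)
}

#' Frequency fit across echoes with optimum weights
#'
#' Per-voxel weighted least-squares line fit `phase(TE) = phi0 + 2 pi f TE`
#' with weights `w_j` proportional to `TE_j^2 |S_j|^2` (inverse-variance
#' weighting of the per-echo phase noise, emphasising late echoes where
#' phase accrual dominates). Returns the frequency map in Hz and the
#' weighted mean-squared fit residual (rad^2).
#'
#' @param phases list of unwrapped per-echo phase arrays (radians)
#' @param magnitudes list of per-echo magnitude arrays
#' @param TE echo times, seconds
#' @param B0 Tesla (stored on the result)
#' @param weights `"te2mag2"` (default) or `"mag2"`
#' @return list with `field` (a [FieldMap-class], Hz), `phi0` and
#'   `residual` (array, rad^2)
#' @export
fitFrequency <- function(phases, magnitudes, TE, B0 = 7,
                         weights = c("te2mag2", "mag2")) {
    weights <- match.arg(weights)
    if (length(TE) < 2) stop("at least two echoes are required")
    d <- dim(phases[[1]])
    Sw <- array(0, dim = d); St <- Sw; Stt <- Sw; Sp <- Sw; Stp <- Sw
    wlist <- vector("list", length(TE))
    for (j in seq_along(TE)) {
        w <- magnitudes[[j]]^2
        if (weights == "te2mag2") w <- w * TE[j]^2
        wlist[[j]] <- w
        Sw <- Sw + w
        St <- St + w * TE[j]
        Stt <- Stt + w * TE[j]^2
        Sp <- Sp + w * phases[[j]]
        Stp <- Stp + w * TE[j] * phases[[j]]
    }
    det <- Sw * Stt - St^2
    bad <- !(det > 0) | !(Sw > 0)
    det[bad] <- 1
    slope <- (Sw * Stp - St * Sp) / det
    inter <- (Stt * Sp - St * Stp) / det
    slope[bad] <- 0
    inter[bad] <- 0
    res <- array(0, dim = d)
    for (j in seq_along(TE)) {
        r <- phases[[j]] - inter - slope * TE[j]
        res <- res + wlist[[j]] * r^2
    }
    res <- res / pmax(Sw, .Machine$double.xmin)
    res[bad] <- Inf
    f <- slope / (2 * pi)
    list(field = methods::new("FieldMap", values = f, unit = "Hz", B0 = B0,
                              spacing = c(1, 1, 1)),
         phi0 = inter, residual = res)
}

#' Background-field removal by the Laplacian boundary-value method
#'
#' The background field generated by sources outside the brain is harmonic
#' inside it. The mask is eroded by one voxel; Laplace's equation is solved
#' on the eroded mask's interior with Dirichlet values taken from the
#' measured field on the mask's inner boundary shell (finite-difference
#' 7-point Laplacian, successive over-relaxation). The harmonic solution is
#' subtracted; the returned local field is demeaned over the solved mask and
#' zero outside it.
#'
#' @param field a [FieldMap-class]
#' @param mask logical brain mask
#' @param tol relative residual tolerance (default 1e-6)
#' @param maxIter iteration cap (default 1e4)
#' @param erode voxels of mask erosion before solving (default 1)
#' @return list with `field` (local-field [FieldMap-class], same unit) and
#'   `mask` (the solved, eroded mask)
#' @export
removeBackgroundLBV <- function(field, mask, tol = 1e-6, maxIter = 10000L,
                                erode = 1L) {
    d <- dim(field@values)
    m <- array(as.logical(mask), dim = d)
    if (erode > 0) m <- binaryErode(m, erode)
    if (!any(m)) stop("mask empty after erosion")
    interior <- m & shiftAnd(m)
    ## keep the solver away from the array border
    edge <- array(TRUE, dim = d)
    edge[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
    interior <- interior & !edge
    if (!any(interior)) stop("mask too small: no interior voxels")
    omega <- 2 / (1 + sin(pi / max(d)))
    sol <- .lbv_sor_cpp(as.double(field@values), interior, as.integer(d),
                        omega, tol, as.integer(maxIter))
    if (!sol$converged)
        stop(sprintf("LBV solver did not converge (relative residual %.3g after %d iterations)",
                     sol$residual, sol$iterations))
    u <- array(sol$u, dim = d)
    local <- field@values - u
    local[!m] <- 0
    local[m] <- local[m] - mean(local[m])
    list(field = methods::new("FieldMap", values = local, unit = field@unit,
                              B0 = field@B0, spacing = field@spacing),
         mask = m)
}

#' Reference phase-processing chain
#'
#' Complex echoes to a (local) field map: spatial unwrapping of echo
#' differences, optimum-weight frequency fit, and (optionally) Laplacian
#' boundary-value background removal.
#'
#' @param series an [EchoSeries-class]
#' @param mask logical brain mask
#' @param removeBackground run the LBV stage (skip for local-field
#'   simulations, which have no background by construction)
#' @return list with `field` (a [FieldMap-class], Hz), `residual` (rad^2),
#'   `phi0`, and `mask` (possibly eroded by the LBV stage)
#' @export
processEchoes <- function(series, mask, removeBackground = FALSE) {
    uw <- unwrapEchoes(series, mask)
    mags <- lapply(seq_len(nEchoes(series)), function(j) Mod(echoData(series, j)))
    fit <- fitFrequency(uw$phase, mags, protocol(series)@TE, B0 = series@B0)
    fld <- methods::new("FieldMap", values = fit$field@values, unit = "Hz",
                        B0 = series@B0, spacing = series@spacing)
    outMask <- uw$mask
    if (removeBackground) {
        bg <- removeBackgroundLBV(fld, uw$mask)
        fld <- bg$field
        outMask <- bg$mask
    }
    list(field = fld, residual = fit$residual, phi0 = fit$phi0, mask = outMask)
}
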