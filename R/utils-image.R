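## Shared array/FFT helpers used across the simulation chain.

#' Discrete Fourier frequencies of an axis
#'
#' @param n axis length
#' @param d sample spacing (mm); frequencies are cycles/mm
#' @return numeric vector in FFT ordering (DC first)
#' @keywords internal
fftFreq <- function(n, d = 1) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    k / (n * d)
}

## Index permutation placing DC at floor(n/2)+1 (fftshift) and its inverse.
fftshiftIdx <- function(n) {
    if (n == 1L) return(1L)
    c((floor(n / 2) + 1):n, 1:floor(n / 2))
}
ifftshiftIdx <- function(n) order(fftshiftIdx(n))

fftshift3 <- function(x) {
    d <- dim(x)
    x[fftshiftIdx(d[1]), fftshiftIdx(d[2]), fftshiftIdx(d[3]), drop = FALSE]
}
ifftshift3 <- function(x) {
    d <- dim(x)
    x[ifftshiftIdx(d[1]), ifftshiftIdx(d[2]), ifftshiftIdx(d[3]), drop = FALSE]
}

## Apply a dense 1-D linear operator (n_out x n_in matrix) along one axis of a
## 3-D array. Used by the separable Gaussian smoother.
applyAlongAxis <- function(vol, axis, op) {
    d <- dim(vol)
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(vol, perm)
    dim(x) <- c(d[axis], prod(d[-axis]))
    y <- op %*% x
    dim(y) <- c(nrow(op), d[perm[2]], d[perm[3]])
    aperm(y, order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' Image-space separable convolution with a Gaussian kernel truncated at
#' 4 sigma; edges are handled by zero padding (no kernel renormalisation),
#' appropriate for compactly supported masks.
#'
#' @param vol numeric 3-D array
#' @param fwhm full width at half maximum, in voxels (scalar or per-axis)
#' @return smoothed array of the same shape
#' @export
gaussianSmooth <- function(vol, fwhm) {
    stopifnot(length(dim(vol)) == 3)
    fwhm <- rep(fwhm, length.out = 3)
    out <- vol
    for (axis in 1:3) {
        sigma <- fwhm[axis] / (2 * sqrt(2 * log(2)))
        if (sigma <= 0) next
        n <- dim(vol)[axis]
        r <- max(1L, ceiling(4 * sigma))
        off <- -r:r
        k <- exp(-off^2 / (2 * sigma^2))
        k <- k / sum(k)
        idx <- seq_len(n)
        G <- matrix(0, n, n)
        band <- abs(outer(idx, idx, `-`))
        inside <- band <= r
        G[inside] <- k[band[inside] + r + 1]
        out <- applyAlongAxis(out, axis, G)
    }
    out
}

## Centred zero padding used before k-space dipole convolution: the original
## volume keeps its corner position (pad appended), which is immaterial for a
## circular convolution followed by cropping the same region.
zeroPad <- function(vol, newDim) {
    d <- dim(vol)
    stopifnot(all(newDim >= d))
    out <- array(0, dim = newDim)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
    out
}

cropTo <- function(vol, d) vol[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]

## Gradient magnitude by central differences (one-sided at edges), per mm.
gradientMagnitude <- function(vol, spacing) {
    d <- dim(vol)
    g2 <- array(0, dim = d)
    for (axis in 1:3) {
        n <- d[axis]
        ip <- pmin(seq_len(n) + 1L, n)
        im <- pmax(seq_len(n) - 1L, 1L)
        h <- (ip - im) * spacing[axis]
        idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        idxp <- idx; idxp[[axis]] <- ip
        idxm <- idx; idxm[[axis]] <- im
        diffv <- (vol[idxp[[1]], idxp[[2]], idxp[[3]], drop = FALSE] -
                  vol[idxm[[1]], idxm[[2]], idxm[[3]], drop = FALSE])
        hs <- array(0, dim = d)
        perm <- c(axis, setdiff(1:3, axis))
        hrep <- array(h, dim = d[perm])
        hs <- aperm(hrep, order(perm))
        g2 <- g2 + (diffv / hs)^2
    }
    sqrt(g2)
}

## 6-connected binary erosion / dilation (n iterations).
binaryErode <- function(mask, n = 1L) {
    m <- mask
    storage.mode(m) <- "logical"
    for (i in seq_len(n)) m <- m & shiftAnd(m)
    m
}

binaryDilate <- function(mask, n = 1L) {
    m <- mask
    storage.mode(m) <- "logical"
    for (i in seq_len(n)) m <- m | shiftOr(m)
    m
}

shiftArr <- function(m, axis, by, fill = FALSE) {
    d <- dim(m)
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- idx[[axis]] - by
    ok <- src >= 1 & src <= d[axis]
    out <- array(fill, dim = d)
    dst <- idx; dst[[axis]] <- idx[[axis]][ok]
    from <- idx; from[[axis]] <- src[ok]
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[from[[1]], from[[2]], from[[3]]]
    out
}

shiftAnd <- function(m) {
    out <- m
    for (axis in 1:3) for (by in c(-1L, 1L))
        out <- out & shiftArr(m, axis, by, fill = FALSE)
    out
}

shiftOr <- function(m) {
    out <- m
    for (axis in 1:3) for (by in c(-1L, 1L))
        out <- out | shiftArr(m, axis, by, fill = FALSE)
    out
}

## Chebyshev (chessboard) distance-to-mask within `maxDist`, via repeated
## 26-neighbourhood dilation; returns logical "within distance" mask.
withinChebyshev <- function(mask, dist) {
    m <- mask
    storage.mode(m) <- "logical"
    for (i in seq_len(dist)) {
        grown <- m
        for (axis in 1:3) grown <- grown | shiftArr(grown, axis, 1L) | shiftArr(grown, axis, -1L)
        m <- grown
    }
    m
}
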