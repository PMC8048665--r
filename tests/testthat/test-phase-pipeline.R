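test_that("region-growing unwrapping recovers smooth fields modulo one global 2 pi", {
    d <- c(24, 24, 24)
    ramp <- array(seq(0, 6 * pi, length.out = d[1]), dim = d)
    wrapped <- atan2(sin(ramp), cos(ramp))
    mag <- array(1, dim = d)
    out <- unwrapSpatial(wrapped, mag)
    ## differences to the wrapped input are exact 2 pi multiples
    k <- (out$phase - wrapped) / (2 * pi)
    expect_equal(k, round(k), tolerance = 1e-9)
    ## recovery up to one global 2 pi multiple
    offs <- out$phase - ramp
    expect_lt(diff(range(offs)), 1e-9)
    expect_equal(offs[1] / (2 * pi), round(offs[1] / (2 * pi)), tolerance = 1e-9)

    ## already-unwrapped phase is returned unchanged
    small <- wrapped * 0.1
    expect_equal(unwrapSpatial(small, mag)$phase, small, tolerance = 1e-12)

    expect_error(unwrapSpatial(wrapped, mag, array(FALSE, dim = d)), "mask")
})

test_that("frequency fit is exact on linear phase and reduces to the two-echo formula", {
    d <- c(5, 5, 5)
    TE <- c(4, 12, 20, 28) * 1e-3
    f0 <- array(rnorm(prod(d), sd = 20), dim = d)
    phi0 <- array(0.4, dim = d)
    phases <- lapply(TE, function(t) phi0 + 2 * pi * f0 * t)
    mags <- lapply(TE, function(t) array(runif(prod(d), 0.5, 1), dim = d))
    fit <- fitFrequency(phases, mags, TE)
    expect_equal(fieldData(fit$field, "Hz"), f0, tolerance = 1e-9)
    expect_equal(fit$phi0, phi0, tolerance = 1e-9)
    expect_lt(max(fit$residual), 1e-18)

    ## two echoes: f = dphi / (2 pi dTE) regardless of weights
    fit2 <- fitFrequency(phases[c(1, 3)], mags[c(1, 3)], TE[c(1, 3)])
    expect_equal(fieldData(fit2$field, "Hz"),
                 (phases[[3]] - phases[[1]]) / (2 * pi * (TE[3] - TE[1])),
                 tolerance = 1e-9)

    ## all-zero magnitude voxel: frequency 0, residual flagged
    mags0 <- lapply(mags, function(m) { m[1, 1, 1] <- 0; m })
    fit0 <- fitFrequency(phases, mags0, TE)
    expect_identical(fieldData(fit0$field, "Hz")[1, 1, 1], 0)
    expect_identical(fit0$residual[1, 1, 1], Inf)

    expect_error(fitFrequency(phases[1], mags[1], TE[1]), "two echoes")
})

test_that("LBV removes harmonic background fields and keeps local ones", {
    d <- c(40, 40, 40)
    ctr <- (d + 1) / 2
    ax <- seq_len(d[1]) - ctr[1]
    x <- array(ax, dim = d)
    y <- aperm(x, c(2, 1, 3))
    z <- aperm(x, c(3, 2, 1))
    mask <- x^2 + y^2 + z^2 <= 11^2

    mkf <- function(v) methods::new("FieldMap", values = v, unit = "Hz",
                                    B0 = 7, spacing = c(1, 1, 1))

    ## field of a source a few voxels OUTSIDE the mask is harmonic inside
    src <- c(37, 20, 20)
    rx <- array(seq_len(d[1]) - src[1], dim = d)
    ry <- aperm(array(seq_len(d[2]) - src[2], dim = d[c(2, 1, 3)]), c(2, 1, 3))
    rz <- aperm(array(seq_len(d[3]) - src[3], dim = d[c(3, 1, 2)]), c(2, 3, 1))
    r2 <- rx^2 + ry^2 + rz^2
    bg <- (3 * rz^2 / r2 - 1) / r2^1.5 * 1e3   # external dipole field
    res <- removeBackgroundLBV(mkf(bg), mask)
    m <- res$mask
    expect_lt(sqrt(mean(fieldData(res$field)[m]^2)),
              0.02 * sqrt(mean(bg[m]^2)))

    ## constant field -> zero
    resC <- removeBackgroundLBV(mkf(array(7, dim = d)), mask)
    expect_lt(max(abs(fieldData(resC$field)[resC$mask])), 1e-6)

    ## local dipole field of an interior source survives (up to its own
    ## harmonic mask-restriction component)
    chi <- array(0, dim = d)
    chi[abs(x) <= 1 & abs(y) <= 1 & abs(z) <= 1] <- 1
    sv <- methods::new("SusceptibilityVolume", chi = chi, mode = "whole_head",
                       brainMask = mask * TRUE, spacing = c(1, 1, 1))
    lf <- fieldData(fieldFromChi(sv), "ppm")
    resL <- removeBackgroundLBV(mkf(lf), mask)
    m2 <- resL$mask
    lf0 <- lf - mean(lf[m2])
    expect_lt(sqrt(mean((fieldData(resL$field)[m2] - lf0[m2])^2)),
              0.10 * sqrt(mean(lf0[m2]^2)))
})

test_that("unwrap-and-fit recovers a known frequency map from complex echoes", {
    d <- c(24, 24, 24)
    mask <- array(TRUE, dim = d)
    f <- array(30 * seq(-1, 1, length.out = d[1]), dim = d)  # Hz, wraps at dTE
    p <- protocolSpec(0.05, c(4, 12, 20, 28) * 1e-3, 15)
    params <- methods::new("ParameterMaps", M0 = array(1, dim = d),
                           R1 = array(1, dim = d), R2star = array(20, dim = d),
                           FA = array(numeric(0)), fiberTheta = array(numeric(0)),
                           spacing = c(1, 1, 1))
    fm <- methods::new("FieldMap", values = f, unit = "Hz", B0 = 7,
                       spacing = c(1, 1, 1))
    s <- greSignal(params, fm, 0.2, p)
    proc <- processEchoes(s, mask)
    expect_equal(fieldData(proc$field, "Hz"), f, tolerance = 1e-9)
})
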