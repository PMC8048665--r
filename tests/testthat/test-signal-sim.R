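mkParams <- function(d, M0 = 1, R1 = 1, R2star = 20) {
    methods::new("ParameterMaps", M0 = array(M0, dim = d),
                 R1 = array(R1, dim = d), R2star = array(R2star, dim = d),
                 FA = array(numeric(0)), fiberTheta = array(numeric(0)),
                 spacing = c(1, 1, 1))
}

mkField <- function(vals, unit = "rad_s") {
    methods::new("FieldMap", values = vals, unit = unit, B0 = 7,
                 spacing = c(1, 1, 1))
}

test_that("spoiled-GRE signal matches the scalar oracle and its limits", {
    d <- c(3, 3, 3)
    ## saturation-recovery limit: alpha = 90 deg, TR >> T1, TE -> 0
    p <- protocolSpec(TR = 50, TE = 1e-9, flipAngle = 90)
    s <- greSignal(mkParams(d, M0 = 2, R1 = 1, R2star = 0),
                   mkField(array(0, dim = d)), 0, p)
    expect_equal(Re(echoData(s, 1)), array(2, dim = d), tolerance = 1e-9)

    ## the fixed-voxel oracle check
    p2 <- protocolSpec(TR = 0.05, TE = 0.020, flipAngle = 15)
    dw <- 2 * pi * 10
    s2 <- greSignal(mkParams(d), mkField(array(dw, dim = d)), 0, p2)
    oracle <- scalarGRE(1, 1, 20, 0.05, 0.020, 15, 0, dw)
    expect_equal(Mod(echoData(s2, 1))[1], Mod(oracle), tolerance = 1e-12)
    expect_equal(Arg(echoData(s2, 1))[1], Arg(oracle), tolerance = 1e-12)

    ## phase is exactly linear in TE per voxel
    p3 <- protocolSpec(0.05, c(4, 12, 20, 28) * 1e-3, 15)
    s3 <- greSignal(mkParams(d), mkField(array(5, dim = d)), 0.3, p3)
    ph <- vapply(1:4, function(j) Arg(echoData(s3, j))[1], numeric(1))
    expect_equal(diff(ph), rep(5 * 8e-3, 3), tolerance = 1e-12)

    expect_error(greSignal(mkParams(d, R2star = -1),
                           mkField(array(0, dim = d)), 0, p2), "negative")
})

test_that("steady-state magnitude peaks at the Ernst angle", {
    TR <- 0.05; R1 <- 1
    ernst <- acos(exp(-TR * R1)) * 180 / pi
    mag <- function(alpha) {
        p <- protocolSpec(TR, 1e-6, alpha)
        Mod(echoData(greSignal(mkParams(c(2, 2, 2)),
                               mkField(array(0, dim = c(2, 2, 2))), 0, p), 1))[1]
    }
    grid <- seq(1, 90, by = 0.5)
    expect_equal(grid[which.max(vapply(grid, mag, numeric(1)))], ernst,
                 tolerance = 0.5)
})

test_that("transceiver phase spans exactly 2 pi over the mask, seeded", {
    d <- c(16, 16, 16)
    mask <- array(FALSE, dim = d); mask[4:12, 4:12, 4:12] <- TRUE
    ph <- transceiverPhase(d, mask, seed = 3)
    expect_equal(diff(range(ph[mask])), 2 * pi, tolerance = 1e-9)
    expect_identical(ph, transceiverPhase(d, mask, seed = 3))
    expect_false(identical(ph, transceiverPhase(d, mask, seed = 4)))
    expect_warning(transceiverPhase(d, mask, seed = 1, order = 0L), "degenerate")
})

test_that("complex noise has the prescribed per-channel SD and is reproducible", {
    d <- c(48, 48, 48)
    p <- protocolSpec(0.05, c(4, 20) * 1e-3, 15)
    s <- greSignal(mkParams(d), mkField(array(0, dim = d)), 0, p)
    n1 <- addNoise(s, peakSNR = 100, seed = 9)
    n2 <- addNoise(s, peakSNR = 100, seed = 9)
    expect_identical(echoData(n1, 1), echoData(n2, 1))
    expect_identical(echoData(addNoise(s, peakSNR = Inf), 1), echoData(s, 1))

    sigma <- max(Mod(echoData(s, 1))) / 100
    resid <- Re(echoData(n1, 1) - echoData(s, 1))
    expect_equal(sd(resid), sigma, tolerance = 0.02)
})

test_that("Fourier downsampling preserves DC and splits at the new Nyquist", {
    n <- 32
    d <- c(n, n, 8)
    ## constant volume unchanged in value
    cst <- fourierDownsample(array(3.5, dim = d), c(1, 1, 1), c(2, 2, 1))
    expect_equal(dim(cst$data), c(16, 16, 8))
    expect_equal(cst$data, array(3.5, dim = c(16, 16, 8)), tolerance = 1e-12)

    x <- (0:(n - 1))
    low <- array(sin(2 * pi * 3 * x / n), dim = d)       # 3 cycles: kept
    high <- array(sin(2 * pi * 12 * x / n), dim = d)     # 12 cycles: cut at nt=16
    lowD <- fourierDownsample(low, c(1, 1, 1), c(2, 2, 1))$data
    highD <- fourierDownsample(high, c(1, 1, 1), c(2, 2, 1))$data
    xt <- (0:15) * 2
    expect_equal(lowD[, 1, 1], sin(2 * pi * 3 * xt / n), tolerance = 1e-10)
    expect_lt(max(abs(highD)), 1e-10)

    expect_error(fourierDownsample(low, c(1, 1, 1), c(0.5, 1, 1)), "spacing")
})

test_that("Gibbs suppression tames truncation ringing and is near idempotent", {
    ## 1-D box, Fourier-cropped 2x
    n <- 128
    box <- numeric(n); box[33:96] <- 1
    crop <- fourierDownsample(array(box, dim = c(n, 1, 1)),
                              c(1, 1, 1), c(2, 1, 1))$data[, 1, 1]
    ## box support on the cropped grid is 17..48 (transition samples 17, 49)
    ring <- c(13:16, 50:53)                  # ringing lobes outside the box
    ringNear <- max(abs(crop[ring]))
    sup <- gibbsSuppress(crop)
    expect_lt(max(abs(sup[ring])), 0.5 * ringNear)
    ## interior overshoot next to the edge drops too
    expect_lt(max(abs(sup[c(18:21, 44:47)] - 1)),
              0.5 * max(abs(crop[c(18:21, 44:47)] - 1)))

    ## near identity on smooth data
    sm <- sin(2 * pi * (0:63) / 64)
    vol <- array(sm, dim = c(64, 8, 8))
    out <- gibbsSuppress(vol)
    expect_lt(sqrt(mean((out - vol)^2)) / sqrt(mean(vol^2)), 0.01)

    ## applying twice changes little compared with the first pass
    once <- gibbsSuppress(crop)
    twice <- gibbsSuppress(once)
    expect_lt(sqrt(mean((twice - once)^2)),
              0.1 * sqrt(mean((once - crop)^2)) + 1e-12)
})
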