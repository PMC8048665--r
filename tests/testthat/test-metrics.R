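test_that("demeaned nRMSE identities hold", {
    set.seed(13)
    d <- c(12, 12, 12)
    truth <- array(rnorm(prod(d), sd = 0.05), dim = d)
    mask <- array(FALSE, dim = d); mask[3:10, 3:10, 3:10] <- TRUE
    expect_equal(nrmse(truth, truth, mask), 0)
    expect_equal(nrmse(truth + 0.42, truth, mask), 0, tolerance = 1e-9)
    t0 <- truth
    t0[mask] <- t0[mask] - mean(t0[mask])       # zero-mean truth
    expect_equal(nrmse(-t0, t0, mask), 200, tolerance = 1e-9)
    expect_error(nrmse(truth, array(1, dim = d), mask), "constant")
})

test_that("detrended RMSE is scale invariant while nRMSE is not", {
    set.seed(14)
    d <- c(24, 24, 24)
    truth <- array(rnorm(prod(d), sd = 0.05), dim = d)
    roi <- array(TRUE, dim = d)
    expect_equal(as.numeric(rmseDetrended(2 * truth, truth, roi)), 0,
                 tolerance = 1e-9)
    expect_equal(as.numeric(rmseDetrended(truth, truth, roi)), 0)
    expect_gt(nrmse(2 * truth, truth, roi), 50)

    ## additive zero-mean noise of SD sigma scores ~ 100 sigma / SD(truth)
    sigma <- 0.01
    noisy <- truth + array(rnorm(prod(d), sd = sigma), dim = d)
    sc <- as.numeric(rmseDetrended(noisy, truth, roi))
    expect_equal(sc, 100 * sigma / sd(truth[roi]), tolerance = 0.1)

    ## non-positive slope is flagged, not detrended
    flipped <- rmseDetrended(-truth, truth, roi)
    expect_false(attr(flipped, "detrended"))
})

test_that("deep gray-matter slope deviation matches regression oracles", {
    d <- c(20, 20, 20)
    prescribed <- c(0.044, 0.131, 0.038, 0.1, 0.152, 0.111)
    masks <- lapply(1:6, function(i) {
        m <- array(FALSE, dim = d); m[(3 * i - 2):(3 * i), 4:6, 4:6] <- TRUE; m
    })
    truth <- array(0, dim = d)
    for (i in 1:6) truth[masks[[i]]] <- prescribed[i]
    expect_equal(deviationFromLinearSlope(truth, masks, prescribed), 0)
    expect_equal(deviationFromLinearSlope(0.8 * truth, masks, prescribed), 0.2,
                 tolerance = 1e-12)

    ## constant offset, intercept-form: compare with an lm() oracle
    recon <- truth + 0.05
    means <- vapply(masks, function(m) mean(recon[m]), numeric(1))
    oracle <- abs(unname(coef(lm(means ~ prescribed))[2]) - 1)
    expect_equal(deviationFromLinearSlope(recon, masks, prescribed,
                                          intercept = TRUE), oracle,
                 tolerance = 1e-12)
    expect_error(deviationFromLinearSlope(truth, masks[1], prescribed[1]),
                 "two regions")
})

test_that("calcification streak ROI is the prescribed hollow prism", {
    d <- c(40, 40, 40)
    calc <- array(FALSE, dim = d); calc[19:22, 19:21, 20:23] <- TRUE
    set.seed(15)
    truth <- array(rnorm(prod(d), sd = 0.02), dim = d)

    expect_equal(calcStreak(truth, truth, calc), 0)
    expect_equal(calcStreak(truth + 3, truth, calc), 0, tolerance = 1e-12)

    ## enumerate the shell voxels directly as the oracle
    idx <- which(calc, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    inBox <- function(p, lo, hi) all(p >= lo) && all(p <= hi)
    streak <- array(rnorm(prod(d), sd = 0.5), dim = d)
    recon <- truth + streak
    vals <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        p <- c(i, j, k)
        if (inBox(p, lo - 8, hi + 8) && !inBox(p, lo - 2, hi + 2))
            vals <- c(vals, streak[i, j, k])
    }
    expect_equal(calcStreak(recon, truth, calc), 100 * sd(vals),
                 tolerance = 1e-12)
})

test_that("calcification moment is the digitised volume integral", {
    d <- c(30, 30, 30)
    ax <- seq_len(d[1]) - 15.5
    x <- array(ax, dim = d); y <- aperm(x, c(2, 1, 3)); z <- aperm(x, c(3, 2, 1))
    sphere <- x^2 + y^2 + z^2 <= 3^2
    chi <- array(0, dim = d); chi[sphere] <- -3.3
    region <- chi != 0
    expect_equal(calcMoment(chi, region, c(1, 1, 1)), -3.3 * sum(sphere))
    ## anisotropic voxels scale the integral by the voxel volume
    expect_equal(calcMoment(chi, region, c(0.5, 0.5, 2)),
                 -3.3 * sum(sphere) * 0.5)
    expect_equal(calcMoment(array(0, dim = d), region), 0)
    ## invariant to redistribution preserving the sum
    chi2 <- chi; v <- which(region)
    chi2[v[1]] <- chi2[v[1]] + 1; chi2[v[2]] <- chi2[v[2]] - 1
    expect_equal(calcMoment(chi2, region), calcMoment(chi, region))
})

test_that("the full metric report carries all seven challenge scores", {
    h <- getHeadSmall()
    truth <- chiData(composeHeadChi(h, mode = "local"))
    set.seed(16)
    recon <- truth + array(rnorm(length(truth), sd = 0.005), dim = dim(truth))
    mr <- scoreReconstruction(recon, truth, h$masks,
                              spacing = voxelSpacing(h$params))
    v <- metricValues(mr)
    expect_named(v, c("nRMSE", "rmse_detrend_tissue", "rmse_detrend_blood",
                      "rmse_detrend_dgm", "deviation_from_linear_slope",
                      "calc_streak", "calc_moment", "calc_moment_dev"),
                 ignore.order = TRUE)
    expect_true(all(is.finite(v)))
    ## identical reconstruction scores zero on all RMSE-type metrics
    v0 <- metricValues(scoreReconstruction(truth, truth, h$masks,
                                           spacing = voxelSpacing(h$params)))
    expect_equal(unname(v0[c("nRMSE", "rmse_detrend_tissue",
                             "rmse_detrend_blood", "rmse_detrend_dgm",
                             "calc_streak", "calc_moment_dev")]),
                 rep(0, 6), tolerance = 1e-9)
})
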