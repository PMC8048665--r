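test_that("modulated tissue susceptibility follows the linear relaxometry model", {
    d <- c(4, 4, 4)
    tb <- tissueTable("model1")
    ref <- data.frame(label = c(1L, 2L, 13L),
                      R2star_mean = c(35, 70, 600), R1_mean = c(0.6, 0.9, 3))
    mk <- function(val) array(val, dim = d)
    params <- methods::new("ParameterMaps", M0 = mk(1),
                           R1 = mk(0.9), R2star = mk(70),
                           FA = array(numeric(0)), fiberTheta = array(numeric(0)),
                           spacing = c(1, 1, 1))

    ## at the reference rates the class mean is returned exactly
    expect_equal(tissueChiMap(params, tb, 2L, ref),
                 mk(0.131), tolerance = 0)

    ## caudate with R2* one unit above reference: 0.044 - 0.012
    params2 <- methods::new("ParameterMaps", M0 = mk(1),
                            R1 = mk(0.6), R2star = mk(36),
                            FA = array(numeric(0)), fiberTheta = array(numeric(0)),
                            spacing = c(1, 1, 1))
    expect_equal(tissueChiMap(params2, tb, 1L, ref), mk(0.032))

    ## piece-wise-constant class ignores the maps entirely
    expect_equal(tissueChiMap(params2, tb, 13L, ref), mk(-2.1))

    ## linearity: scaling the R2* deviation scales that term's contribution
    base <- tissueChiMap(params2, tb, 1L, ref) - 0.044
    params3 <- methods::new("ParameterMaps", M0 = mk(1),
                            R1 = mk(0.6), R2star = mk(35 + 5),
                            FA = array(numeric(0)), fiberTheta = array(numeric(0)),
                            spacing = c(1, 1, 1))
    expect_equal(tissueChiMap(params3, tb, 1L, ref) - 0.044, 5 * base)

    expect_error(tissueChiMap(params, tb, 99L, ref), "99")
})

test_that("partial-volume maps are normalised and match a direct convolution oracle", {
    set.seed(42)
    d <- c(16, 16, 16)
    labels <- array(1L, dim = d)
    labels[9:16, , ] <- 8L          # two half-space brain tissues
    labels[, , 1:4] <- 13L          # a non-brain slab (sharp)
    flags <- c(`1` = TRUE, `8` = TRUE, `13` = FALSE)

    P <- partialVolumeMaps(labels, flags, fwhmVoxels = 1.2)
    tot <- Reduce(`+`, P)
    expect_true(max(abs(tot - 1)) < 1e-6)
    expect_true(all(vapply(P, function(p) all(p >= 0), logical(1))))

    ## non-brain mask passes through unsmoothed: support stays its own label
    ## (renormalisation against smoothed neighbours reduces P only at its
    ## boundary)
    expect_identical(P[["13"]] > 0, labels == 13L)
    expect_gt(min(P[["13"]][, , 1:2]), 1 - 1e-3)

    ## interior voxel far from boundaries: probability ~ 1
    expect_gt(P[["1"]][4, 8, 10], 1 - 1e-3)

    ## two half-spaces meeting at a plane: 0.5 each at the interface
    ## (between voxels 8 and 9; both adjacent planes are symmetric)
    expect_equal(P[["1"]][8, 8, 10] + P[["1"]][9, 8, 10], 1, tolerance = 1e-9)
    expect_equal(P[["1"]][8, 8, 10], P[["8"]][9, 8, 10], tolerance = 1e-9)

    ## brute-force spatial convolution oracle for the smoothed mask
    sigma <- 1.2 / (2 * sqrt(2 * log(2)))
    r <- ceiling(4 * sigma)
    off <- -r:r
    k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    m <- (labels == 1L) * 1
    sm <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
        acc <- 0
        for (a in off) for (b in off) for (cc in off) {
            ii <- i + a; jj <- j + b; ll <- l + cc
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                ll >= 1 && ll <= d[3])
                acc <- acc + m[ii, jj, ll] *
                    k1[a + r + 1] * k1[b + r + 1] * k1[cc + r + 1]
        }
        sm[i, j, l] <- acc
    }
    S8 <- gaussianSmooth((labels == 8L) * 1, 1.2)
    S13 <- (labels == 13L) * 1
    oracleP1 <- sm / (sm + S8 + S13 + (sm + S8 + S13 == 0))
    expect_equal(P[["1"]], oracleP1, tolerance = 1e-10)

    ## a label volume with no brain tissue is rejected
    expect_error(partialVolumeMaps(array(13L, dim = c(4, 4, 4)),
                                   c(`13` = FALSE)), "brain tissue")
})

test_that("gradient-reliability blend interpolates linearly between models", {
    d <- c(3, 3, 3)
    full <- array(0.2, dim = d)
    noR2 <- array(0.1, dim = d)
    g <- array(0, dim = d)
    g[1, 1, 1] <- 0           # fully trusted
    g[2, 1, 1] <- 0.5         # above gHi
    g[3, 1, 1] <- (0.08 + 0.3) / 2
    out <- gradientReliabilityBlend(full, noR2, g)
    expect_identical(out[1, 1, 1], 0.2)
    expect_identical(out[2, 1, 1], 0.1)
    expect_equal(out[3, 1, 1], 0.15)
    expect_error(gradientReliabilityBlend(full, noR2, g, gLo = 0.3, gHi = 0.1),
                 "gLo")
})

test_that("susceptibility composition is a probability-weighted mixture", {
    d <- c(6, 6, 6)
    tb <- tissueTable("model1")
    labels <- array(13L, dim = d)   # bone: piece-wise constant -2.1
    labels[1:3, , ] <- 14L          # air: 9.2
    mk <- function(val) array(val, dim = d)
    params <- methods::new("ParameterMaps", M0 = mk(1), R1 = mk(1),
                           R2star = mk(30), FA = array(numeric(0)),
                           fiberTheta = array(numeric(0)), spacing = c(1, 1, 1))
    model <- methods::new("TissueModel", labels = labels,
                          probMaps = list(`13` = mk(0.25), `14` = mk(0.75)),
                          refMeans = referenceMeans(labels, params),
                          spacing = c(1, 1, 1))
    out <- composeChi(model, params, tb, mk(TRUE))
    expect_equal(chiData(out), mk(0.25 * -2.1 + 0.75 * 9.2))

    ## single tissue with P = 1 reproduces the class map; with binary P and
    ## piece-wise-constant classes the composition is a label lookup
    model2 <- methods::new("TissueModel", labels = labels,
                           probMaps = list(`13` = (labels == 13L) * 1,
                                           `14` = (labels == 14L) * 1),
                           refMeans = referenceMeans(labels, params),
                           spacing = c(1, 1, 1))
    out2 <- composeChi(model2, params, tb, mk(TRUE))
    lookup <- ifelse(labels == 13L, -2.1, 9.2)
    expect_identical(chiData(out2), array(lookup, dim = d))
})

test_that("localisation demeans inside the mask, zeroes outside, and is idempotent", {
    set.seed(7)
    d <- c(10, 10, 10)
    chi <- array(rnorm(prod(d), sd = 0.05), dim = d)
    mask <- array(FALSE, dim = d); mask[3:8, 3:8, 3:8] <- TRUE
    sv <- methods::new("SusceptibilityVolume", chi = chi, mode = "whole_head",
                       brainMask = mask * TRUE, spacing = c(1, 1, 1))
    loc <- localizeChi(sv)
    expect_lt(abs(mean(chiData(loc)[mask])), 1e-9)
    expect_true(all(chiData(loc)[!mask] == 0))

    loc2 <- localizeChi(loc)
    expect_equal(chiData(loc2), chiData(loc), tolerance = 1e-14)

    ## constant input collapses to zero
    svc <- methods::new("SusceptibilityVolume", chi = array(0.3, dim = d),
                        mode = "whole_head", brainMask = mask * TRUE,
                        spacing = c(1, 1, 1))
    expect_true(all(abs(chiData(localizeChi(svc))[mask]) < 1e-15))

    expect_error(localizeChi(sv, array(FALSE, dim = d)), "mask")
})
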