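#' @include phantom-model.R
NULL

## Per-class relaxometry targets (7 T) used by the generator: T1/T2* in ms,
## M0 in arbitrary units, and absolute texture SDs of the rates (s^-1).
## The SDs are sized so that, through the Model-1 modulation coefficients,
## each term contributes roughly +/- 0.06 ppm (3 SD) of susceptibility
## texture -- the amplitude seen in measured QSM -- capped at a few percent
## of the rate itself for weakly coupled tissues.
HEAD_TISSUE_PROPS <- data.frame(
    name = c("Caudate", "GlobusPallidus", "Putamen", "RedNucleus",
             "DentateNucleus", "SubstantiaNigra", "Thalamus", "WhiteMatter",
             "GrayMatter", "CSF", "Blood", "Fat", "Bone", "Air", "Muscle",
             "Calcification"),
    T1 = c(1600, 1100, 1500, 1200, 1300, 1200, 1500, 1100,
           1900, 4000, 2100, 400, 300, 1000, 1800, 1000),
    T2star = c(28, 14, 22, 18, 16, 15, 30, 26,
               33, 50, 12, 15, 1.5, 1, 18, 2),
    M0 = c(0.85, 0.8, 0.85, 0.8, 0.8, 0.8, 0.85, 0.75,
           0.85, 1.0, 0.9, 0.9, 0.1, 0, 0.8, 0.02),
    sdR1 = c(0.0179, 0.0237, 0.0108, 0.0112, 0.0117, 0.0134, 0.0157, 0.0174,
             0.0143, 0.0125, 0.0238, 0.075, 0.1, 0, 0.0167, 0.03),
    sdR2star = c(1.67, 0.769, 0.8, 0.455, 0.312, 0.267, 0.233, 0.256,
                 0.211, 1.6, 0.345, 3.33, 13.3, 0, 2.78, 10))

#' Specification of a synthetic head phantom
#'
#' Geometry defaults are expressed for the default 128^3 grid and scale
#' proportionally with the grid; every element can be overridden. All sizes
#' are in voxels.
#'
#' @param shape grid size (default 128^3)
#' @param spacing mm per axis (default 1 mm isotropic)
#' @param seed RNG seed controlling textures, FA/fiber fields and vein
#'   placement; the run is fully deterministic given the seed
#' @param scalpSemi outer (scalp) ellipsoid semi-axes
#' @param shells named thicknesses of the concentric layers (fat, muscle,
#'   bone, csf, gm), outermost first
#' @param nucleusRadii named radii of the six deep-gray nuclei spheres
#' @param thalamusRadius radius of the thalamus sphere
#' @param veinRadius vein cylinder radius (1-3)
#' @param calcRadius calcification sphere radius (2-4)
#' @param corrLen texture correlation length (Gaussian FWHM), voxels
#' @return list of class `headSpec`
#' @export
headSpec <- function(shape = c(128, 128, 128), spacing = c(1, 1, 1), seed = 1L,
                     scalpSemi = NULL, shells = NULL, nucleusRadii = NULL,
                     thalamusRadius = NULL, veinRadius = NULL,
                     calcRadius = NULL, corrLen = 3) {
    shape <- rep(shape, length.out = 3)
    sc <- min(shape) / 128
    rs <- function(x, minv = 1) pmax(minv, floor(x * sc + 0.5))
    spec <- list(
        shape = as.integer(shape), spacing = rep(spacing, length.out = 3),
        seed = as.integer(seed),
        scalpSemi = if (is.null(scalpSemi)) 0.82 * shape / 2 else scalpSemi,
        shells = if (is.null(shells))
            c(fat = rs(3), muscle = rs(2), bone = rs(4), csf = rs(3), gm = rs(3))
            else shells,
        nucleusRadii = if (is.null(nucleusRadii))
            c(Caudate = rs(5, 2), GlobusPallidus = rs(5, 2), Putamen = rs(6, 2),
              RedNucleus = rs(4, 2), DentateNucleus = rs(5, 2),
              SubstantiaNigra = rs(4, 2)) else nucleusRadii,
        thalamusRadius = if (is.null(thalamusRadius)) rs(7, 2) else thalamusRadius,
        veinRadius = if (is.null(veinRadius)) rs(2, 1) else veinRadius,
        calcRadius = if (is.null(calcRadius)) rs(3, 2) else calcRadius,
        corrLen = corrLen)
    class(spec) <- "headSpec"
    spec
}

## Gaussian random field: seeded white noise smoothed to the requested
## correlation length and renormalised to unit variance.
gaussianRandomField <- function(shape, corrLen) {
    z <- array(stats::rnorm(prod(shape)), dim = shape)
    z <- gaussianSmooth(z, corrLen)
    (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic head phantom
#'
#' Builds a brain-like label volume (16 tissue classes: six deep-gray
#' nuclei, thalamus, white matter, cortical gray-matter shell, CSF, veins,
#' fat/muscle/bone/air head layers, one calcification), textured R1/R2*
#' parameter maps around per-class 7 T means (Gaussian random fields,
#' clipped at +/- 3 SD), an M0 map with mild smooth modulation, FA and
#' fiber-angle maps supported on white matter, and the ROI masks the
#' challenge metrics use. Deterministic given `spec$seed`.
#'
#' @param spec a [headSpec()]
#' @param table a [TissueParamTable-class] used for partial-volume flags
#' @param pvFwhm partial-volume smoothing FWHM, voxels
#' @return list with `model` ([TissueModel-class]), `params`
#'   ([ParameterMaps-class]), `masks` (named list of logical arrays:
#'   `brain`, `tissue`, `wm`, `blood`, `dgm`, `dgm_regions`, `calc`,
#'   `calc_region`) and `spec`
#' @export
generateHead <- function(spec = headSpec(), table = tissueTable("model1"),
                         pvFwhm = 1.2) {
    d <- spec$shape
    set.seed(spec$seed)
    ctr <- (d + 1) / 2
    cx <- array(seq_len(d[1]), dim = d)
    cy <- aperm(array(seq_len(d[2]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
    cz <- aperm(array(seq_len(d[3]), dim = d[c(3, 1, 2)]), c(2, 3, 1))

    insideEllipsoid <- function(center, semi)
        ((cx - center[1]) / semi[1])^2 + ((cy - center[2]) / semi[2])^2 +
        ((cz - center[3]) / semi[3])^2 <= 1
    insideSphere <- function(center, r)
        (cx - center[1])^2 + (cy - center[2])^2 + (cz - center[3])^2 <= r^2
    insideCylinder <- function(center, u, r, halfLen) {
        u <- u / sqrt(sum(u^2))
        px <- cx - center[1]; py <- cy - center[2]; pz <- cz - center[3]
        t <- px * u[1] + py * u[2] + pz * u[3]
        d2 <- (px - t * u[1])^2 + (py - t * u[2])^2 + (pz - t * u[3])^2
        d2 <= r^2 & abs(t) <= halfLen
    }

    if (any(ctr + spec$scalpSemi > d - 0.5) || any(ctr - spec$scalpSemi < 1.5))
        stop("geometry error: scalp ellipsoid exceeds the grid (semi-axes ",
             paste(round(spec$scalpSemi, 1), collapse = "/"), " on grid ",
             paste(d, collapse = "x"), ")")

    sh <- spec$shells
    brainSemi <- spec$scalpSemi - sum(sh)
    if (any(brainSemi < 4))
        stop("geometry error: shells leave no room for the brain (semi-axes ",
             paste(round(brainSemi, 1), collapse = "/"), ")")

    L <- TISSUE_LABELS
    labels <- array(L[["Air"]], dim = d)
    layerOrder <- c("Fat", "Muscle", "Bone", "CSF", "GrayMatter")
    semi <- spec$scalpSemi
    labels[insideEllipsoid(ctr, semi)] <- L[["Fat"]]
    for (i in seq_along(layerOrder)[-1]) {
        semi <- semi - sh[i - 1]
        labels[insideEllipsoid(ctr, semi)] <- L[[layerOrder[i]]]
    }
    gmSemi <- semi
    wmSemi <- gmSemi - sh[["gm"]]
    labels[insideEllipsoid(ctr, wmSemi)] <- L[["WhiteMatter"]]

    ## deep structures, placed at fixed fractions of the WM ellipsoid
    nucleusPos <- list(
        Caudate = c(0.35, 0.25, 0.15), GlobusPallidus = c(-0.35, 0.25, 0.15),
        Putamen = c(0.45, -0.25, 0.0), RedNucleus = c(-0.45, -0.25, 0.0),
        DentateNucleus = c(0.0, 0.5, -0.3), SubstantiaNigra = c(0.0, -0.5, -0.3))
    placeSphere <- function(frac, r, what) {
        center <- ctr + frac * wmSemi
        reach <- sqrt(sum(((center - ctr) / (wmSemi - r))^2))
        if (any(wmSemi - r <= 0) || reach > 1)
            stop("geometry error: ", what, " (radius ", r,
                 ") does not fit inside the white matter ellipsoid")
        insideSphere(center, r)
    }
    dgmRegions <- list()
    for (nm in names(nucleusPos)) {
        m <- placeSphere(nucleusPos[[nm]], spec$nucleusRadii[[nm]], nm)
        labels[m] <- L[[nm]]
        dgmRegions[[nm]] <- m
    }
    thal <- placeSphere(c(0.0, 0.05, 0.45), spec$thalamusRadius, "thalamus")
    labels[thal] <- L[["Thalamus"]]

    calcCenterFrac <- c(0.3, 0.45, 0.35)
    calcMask <- placeSphere(calcCenterFrac, spec$calcRadius, "calcification")
    labels[calcMask] <- L[["Calcification"]]

    ## veins: one superior-sagittal-like cylinder plus two seeded oblique ones
    brainVol <- insideEllipsoid(ctr, gmSemi)
    veins <- insideCylinder(ctr + c(0, 0, 0.75 * wmSemi[3]), c(0, 1, 0),
                            spec$veinRadius, 0.5 * gmSemi[2])
    for (i in 1:2) {
        u <- stats::rnorm(3); u[3] <- abs(u[3]) + 0.5
        cshift <- stats::runif(3, -0.3, 0.3) * wmSemi
        veins <- veins | insideCylinder(ctr + cshift, u,
                                        max(1, spec$veinRadius - 1), 0.6 * wmSemi[1])
    }
    veins <- veins & brainVol & !calcMask
    labels[veins] <- L[["Blood"]]

    ## air cavities (sinus-like), carved only from non-brain head layers
    airCarve <- insideEllipsoid(ctr + c(0, 0.55, -0.85) * spec$scalpSemi,
                                pmax(2, 0.12 * spec$scalpSemi)) |
        insideEllipsoid(ctr + c(0.25, 0.5, -0.9) * spec$scalpSemi,
                        pmax(2, 0.09 * spec$scalpSemi))
    carvable <- labels %in% c(L[["Fat"]], L[["Muscle"]], L[["Bone"]], L[["CSF"]])
    labels[airCarve & array(carvable, dim = d)] <- L[["Air"]]

    ## textured parameter maps
    props <- HEAD_TISSUE_PROPS
    zR1 <- gaussianRandomField(d, spec$corrLen)
    zR2 <- gaussianRandomField(d, spec$corrLen)
    zM0 <- gaussianRandomField(d, max(spec$corrLen * 3, 6))
    clip3 <- function(z) pmax(-3, pmin(3, z))
    R1 <- array(0, dim = d); R2star <- array(0, dim = d); M0 <- array(0, dim = d)
    for (i in seq_len(nrow(props))) {
        id <- L[[props$name[i]]]
        m <- labels == id
        if (!any(m)) next
        r1 <- 1000 / props$T1[i]
        r2 <- 1000 / props$T2star[i]
        R1[m] <- r1 + props$sdR1[i] * clip3(zR1[m])
        R2star[m] <- r2 + props$sdR2star[i] * clip3(zR2[m])
        M0[m] <- props$M0[i] * (1 + 0.05 * clip3(zM0[m]))
    }
    R1 <- pmax(R1, 0)
    R2star <- pmax(R2star, 0)
    M0 <- pmax(M0, 0)

    ## white-matter microstructure inputs
    wm <- labels == L[["WhiteMatter"]]
    FA <- array(0, dim = d)
    theta <- array(0, dim = d)
    zFA <- gaussianRandomField(d, spec$corrLen)
    zTh <- gaussianRandomField(d, max(spec$corrLen * 2, 4))
    FA[wm] <- pmin(1, pmax(0, 0.7 + 0.1 * zFA[wm]))
    theta[wm] <- (pi / 2) * stats::pnorm(zTh[wm])

    params <- methods::new("ParameterMaps", M0 = M0, R1 = R1, R2star = R2star,
                           FA = FA, fiberTheta = theta, spacing = spec$spacing)
    model <- tissueModel(labels, params, table, fwhmVoxels = pvFwhm)

    ## intracranial mask: everything inside the skull, CSF included, as in
    ## QSM-challenge brain masks
    brainLabels <- c(L[["Caudate"]], L[["GlobusPallidus"]], L[["Putamen"]],
                     L[["RedNucleus"]], L[["DentateNucleus"]],
                     L[["SubstantiaNigra"]], L[["Thalamus"]], L[["WhiteMatter"]],
                     L[["GrayMatter"]], L[["CSF"]], L[["Blood"]],
                     L[["Calcification"]])
    brain <- array(labels %in% brainLabels, dim = d)
    masks <- list(
        brain = brain,
        tissue = array(labels %in% c(L[["WhiteMatter"]], L[["GrayMatter"]]), dim = d),
        wm = wm,
        blood = binaryDilate(labels == L[["Blood"]], 1L) & brain,
        dgm = array(labels %in% unlist(L[DGM_LABELS]), dim = d),
        dgm_regions = lapply(DGM_LABELS, function(nm) labels == L[[nm]]),
        calc = labels == L[["Calcification"]],
        calc_region = withinChebyshev(labels == L[["Calcification"]], 2L))
    names(masks$dgm_regions) <- DGM_LABELS

    list(model = model, params = params, masks = masks, spec = spec)
}
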