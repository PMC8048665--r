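#' @include synthetic-head.R signal-sim.R phase-pipeline.R inversion.R metrics.R
NULL

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file
#' @return list with `data` (numeric array), `spacing` (mm per axis) and
#'   `affine`; the voxel lattice is used as the internal grid, with the
#'   third axis taken as B0
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    aff <- RNifti::xform(img)
    rot <- aff[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(rot))))
        warning("oblique/sheared affine in ", basename(path),
                "; the voxel lattice is used as-is")
    list(data = array(as.numeric(img), dim = dim(img)[1:3]),
         spacing = sp, affine = aff)
}

#' Write a NIfTI volume
#'
#' @param data numeric 3-D array
#' @param path output path (.nii or .nii.gz)
#' @param spacing mm per axis
#' @param description free-text header description (e.g. the field unit)
#' @return `path`, invisibly
#' @export
writeVolume <- function(data, path, spacing = c(1, 1, 1), description = "") {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- spacing
    if (nzchar(description)) img$descrip <- substr(description, 1, 79)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Materialise a phantom directory
#'
#' Writes labels, M0/R1/R2*/FA/theta, the ROI masks and the tissue table of
#' a generated head to NIfTI + CSV files, ready for `simulateProtocol()`.
#'
#' @param head result of [generateHead()]
#' @param dir output directory (created)
#' @param table the [TissueParamTable-class] to ship alongside
#' @return `dir`, invisibly
#' @export
writePhantom <- function(head, dir, table = tissueTable("model1")) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sp <- voxelSpacing(head$params)
    writeVolume(tissueLabels(head$model) * 1, file.path(dir, "labels.nii.gz"), sp, "tissue labels")
    writeVolume(head$params@M0, file.path(dir, "M0.nii.gz"), sp, "M0 a.u.")
    writeVolume(head$params@R1, file.path(dir, "R1.nii.gz"), sp, "R1 1/s")
    writeVolume(head$params@R2star, file.path(dir, "R2star.nii.gz"), sp, "R2* 1/s")
    writeVolume(head$params@FA, file.path(dir, "FA.nii.gz"), sp, "fractional anisotropy")
    writeVolume(head$params@fiberTheta, file.path(dir, "fiber_theta.nii.gz"), sp, "fiber angle rad")
    for (nm in c("brain", "tissue", "wm", "blood", "dgm", "calc", "calc_region"))
        writeVolume(head$masks[[nm]] * 1, file.path(dir, paste0("mask_", nm, ".nii.gz")),
                    sp, paste(nm, "mask"))
    utils::write.csv(paramTable(table), file.path(dir, "tissue_table.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' Compose ground-truth susceptibility for a generated head
#'
#' Runs the full composition chain: per-class modulated susceptibility, the
#' R2*-reliability blend driven by a low-pass-filtered provisional field
#' gradient, probability-weighted mixing, and optional localisation
#' (brain-only demeaned variant).
#'
#' When a brain-tissue class is evaluated at voxels outside its own label
#' (through the partial-volume tails of its smoothed mask), the local
#' relaxation rates can belong to a very different compartment -- most
#' extremely inside the signal-free calcification, whose R2* is an order of
#' magnitude above any brain tissue. To keep the extrapolated modulation
#' physical, each class's rate maps are clamped to the range observed over
#' its own binary label before evaluating the modulation (a no-op inside the
#' class).
#'
#' @param head result of [generateHead()]
#' @param table a [TissueParamTable-class]
#' @param mode `"whole_head"` or `"local"`
#' @param gradientBlend apply the field-gradient reliability blend
#' @param lpFwhmMm low-pass FWHM for the provisional field-gradient map, mm
#' @return a [SusceptibilityVolume-class]
#' @export
composeHeadChi <- function(head, table = tissueTable("model1"),
                           mode = c("whole_head", "local"),
                           gradientBlend = TRUE, lpFwhmMm = 5) {
    mode <- match.arg(mode)
    labels <- tissueLabels(head$model)
    ref <- head$model@refMeans
    clampedChi <- function(dropR2star) {
        out <- list()
        for (nm in names(probabilityMaps(head$model))) {
            id <- as.integer(nm)
            row <- tissueRow(table, id)
            j <- match(id, ref$label)
            own <- labels == id
            r2 <- pmin(pmax(head$params@R2star, min(head$params@R2star[own])),
                       max(head$params@R2star[own]))
            r1 <- pmin(pmax(head$params@R1, min(head$params@R1[own])),
                       max(head$params@R1[own]))
            a <- if (dropR2star) 0 else row$a_tissue
            out[[nm]] <- row$chi_mean +
                a * (r2 - ref$R2star_mean[j]) +
                row$b_tissue * (r1 - ref$R1_mean[j])
        }
        out
    }
    full <- composeChi(head$model, head$params, table, head$masks$brain,
                       perTissueChi = clampedChi(FALSE))
    chi <- full
    if (gradientBlend) {
        noR2 <- composeChi(head$model, head$params, table, head$masks$brain,
                           perTissueChi = clampedChi(TRUE))
        ## provisional field from the full composition drives the blend
        sp <- voxelSpacing(full)
        prov <- fieldFromChi(full)
        lp <- gaussianSmooth(fieldData(prov, "ppm"), lpFwhmMm / sp)
        gmag <- gradientMagnitude(lp, sp)
        blended <- gradientReliabilityBlend(chiData(full), chiData(noR2), gmag)
        chi <- methods::new("SusceptibilityVolume", chi = blended,
                            mode = "whole_head", brainMask = full@brainMask,
                            spacing = sp)
    }
    if (mode == "local") chi <- localizeChi(chi) else chi
}

#' Simulate a protocol end to end
#'
#' Forward field (whole-head or local), optional shim and microstructure
#' term, transceiver phase, steady-state signal, optional noise and
#' Fourier-crop downsampling.
#'
#' @param head result of [generateHead()]
#' @param chi a [SusceptibilityVolume-class] from [composeHeadChi()]
#' @param protocol a [Protocol-class]
#' @param B0 Tesla
#' @param shim fit-and-subtract Legendre shim over the brain mask (only
#'   meaningful for whole-head fields)
#' @param microstructure add the white-matter fiber-orientation term
#' @param phi0Seed seed of the transceiver-phase polynomial
#' @param noiseSeed seed of the complex noise (used when the protocol's
#'   `peakSNR` is finite)
#' @return list with `series` (an [EchoSeries-class]), `field` (the
#'   simulated ground-truth [FieldMap-class], ppm) and `spacingNative`
#' @export
simulateProtocol <- function(head, chi, protocol, B0 = 7, shim = FALSE,
                             microstructure = FALSE, phi0Seed = 1L,
                             noiseSeed = 1L) {
    field <- fieldFromChi(chi, B0 = B0)
    if (shim) field <- simulateShim(field, head$masks$brain)
    if (microstructure)
        field <- microstructureShift(field, head$params@FA,
                                     head$params@fiberTheta, head$masks$wm)
    phi0 <- transceiverPhase(dim(chiData(chi)), head$masks$brain, seed = phi0Seed)
    series <- greSignal(head$params, field, phi0, protocol, B0 = B0,
                        provenance = list(mode = chi@mode, shim = shim,
                                          microstructure = microstructure,
                                          phi0_seed = phi0Seed))
    if (is.finite(protocol@peakSNR))
        series <- addNoise(series, protocol@peakSNR, seed = noiseSeed)
    native <- voxelSpacing(series)
    if (!is.na(protocol@targetSpacing) &&
        any(protocol@targetSpacing > native + 1e-12))
        series <- downsampleEchoes(series, protocol@targetSpacing)
    list(series = series, field = field, spacingNative = native)
}

#' Write an echo series as magnitude/phase NIfTI pairs plus a JSON sidecar
#'
#' @param series an [EchoSeries-class]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writeEchoes <- function(series, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sp <- voxelSpacing(series)
    for (j in seq_len(nEchoes(series))) {
        e <- echoData(series, j)
        writeVolume(Mod(e), file.path(dir, sprintf("magn_e%d.nii.gz", j)), sp, "magnitude a.u.")
        writeVolume(Arg(e), file.path(dir, sprintf("phase_e%d.nii.gz", j)), sp, "phase rad")
    }
    p <- protocol(series)
    sidecar <- list(TR_s = p@TR, TE_s = p@TE, flip_angle_deg = p@flipAngle,
                    B0_T = series@B0, spacing_mm = sp,
                    provenance = series@provenance)
    jsonlite::write_json(sidecar, file.path(dir, "protocol.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Read an echo series written by [writeEchoes()]
#'
#' @param dir directory with `magn_e*.nii.gz` / `phase_e*.nii.gz` pairs and
#'   `protocol.json`
#' @return an [EchoSeries-class]
#' @export
readEchoes <- function(dir) {
    sidecar <- jsonlite::read_json(file.path(dir, "protocol.json"),
                                   simplifyVector = TRUE)
    nTE <- length(sidecar$TE_s)
    echoes <- vector("list", nTE)
    sp <- NULL
    for (j in seq_len(nTE)) {
        mg <- readVolume(file.path(dir, sprintf("magn_e%d.nii.gz", j)))
        ph <- readVolume(file.path(dir, sprintf("phase_e%d.nii.gz", j)))
        if (!identical(dim(mg$data), dim(ph$data)))
            stop("grid mismatch between magnitude and phase of echo ", j)
        if (is.null(sp)) sp <- mg$spacing
        else if (max(abs(sp - mg$spacing)) > 1e-6)
            stop("grid mismatch across echoes in ", dir, " (echo ", j, ")")
        echoes[[j]] <- mg$data * exp(1i * ph$data)
    }
    proto <- protocolSpec(sidecar$TR_s, sidecar$TE_s, sidecar$flip_angle_deg)
    methods::new("EchoSeries", echoes = echoes, protocol = proto,
                 B0 = sidecar$B0_T, spacing = sp,
                 provenance = as.list(sidecar$provenance))
}

#' Run the whole pipeline from a configuration
#'
#' Generate -> compose -> forward field -> signal -> (downsample) ->
#' process -> invert -> score, writing all artifacts plus a JSON manifest
#' (seeds, parameters, per-stage log) to `outDir`. Deterministic stages are
#' bit-reproducible for identical configurations.
#'
#' @param config named list (or path to a YAML file) with elements `seed`,
#'   `model` ("model1"/"model2"/path), `protocol` (preset name or list with
#'   `TR`, `TE`, `flip_angle`), `mode` ("whole_head"/"local"), `shim`,
#'   `microstructure`, `peak_snr` (NULL/Inf for noiseless),
#'   `target_spacing` (mm, NA for native), `grid` (edge voxels),
#'   `invert` (list of `method`, `param`), `phi0_seed`, `noise_seed`
#' @param outDir output directory
#' @return the manifest list, invisibly; artifacts under `outDir`
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(list(
        seed = 1L, model = "model1", protocol = "challenge",
        mode = "local", shim = FALSE, microstructure = FALSE,
        peak_snr = Inf, target_spacing = NA_real_, grid = 128L,
        invert = list(method = "tkd", param = 0.2),
        phi0_seed = 1L, noise_seed = 1L), as.list(config))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- list()
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
        log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
        res
    }

    table <- if (cfg$model %in% c("model1", "model2")) tissueTable(cfg$model)
             else tissueTable(path = cfg$model)
    proto <- if (is.character(cfg$protocol)) protocolPreset(cfg$protocol)
             else protocolSpec(cfg$protocol$TR, cfg$protocol$TE, cfg$protocol$flip_angle)
    if (!is.null(cfg$peak_snr) && is.finite(cfg$peak_snr)) proto@peakSNR <- cfg$peak_snr
    if (!is.na(cfg$target_spacing)) proto@targetSpacing <- cfg$target_spacing

    head <- stage("generate", generateHead(headSpec(shape = rep(cfg$grid, 3),
                                                    seed = cfg$seed), table))
    stage("write_phantom", writePhantom(head, file.path(outDir, "phantom"), table))
    chi <- stage("compose", composeHeadChi(head, table, mode = cfg$mode))
    writeVolume(chiData(chi), file.path(outDir, "chi_gt.nii.gz"),
                voxelSpacing(chi), "ground-truth chi ppm")
    sim <- stage("simulate", simulateProtocol(
        head, chi, proto, shim = isTRUE(cfg$shim),
        microstructure = isTRUE(cfg$microstructure),
        phi0Seed = cfg$phi0_seed, noiseSeed = cfg$noise_seed))
    stage("write_echoes", writeEchoes(sim$series, file.path(outDir, "echoes")))

    downsampled <- any(voxelSpacing(sim$series) > sim$spacingNative + 1e-9)
    mask <- head$masks$brain
    chiEval <- chi
    if (downsampled) {
        mask <- fourierDownsample(head$masks$brain * 1, sim$spacingNative,
                                  voxelSpacing(sim$series))$data > 0.5
        chiDs <- fourierDownsample(chiData(chi), sim$spacingNative,
                                   voxelSpacing(sim$series))$data
        chiDs <- stage("gibbs_suppress", gibbsSuppress(chiDs))
        chiEval <- methods::new("SusceptibilityVolume", chi = chiDs,
                                mode = "whole_head",
                                brainMask = array(mask, dim = dim(chiDs)),
                                spacing = voxelSpacing(sim$series))
    }
    proc <- stage("process", processEchoes(sim$series, mask,
                                           removeBackground = cfg$mode == "whole_head"))
    writeVolume(fieldData(proc$field, "Hz"), file.path(outDir, "fieldmap.nii.gz"),
                voxelSpacing(sim$series), "field Hz")

    inv <- stage("invert", {
        fm <- methods::new("FieldMap", values = fieldData(proc$field, "ppm") *
                               (proc$mask * 1), unit = "ppm", B0 = sim$series@B0,
                           spacing = voxelSpacing(sim$series))
        if (cfg$invert$method == "tkd") invertTKD(fm, proc$mask, cfg$invert$param)
        else invertL2(fm, proc$mask, cfg$invert$param)
    })
    writeVolume(chiData(inv), file.path(outDir, "chi_recon.nii.gz"),
                voxelSpacing(inv), "reconstructed chi ppm")

    masksEval <- head$masks
    if (downsampled) {
        ds <- function(m) fourierDownsample(m * 1, sim$spacingNative,
                                            voxelSpacing(sim$series))$data > 0.5
        masksEval <- list(brain = mask, tissue = ds(head$masks$tissue),
                          wm = ds(head$masks$wm), blood = ds(head$masks$blood),
                          dgm = ds(head$masks$dgm),
                          dgm_regions = lapply(head$masks$dgm_regions, ds),
                          calc = ds(head$masks$calc),
                          calc_region = ds(head$masks$calc_region))
    }
    report <- stage("score", scoreReconstruction(
        chiData(inv), chiData(chiEval), masksEval,
        spacing = voxelSpacing(inv)))
    jsonlite::write_json(as.list(metricValues(report)),
                         file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    manifest <- list(package_version = as.character(utils::packageVersion("qsmphantom")),
                     config = cfg, stages = log)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
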