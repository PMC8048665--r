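#' @include tissue-table.R utils-image.R
NULL

#' Per-class reference relaxation means
#'
#' Mean R2* and R1 over the binary (pre-smoothing) voxels of each label, the
#' reference values the susceptibility modulation is anchored to.
#'
#' @param labels integer 3-D label array
#' @param params a [ParameterMaps-class]
#' @return data.frame with columns `label`, `R2star_mean`, `R1_mean`
#' @export
referenceMeans <- function(labels, params) {
    ids <- sort(unique(as.vector(labels)))
    ids <- ids[ids > 0]
    data.frame(
        label = ids,
        R2star_mean = vapply(ids, function(id) mean(params@R2star[labels == id]), numeric(1)),
        R1_mean = vapply(ids, function(id) mean(params@R1[labels == id]), numeric(1)))
}

#' Modulated susceptibility map of one tissue class
#'
#' chi_tissue(r) = chi_mean + a * (R2*(r) - R2*_ref) + b * (R1(r) - R1_ref),
#' evaluated at every voxel; masking/weighting by the class probability
#' happens later in [composeChi()].
#'
#' @param params a [ParameterMaps-class]
#' @param table a [TissueParamTable-class]
#' @param tissueId integer label id
#' @param refMeans data.frame from [referenceMeans()]
#' @param dropR2star if TRUE, force a_tissue = 0 (used where R2* is unreliable
#'   near strong field gradients)
#' @return numeric 3-D array, ppm
#' @export
tissueChiMap <- function(params, table, tissueId, refMeans, dropR2star = FALSE) {
    row <- tissueRow(table, tissueId)
    j <- match(tissueId, refMeans$label)
    if (is.na(j)) stop("no reference means for label id ", tissueId)
    a <- if (dropR2star) 0 else row$a_tissue
    row$chi_mean +
        a * (params@R2star - refMeans$R2star_mean[j]) +
        row$b_tissue * (params@R1 - refMeans$R1_mean[j])
}

#' Partial-volume probability maps
#'
#' Each binary brain-tissue mask is smoothed with a 3-D Gaussian kernel
#' (default FWHM 1.2 voxels); vein and non-brain masks pass through
#' unsmoothed, keeping those interfaces sharp. The smoothed/unsmoothed masks
#' S_tissue are then normalised voxel-wise: P_tissue = S_tissue / sum S.
#'
#' @param labels integer 3-D label array
#' @param brainFlags named logical vector over label ids (names = ids),
#'   TRUE where the class takes part in partial-volume smoothing
#' @param fwhmVoxels Gaussian FWHM in voxels
#' @return named list of probability arrays (names = label ids present)
#' @export
partialVolumeMaps <- function(labels, brainFlags, fwhmVoxels = 1.2) {
    ids <- sort(unique(as.vector(labels)))
    ids <- ids[ids > 0]
    if (!any(brainFlags[as.character(ids)], na.rm = TRUE))
        stop("at least one brain tissue label is required")
    S <- vector("list", length(ids))
    names(S) <- as.character(ids)
    for (id in ids) {
        m <- (labels == id) * 1
        if (!any(m > 0)) {
            warning("label ", id, " has an all-zero mask")
            S[[as.character(id)]] <- m
            next
        }
        sm <- isTRUE(brainFlags[[as.character(id)]])
        S[[as.character(id)]] <- if (sm) gaussianSmooth(m, fwhmVoxels) else m
    }
    tot <- Reduce(`+`, S)
    tot[tot == 0] <- 1 # uncovered voxels keep P = 0 for every class
    lapply(S, function(s) s / tot)
}

#' Build a TissueModel from labels and parameter maps
#'
#' @param labels integer 3-D label array
#' @param params a [ParameterMaps-class]
#' @param table a [TissueParamTable-class] supplying the smoothing flags
#' @param fwhmVoxels partial-volume Gaussian FWHM, voxels
#' @return a [TissueModel-class]
#' @export
tissueModel <- function(labels, params, table, fwhmVoxels = 1.2) {
    tb <- paramTable(table)
    flags <- stats::setNames(tb$is_brain_tissue, as.character(tb$label))
    methods::new("TissueModel",
        labels = labels,
        probMaps = partialVolumeMaps(labels, flags, fwhmVoxels),
        refMeans = referenceMeans(labels, params),
        spacing = params@spacing)
}

#' Blend full and R2*-free susceptibility by field-gradient reliability
#'
#' Near air-tissue boundaries strong field gradients inflate apparent R2*;
#' there the R2* modulation term is dropped. A low-pass-filtered field
#' gradient magnitude drives a continuous mix: below `gLo` the full model is
#' used, above `gHi` the a_tissue = 0 model, with a linear transition in
#' between.
#'
#' @param chiFull chi composed with the full modulation (ppm array)
#' @param chiNoR2star chi composed with a_tissue = 0 for all classes
#' @param fieldGradientMag low-pass-filtered field gradient magnitude, ppm/mm
#' @param gLo,gHi blend thresholds, ppm/mm (defaults 0.08 and 0.3)
#' @return blended ppm array
#' @export
gradientReliabilityBlend <- function(chiFull, chiNoR2star, fieldGradientMag,
                                     gLo = 0.08, gHi = 0.3) {
    if (gLo >= gHi) stop("gLo must be smaller than gHi")
    w <- pmin(1, pmax(0, (fieldGradientMag - gLo) / (gHi - gLo)))
    (1 - w) * chiFull + w * chiNoR2star
}

#' Compose the ground-truth susceptibility volume
#'
#' Probability-weighted sum of the per-class modulated susceptibility maps:
#' chi(r) = sum_tissue P_tissue(r) chi_tissue(r). Voxels covered by no class
#' receive the air susceptibility.
#'
#' @param model a [TissueModel-class]
#' @param params a [ParameterMaps-class]
#' @param table a [TissueParamTable-class]
#' @param brainMask logical array marking the brain (stored on the result)
#' @param dropR2star passed to [tissueChiMap()] for every class
#' @param perTissueChi optional named list of precomputed per-class chi maps
#'   (names = label ids); overrides the Eq-style evaluation when given
#' @return a [SusceptibilityVolume-class], mode `"whole_head"`
#' @export
composeChi <- function(model, params, table, brainMask,
                       dropR2star = FALSE, perTissueChi = NULL) {
    probs <- probabilityMaps(model)
    d <- dim(tissueLabels(model))
    chi <- array(0, dim = d)
    covered <- array(0, dim = d)
    for (nm in names(probs)) {
        id <- as.integer(nm)
        p <- probs[[nm]]
        ct <- if (!is.null(perTissueChi)) {
            if (is.null(perTissueChi[[nm]])) stop("missing per-tissue chi for label ", nm)
            perTissueChi[[nm]]
        } else {
            tissueChiMap(params, table, id, model@refMeans, dropR2star = dropR2star)
        }
        if (!identical(dim(ct), d)) stop("per-tissue chi shape mismatch for label ", nm)
        chi <- chi + p * ct
        covered <- covered + p
    }
    airChi <- tissueRow(table, TISSUE_LABELS[["Air"]])$chi_mean
    chi <- chi + (1 - covered) * airChi
    methods::new("SusceptibilityVolume", chi = chi, mode = "whole_head",
                 brainMask = array(as.logical(brainMask), dim = d),
                 spacing = voxelSpacing(model))
}

#' Brain-only, demeaned susceptibility (perfect background-field correction)
#'
#' Inside the brain mask the mean is subtracted; outside the mask chi is set
#' to zero. The resulting volume generates only local (tissue) fields.
#'
#' @param chiWhole a [SusceptibilityVolume-class]
#' @param mask optional logical array (defaults to the stored brain mask)
#' @return a [SusceptibilityVolume-class], mode `"local"`
#' @export
localizeChi <- function(chiWhole, mask = brainMask(chiWhole)) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty brain mask")
    chi <- chiData(chiWhole)
    chi[!m] <- 0
    chi[m] <- chi[m] - mean(chi[m])
    methods::new("SusceptibilityVolume", chi = chi, mode = "local",
                 brainMask = array(m, dim = dim(chi)),
                 spacing = voxelSpacing(chiWhole))
}
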