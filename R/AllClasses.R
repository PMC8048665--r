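#' @import methods
NULL

## Central S4 containers. All image data are plain 3-D numeric arrays on a
## regular voxel lattice; `spacing` is mm per axis and the third array axis is
## taken as the B0 (z) direction unless stated otherwise.

#' Tissue parameter table
#'
#' One row per tissue label: the mean magnetic susceptibility of the class
#' (ppm), the coefficients modulating susceptibility by the voxel-wise
#' deviation of R2* and R1 from the class means (ppm s), and flags controlling
#' partial-volume smoothing and piece-wise-constant behaviour.
#'
#' @slot table a `data.frame` with columns `label` (integer id), `name`,
#'   `chi_mean` (ppm), `a_tissue` (ppm s, multiplies R2* deviation),
#'   `b_tissue` (ppm s, multiplies R1 deviation), `is_brain_tissue` (logical;
#'   participates in partial-volume smoothing) and `is_piecewise_constant`
#'   (logical; a = b = 0 enforced).
#' @exportClass TissueParamTable
setClass("TissueParamTable", representation(table = "data.frame"))

setValidity("TissueParamTable", function(object) {
    tb <- object@table
    need <- c("label", "name", "chi_mean", "a_tissue", "b_tissue",
              "is_brain_tissue", "is_piecewise_constant")
    if (!all(need %in% names(tb)))
        return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
    if (anyDuplicated(tb$label)) return("duplicated label ids")
    if (!all(is.finite(tb$chi_mean))) return("chi_mean must be finite")
    pw <- tb$is_piecewise_constant
    if (any(pw & (tb$a_tissue != 0 | tb$b_tissue != 0)))
        return("piece-wise-constant tissues must have a_tissue = b_tissue = 0")
    TRUE
})

#' Tissue model: labels, partial-volume probabilities, reference means
#'
#' @slot labels integer 3-D array, one tissue code per voxel.
#' @slot probMaps named list of numeric arrays, one probability map per
#'   tissue present; sums to 1 voxel-wise over the listed tissues.
#' @slot refMeans data.frame with columns `label`, `R2star_mean`, `R1_mean`
#'   (s^-1), the per-class means over the binary label masks.
#' @slot spacing numeric length-3, mm per axis.
#' @exportClass TissueModel
setClass("TissueModel", representation(
    labels = "array", probMaps = "list", refMeans = "data.frame",
    spacing = "numeric"))

setValidity("TissueModel", function(object) {
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
        return("spacing must be 3 positive values")
    if (length(object@probMaps)) {
        d <- dim(object@labels)
        ok <- vapply(object@probMaps, function(p) identical(dim(p), d), logical(1))
        if (!all(ok)) return("probability maps must match label grid")
        tot <- Reduce(`+`, object@probMaps)
        covered <- tot > 0.5
        if (any(abs(tot[covered] - 1) > 1e-6))
            return("probability maps must sum to 1 over covered voxels (1e-6)")
        if (any(vapply(object@probMaps, function(p) any(p < -1e-12), logical(1))))
            return("negative probabilities")
    }
    TRUE
})

#' Co-registered quantitative parameter maps
#'
#' @slot M0 equilibrium signal (arbitrary units), 3-D array.
#' @slot R1 longitudinal relaxation rate (s^-1).
#' @slot R2star apparent transverse relaxation rate (s^-1).
#' @slot FA fractional anisotropy in \[0, 1\] (optional; 0-length array if absent).
#' @slot fiberTheta angle between the local fiber direction and B0, radians
#'   (optional).
#' @slot spacing mm per axis.
#' @exportClass ParameterMaps
setClass("ParameterMaps", representation(
    M0 = "array", R1 = "array", R2star = "array",
    FA = "array", fiberTheta = "array", spacing = "numeric"))

setValidity("ParameterMaps", function(object) {
    d <- dim(object@M0)
    if (!identical(dim(object@R1), d) || !identical(dim(object@R2star), d))
        return("M0, R1, R2star must share a grid")
    for (nm in c("FA", "fiberTheta"))
        if (length(slot(object, nm)) && !identical(dim(slot(object, nm)), d))
            return(paste(nm, "does not match the grid"))
    if (any(object@R1 < 0) || any(object@R2star < 0))
        return("relaxation rates must be non-negative")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
        return("spacing must be 3 positive values")
    TRUE
})

#' Ground-truth susceptibility volume
#'
#' @slot chi susceptibility (ppm), 3-D array.
#' @slot mode `"whole_head"` or `"local"`; in local mode chi is demeaned over
#'   the brain mask and zero outside it (mimicking perfect background-field
#'   correction).
#' @slot brainMask logical 3-D array.
#' @slot spacing mm per axis.
#' @exportClass SusceptibilityVolume
setClass("SusceptibilityVolume", representation(
    chi = "array", mode = "character", brainMask = "array", spacing = "numeric"))

setValidity("SusceptibilityVolume", function(object) {
    if (!object@mode %in% c("whole_head", "local"))
        return("mode must be 'whole_head' or 'local'")
    if (!identical(dim(object@chi), dim(object@brainMask)))
        return("chi and brainMask must share a grid")
    if (object@mode == "local") {
        m <- as.logical(object@brainMask)
        if (!any(m)) return("local mode requires a non-empty brain mask")
        if (abs(mean(object@chi[m])) > 1e-9)
            return("local-mode chi must have zero mean over the brain mask")
        if (any(object@chi[!m] != 0))
            return("local-mode chi must vanish outside the brain mask")
    }
    TRUE
})

#' Frequency-shift (field) map
#'
#' @slot values 3-D array in the unit given by `unit`.
#' @slot unit one of `"ppm"`, `"Hz"`, `"rad_s"`.
#' @slot B0 main field strength, Tesla.
#' @slot spacing mm per axis.
#' @exportClass FieldMap
setClass("FieldMap", representation(
    values = "array", unit = "character", B0 = "numeric", spacing = "numeric"))

setValidity("FieldMap", function(object) {
    if (!object@unit %in% c("ppm", "Hz", "rad_s"))
        return("unit must be one of 'ppm', 'Hz', 'rad_s'")
    if (length(object@B0) != 1 || object@B0 <= 0) return("B0 must be a positive scalar")
    TRUE
})

#' Acquisition protocol for spoiled gradient-echo simulation
#'
#' @slot TR repetition time, seconds.
#' @slot TE echo times, seconds, strictly ascending, all < TR.
#' @slot flipAngle excitation flip angle, degrees, in (0, 90].
#' @slot targetSpacing target voxel size for Fourier-crop downsampling, mm
#'   (NA for native resolution).
#' @slot peakSNR ratio of the peak first-echo magnitude to the per-channel
#'   noise SD (Inf for noiseless).
#' @exportClass Protocol
setClass("Protocol", representation(
    TR = "numeric", TE = "numeric", flipAngle = "numeric",
    targetSpacing = "numeric", peakSNR = "numeric"))

setValidity("Protocol", function(object) {
    if (object@TR <= 0) return("TR must be positive")
    if (!length(object@TE) || is.unsorted(object@TE, strictly = TRUE))
        return("TE must be strictly ascending")
    if (any(object@TE <= 0) || any(object@TE >= object@TR))
        return("TEs must satisfy 0 < TE < TR")
    if (object@flipAngle <= 0 || object@flipAngle > 90)
        return("flip angle must lie in (0, 90] degrees")
    TRUE
})

#' Multi-echo complex image stack
#'
#' @slot echoes list of complex 3-D arrays, one per echo time.
#' @slot protocol a [Protocol-class].
#' @slot B0 Tesla.
#' @slot spacing mm per axis.
#' @slot provenance named list of simulation flags (seeds, field mode,
#'   microstructure on/off, ...).
#' @exportClass EchoSeries
setClass("EchoSeries", representation(
    echoes = "list", protocol = "Protocol", B0 = "numeric",
    spacing = "numeric", provenance = "list"))

setValidity("EchoSeries", function(object) {
    if (length(object@echoes) != length(object@protocol@TE))
        return("one echo volume per TE required")
    d <- dim(object@echoes[[1]])
    if (!all(vapply(object@echoes, function(e) identical(dim(e), d), logical(1))))
        return("all echoes must share a grid")
    TRUE
})

#' QSM-challenge metric report
#'
#' Holds the seven challenge scores (RMSE-type values already multiplied by
#' 100) plus the ROI masks they were computed on.
#'
#' @slot values named numeric: `nRMSE`, `rmse_detrend_tissue`,
#'   `rmse_detrend_blood`, `rmse_detrend_dgm`, `deviation_from_linear_slope`,
#'   `calc_streak`, `calc_moment` (ppm mm^3), `calc_moment_dev`.
#' @slot masks named list of logical arrays used for each score.
#' @exportClass MetricReport
setClass("MetricReport", representation(values = "numeric", masks = "list"))

setValidity("MetricReport", function(object) {
    v <- object@values
    signed <- c("calc_moment", "calc_moment_dev")
    unsigned <- setdiff(names(v), signed)
    if (any(!is.finite(v))) return("all metric values must be finite")
    if (any(v[unsigned] < 0)) return("RMSE-type metrics must be non-negative")
    TRUE
})
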