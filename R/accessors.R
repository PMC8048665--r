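#' @include AllGenerics.R
NULL

#' @describeIn voxelSpacing spacing of a TissueModel
#' @export
setMethod("voxelSpacing", "TissueModel", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of a ParameterMaps
#' @export
setMethod("voxelSpacing", "ParameterMaps", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of a SusceptibilityVolume
#' @export
setMethod("voxelSpacing", "SusceptibilityVolume", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of a FieldMap
#' @export
setMethod("voxelSpacing", "FieldMap", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of an EchoSeries
#' @export
setMethod("voxelSpacing", "EchoSeries", function(x) x@spacing)

#' @describeIn brainMask mask of a SusceptibilityVolume
#' @export
setMethod("brainMask", "SusceptibilityVolume", function(x) {
    m <- x@brainMask
    storage.mode(m) <- "logical"
    m
})

#' @describeIn chiData susceptibility array of a SusceptibilityVolume
#' @export
setMethod("chiData", "SusceptibilityVolume", function(x) x@chi)

#' Convert a field value array between ppm, Hz and rad/s
#'
#' The conversion uses delta_f_Hz = delta_f_ppm * 1e-6 * gamma_bar * B0 with
#' gamma_bar = 42.577e6 Hz/T, and rad/s = 2 pi Hz.
#'
#' @param values numeric array
#' @param from,to source and target unit, `"ppm"`, `"Hz"` or `"rad_s"`
#' @param B0 field strength, Tesla
#' @return converted array
#' @export
convertFieldUnit <- function(values, from, to, B0 = 7) {
    gammaBar <- 42.577e6
    toHz <- switch(from,
        ppm   = values * 1e-6 * gammaBar * B0,
        Hz    = values,
        rad_s = values / (2 * pi),
        stop("unknown unit: ", from))
    switch(to,
        ppm   = toHz / (1e-6 * gammaBar * B0),
        Hz    = toHz,
        rad_s = toHz * 2 * pi,
        stop("unknown unit: ", to))
}

#' @describeIn fieldData field array of a FieldMap, converted to `unit`
#' @export
setMethod("fieldData", "FieldMap", function(x, unit = x@unit)
    convertFieldUnit(x@values, x@unit, unit, x@B0))

#' @describeIn echoData echo `i` of an EchoSeries
#' @export
setMethod("echoData", "EchoSeries", function(x, i = 1L) x@echoes[[i]])

#' @describeIn nEchoes number of echoes of an EchoSeries
#' @export
setMethod("nEchoes", "EchoSeries", function(x) length(x@echoes))

#' @describeIn protocol protocol of an EchoSeries
#' @export
setMethod("protocol", "EchoSeries", function(x) x@protocol)

#' @describeIn metricValues values of a MetricReport
#' @export
setMethod("metricValues", "MetricReport", function(x) x@values)

#' @describeIn paramTable rows of a TissueParamTable
#' @export
setMethod("paramTable", "TissueParamTable", function(x) x@table)

#' @describeIn tissueLabels label array of a TissueModel
#' @export
setMethod("tissueLabels", "TissueModel", function(x) x@labels)

#' @describeIn probabilityMaps probability maps of a TissueModel
#' @export
setMethod("probabilityMaps", "TissueModel", function(x) x@probMaps)

setMethod("show", "TissueParamTable", function(object) {
    tb <- object@table
    cat("TissueParamTable with", nrow(tb), "tissue classes\n")
    cat("  chi_mean range:", paste(range(tb$chi_mean), collapse = " .. "), "ppm\n")
    cat("  brain tissues:", sum(tb$is_brain_tissue),
        "| piece-wise constant:", sum(tb$is_piecewise_constant), "\n")
})

setMethod("show", "TissueModel", function(object) {
    cat("TissueModel", paste(dim(object@labels), collapse = " x "),
        "voxels @", paste(object@spacing, collapse = " x "), "mm\n")
    cat("  labels present:", paste(sort(unique(as.vector(object@labels))), collapse = ", "), "\n")
    cat("  probability maps:", length(object@probMaps), "\n")
})

setMethod("show", "ParameterMaps", function(object) {
    cat("ParameterMaps", paste(dim(object@M0), collapse = " x "),
        "voxels @", paste(object@spacing, collapse = " x "), "mm\n")
    cat(sprintf("  R1 in [%.3g, %.3g] s^-1; R2* in [%.3g, %.3g] s^-1\n",
                min(object@R1), max(object@R1), min(object@R2star), max(object@R2star)))
    cat("  optional maps:",
        paste(c("FA", "fiberTheta")[c(length(object@FA) > 0, length(object@fiberTheta) > 0)],
              collapse = ", "), "\n")
})

setMethod("show", "SusceptibilityVolume", function(object) {
    cat("SusceptibilityVolume (", object@mode, ") ",
        paste(dim(object@chi), collapse = " x "), " voxels\n", sep = "")
    m <- as.logical(object@brainMask)
    cat(sprintf("  chi over brain mask: mean %.4g, range [%.3g, %.3g] ppm\n",
                mean(object@chi[m]), min(object@chi[m]), max(object@chi[m])))
})

setMethod("show", "FieldMap", function(object) {
    cat("FieldMap", paste(dim(object@values), collapse = " x "),
        "voxels, unit:", object@unit, ", B0 =", object@B0, "T\n")
})

setMethod("show", "Protocol", function(object) {
    cat(sprintf("Protocol: TR = %g ms, flip = %g deg, TEs (ms): %s\n",
                1e3 * object@TR, object@flipAngle,
                paste(1e3 * object@TE, collapse = "/")))
    if (is.finite(object@peakSNR)) cat("  peak SNR:", object@peakSNR, "\n")
    if (!is.na(object@targetSpacing))
        cat("  target resolution:", object@targetSpacing, "mm\n")
})

setMethod("show", "EchoSeries", function(object) {
    cat("EchoSeries with", length(object@echoes), "echoes,",
        paste(dim(object@echoes[[1]]), collapse = " x "), "voxels\n")
    show(object@protocol)
})

setMethod("show", "MetricReport", function(object) {
    cat("MetricReport (RMSE-type values x100):\n")
    v <- object@values
    for (nm in names(v)) cat(sprintf("  %-28s %.4g\n", nm, v[[nm]]))
})
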