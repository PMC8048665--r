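#' @include AllClasses.R
NULL

#' Voxel spacing of an image container
#' @param x an image container object
#' @return numeric length-3 vector, mm per axis
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Extract the brain mask
#' @param x an object carrying a brain mask
#' @return logical 3-D array
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' Extract the susceptibility array (ppm)
#' @param x a SusceptibilityVolume
#' @return numeric 3-D array, ppm
#' @export
setGeneric("chiData", function(x) standardGeneric("chiData"))

#' Extract the field array in a chosen unit
#' @param x a FieldMap
#' @param unit `"ppm"`, `"Hz"` or `"rad_s"`
#' @return numeric 3-D array in `unit`
#' @export
setGeneric("fieldData", function(x, unit = x@unit) standardGeneric("fieldData"))

#' Extract one complex echo volume
#' @param x an EchoSeries
#' @param i echo index
#' @return complex 3-D array
#' @export
setGeneric("echoData", function(x, i = 1L) standardGeneric("echoData"))

#' Number of echoes
#' @param x an EchoSeries
#' @return integer
#' @export
setGeneric("nEchoes", function(x) standardGeneric("nEchoes"))

#' Acquisition protocol of an echo series
#' @param x an EchoSeries
#' @return a Protocol object
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Metric values of a report
#' @param x a MetricReport
#' @return named numeric vector
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' Tissue parameter rows
#' @param x a TissueParamTable
#' @return data.frame
#' @export
setGeneric("paramTable", function(x) standardGeneric("paramTable"))

#' Tissue label array
#' @param x a TissueModel
#' @return integer 3-D array
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' Partial-volume probability maps
#' @param x a TissueModel
#' @return named list of numeric arrays
#' @export
setGeneric("probabilityMaps", function(x) standardGeneric("probabilityMaps"))
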