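#' @include AllClasses.R
NULL

## Label taxonomy used throughout the package. Codes 1..16; background air is
## coded 14 as well (outside the head everything is air).
TISSUE_LABELS <- c(
    Caudate = 1L, GlobusPallidus = 2L, Putamen = 3L, RedNucleus = 4L,
    DentateNucleus = 5L, SubstantiaNigra = 6L, Thalamus = 7L,
    WhiteMatter = 8L, GrayMatter = 9L, CSF = 10L, Blood = 11L, Fat = 12L,
    Bone = 13L, Air = 14L, Muscle = 15L, Calcification = 16L)

## The six deep gray-matter nuclei entering the linear-slope metric.
DGM_LABELS <- c("Caudate", "GlobusPallidus", "Putamen", "RedNucleus",
                "DentateNucleus", "SubstantiaNigra")

#' Load a tissue susceptibility parameter table
#'
#' Two calibrated models ship with the package: `"model1"` (literature mean
#' susceptibilities with R1/R2*-fitted modulation coefficients) and
#' `"model2"` (perturbed means, modulation coefficients changed by +/-10%).
#' A user CSV with the same columns is accepted via `path`.
#'
#' @param model `"model1"` or `"model2"` (ignored when `path` given)
#' @param path optional path to a CSV with columns `label`, `name`,
#'   `chi_mean` (ppm), `a_tissue`, `b_tissue` (ppm s), `is_brain_tissue`,
#'   `is_piecewise_constant`
#' @return a [TissueParamTable-class]
#' @examples
#' tb <- tissueTable("model1")
#' paramTable(tb)[paramTable(tb)$name == "GlobusPallidus", ]
#' @export
tissueTable <- function(model = c("model1", "model2"), path = NULL) {
    if (is.null(path)) {
        model <- match.arg(model)
        path <- system.file("extdata", paste0("tissue_", model, ".csv"),
                            package = "qsmphantom", mustWork = TRUE)
    }
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    tb$is_brain_tissue <- as.logical(tb$is_brain_tissue)
    tb$is_piecewise_constant <- as.logical(tb$is_piecewise_constant)
    tb$a_tissue[tb$is_piecewise_constant] <- 0
    tb$b_tissue[tb$is_piecewise_constant] <- 0
    methods::new("TissueParamTable", table = tb)
}

## Fetch the row for one label id, failing loudly with the id.
tissueRow <- function(table, labelId) {
    tb <- paramTable(table)
    i <- match(labelId, tb$label)
    if (is.na(i)) stop("no tissue parameter row for label id ", labelId)
    tb[i, , drop = FALSE]
}
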