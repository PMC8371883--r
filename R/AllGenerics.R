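#' Power-law exponent
#'
#' Extract the scaling exponent `b` of a power law `y = a * x^b`, either
#' from a fitted [PowerLawFit-class] or from an [AllometricModel-class].
#'
#' @param object a `PowerLawFit` or `AllometricModel`.
#' @return a single numeric value.
#' @examples
#' exponent(allometricModel())
#' @export
setGeneric("exponent", function(object) standardGeneric("exponent"))

#' Power-law normalization constant
#'
#' Extract the prefactor `a` of a power law `y = a * x^b`: the predicted
#' value of `y` at `x = 1` (here, ribosomal gene copies per cell at a cell
#' volume of 1 um^3).
#'
#' @param object a `PowerLawFit` or `AllometricModel`.
#' @return a single numeric value.
#' @examples
#' normConst(allometricModel())
#' @export
setGeneric("normConst", function(object) standardGeneric("normConst"))

#' Coefficient of determination of the ln-ln regression
#'
#' @param object a `PowerLawFit`.
#' @return R-squared of the regression of `ln y` on `ln x`.
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' Coerce a fit to an allometric model
#'
#' Collapse a [PowerLawFit-class] to the two numbers needed for abundance
#' correction (constant and exponent), dropping uncertainty information.
#'
#' @param object a `PowerLawFit` (or an `AllometricModel`, returned as is).
#' @return an [AllometricModel-class].
#' @export
setGeneric("asModel", function(object) standardGeneric("asModel"))

#' Number of size bins in a binning scheme
#'
#' @param object a [SizeBinScheme-class].
#' @return integer count of bins.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' Diameter break points of a binning scheme
#'
#' @param object a [SizeBinScheme-class].
#' @return numeric vector of bin edges in um, length `nBins(object) + 1`.
#' @export
setGeneric("binBreaks", function(object) standardGeneric("binBreaks"))

#' Per-taxon relative ribosomal gene frequencies
#'
#' @param object a [CommunityProfile-class] or [CorrectedProfile-class].
#' @return named numeric vector of frequencies (normalized to sum to 1 for
#'   corrected profiles; as supplied for raw profiles).
#' @export
setGeneric("relFreq", function(object) standardGeneric("relFreq"))

#' Sample-level total ribosomal gene copies
#'
#' The qPCR-determined total number of SSU rRNA gene copies per unit of
#' sample (mass, volume or surface), used to convert relative frequencies
#' into absolute abundances. `NA` when no total was supplied.
#'
#' @param object a [CommunityProfile-class] or [CorrectedProfile-class].
#' @return a single numeric value (possibly `NA`).
#' @export
setGeneric("qpcrTotal", function(object) standardGeneric("qpcrTotal"))

#' Per-taxon cell-number fractions
#'
#' @param object a [CorrectedProfile-class].
#' @return named numeric vector summing to 1 (or `NA`s if not yet filled).
#' @export
setGeneric("cellFrac", function(object) standardGeneric("cellFrac"))

#' Per-taxon biovolume fractions
#'
#' @param object a [CorrectedProfile-class].
#' @return named numeric vector summing to 1 (or `NA`s if not yet filled).
#' @export
setGeneric("biovolFrac", function(object) standardGeneric("biovolFrac"))
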