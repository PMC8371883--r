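#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## AllometricModel
## ---------------------------------------------------------------------------

#' Allometric model of ribosomal gene content per cell
#'
#' A two-parameter power law \eqn{R_c = a \, V_c^{b}} relating ribosomal
#' (SSU rRNA) gene copies per cell to cell volume in \eqn{\mu m^3}. The
#' defaults are the empirical constants of the microbial scaling law,
#' `a = 9.58` and `b = 0.66` (the exponent is statistically
#' indistinguishable from the idealized 2/3, which can be selected with
#' `idealized = TRUE`).
#'
#' @slot normConst numeric(1), prefactor `a` (copies per cell at 1 um^3); > 0.
#' @slot exponent numeric(1), scaling exponent `b`; > 0. (An identity model
#'   with `b = 1` is permitted, e.g. for sensitivity checks, even though
#'   empirical fits give `b < 1`.)
#'
#' @param normConst,exponent model constants (see slots).
#' @param idealized logical; if `TRUE` use the idealized exponent 2/3
#'   instead of the printed 0.66 (ignored when `exponent` is given
#'   explicitly).
#'
#' @return `allometricModel()` returns an `AllometricModel` object.
#' @seealso [rcFromVolume()], [rcFromDiameter()], [asModel()]
#' @examples
#' allometricModel()                  # a = 9.58, b = 0.66
#' allometricModel(idealized = TRUE)  # a = 9.58, b = 2/3
#' @aliases AllometricModel
#' @export allometricModel
#' @exportClass AllometricModel
setClass("AllometricModel",
  representation(normConst = "numeric", exponent = "numeric"),
  prototype(normConst = 9.58, exponent = 0.66))

setValidity("AllometricModel", function(object) {
  msg <- character()
  if (length(object@normConst) != 1L || !is.finite(object@normConst) ||
      object@normConst <= 0)
    msg <- c(msg, "'normConst' must be a single positive number")
  if (length(object@exponent) != 1L || !is.finite(object@exponent) ||
      object@exponent <= 0)
    msg <- c(msg, "'exponent' must be a single positive number")
  if (length(msg)) msg else TRUE
})

allometricModel <- function(normConst = 9.58,
                            exponent = if (idealized) 2 / 3 else 0.66,
                            idealized = FALSE) {
  new("AllometricModel", normConst = as.numeric(normConst),
      exponent = as.numeric(exponent))
}

## ---------------------------------------------------------------------------
## PowerLawFit
## ---------------------------------------------------------------------------

#' Result of a power-law fit on ln-transformed data
#'
#' Holds the estimates, uncertainties and sufficient statistics of an
#' ordinary least-squares regression of `ln y` on `ln x`, interpreted as
#' the power law \eqn{y = a x^b}. The residual sum of squares and the
#' centered sum of squares of `ln x` are retained so that two fits can be
#' compared with a pooled-variance slope t test ([compareSlopes()]).
#'
#' @slot n integer(1), number of data pairs (>= 3).
#' @slot exponent numeric(1), slope `b` of the ln-ln regression.
#' @slot exponentSE numeric(1), standard error of `b`.
#' @slot lnIntercept numeric(1), intercept `ln a`.
#' @slot lnInterceptSE numeric(1), standard error of `ln a`.
#' @slot normConst numeric(1), back-transformed prefactor `a = exp(ln a)`.
#' @slot normConstSE numeric(1), delta-method SE of `a`
#'   (`a * lnInterceptSE`).
#' @slot rSquared numeric(1), coefficient of determination in ln space.
#' @slot residualSS numeric(1), residual sum of squares in ln space.
#' @slot xCenteredSS numeric(1), centered sum of squares of `ln x`.
#' @slot df integer(1), residual degrees of freedom, `n - 2`.
#'
#' @seealso [fitPowerLaw()], [compareSlopes()], [asModel()]
#' @aliases PowerLawFit
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(n = "integer", exponent = "numeric", exponentSE = "numeric",
                 lnIntercept = "numeric", lnInterceptSE = "numeric",
                 normConst = "numeric", normConstSE = "numeric",
                 rSquared = "numeric", residualSS = "numeric",
                 xCenteredSS = "numeric", df = "integer"))

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "'n' must be at least 3")
  if (object@df != object@n - 2L) msg <- c(msg, "'df' must equal n - 2")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  if (object@residualSS > 1e-12 * max(1, abs(object@lnIntercept)) &&
      object@exponentSE <= 0)
    msg <- c(msg, "'exponentSE' must be positive when residuals are nonzero")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SlopeComparison
## ---------------------------------------------------------------------------

#' Two-sample t test for equality of regression slopes
#'
#' Result of comparing the exponents of two independent ln-ln power-law
#' fits with the classical pooled-residual-variance slope t test on
#' `n1 + n2 - 4` degrees of freedom.
#'
#' @slot statistic numeric(1), the t statistic for `b1 - b2`.
#' @slot df integer(1), degrees of freedom (`n1 + n2 - 4`).
#' @slot pValue numeric(1), two-sided p value in `[0, 1]`.
#'
#' @seealso [compareSlopes()]
#' @aliases SlopeComparison
#' @exportClass SlopeComparison
setClass("SlopeComparison",
  representation(statistic = "numeric", df = "integer", pValue = "numeric"))

setValidity("SlopeComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    "'pValue' must lie in [0, 1]"
  else if (object@df < 1L)
    "'df' must be positive"
  else TRUE
})

## ---------------------------------------------------------------------------
## SizeBinScheme
## ---------------------------------------------------------------------------

#' Variable-width cell-diameter binning scheme
#'
#' An ordered set of contiguous spherical-equivalent diameter intervals
#' used to assign taxa with only roughly known sizes to discrete size
#' classes. The default scheme has 13 bins spanning 0.2--16.4 um:
#' 0.2--0.3, 0.3--0.4, 0.4--0.6, 0.6--0.9, 0.9--1.2, 1.2--1.5, 1.5--2.1,
#' 2.1--2.9, 2.9--4.1, 4.1--5.8, 5.8--8.2, 8.2--11.6 and 11.6--16.4. The
#' widths grow geometrically so that the representative ribosomal gene
#' content per cell varies by less than 8% within every bin, less than
#' the uncertainty of the scaling law's normalization constant.
#'
#' Bins are half-open `[lo, hi)`; the top bin additionally includes its
#' upper edge.
#'
#' @slot breaks strictly increasing numeric vector of diameter edges, um.
#'
#' @param breaks bin edges in um; the default is the 13-bin scheme above.
#' @return `sizeBinScheme()` returns a `SizeBinScheme` object.
#' @seealso [binAssign()], [binRc()], [binTable()]
#' @examples
#' sizeBinScheme()
#' @aliases SizeBinScheme
#' @export sizeBinScheme
#' @exportClass SizeBinScheme
setClass("SizeBinScheme", representation(breaks = "numeric"))

setValidity("SizeBinScheme", function(object) {
  b <- object@breaks
  if (length(b) < 2L) return("need at least two break points")
  if (any(!is.finite(b)) || any(b <= 0)) return("breaks must be positive")
  if (any(diff(b) <= 0)) return("breaks must be strictly increasing")
  TRUE
})

.defaultBinBreaks <- c(0.2, 0.3, 0.4, 0.6, 0.9, 1.2, 1.5, 2.1, 2.9, 4.1,
                       5.8, 8.2, 11.6, 16.4)

sizeBinScheme <- function(breaks = .defaultBinBreaks) {
  new("SizeBinScheme", breaks = as.numeric(breaks))
}

## ---------------------------------------------------------------------------
## CommunityProfile
## ---------------------------------------------------------------------------

#' Per-taxon ribosomal gene frequency profile of one community sample
#'
#' The raw, uncorrected description of a community as it comes out of an
#' rRNA gene survey: one row per taxon with its relative ribosomal gene
#' frequency `F_r` and either a cell volume (um^3) or a size-bin
#' assignment, plus optionally a sample-level qPCR total of ribosomal
#' gene copies (`R_s`) that anchors absolute abundance estimates.
#'
#' Frequencies may be supplied as read counts or percentages; they are
#' interpreted proportionally and renormalized (with a warning when they
#' do not already sum to 1) by the correction functions.
#'
#' @slot taxon character vector of taxon identifiers (unique).
#' @slot freq numeric vector of ribosomal gene frequencies, >= 0, at
#'   least one positive.
#' @slot volume numeric vector of cell volumes in um^3 (`NA` where a bin
#'   is used instead).
#' @slot bin integer vector of size-bin indices into `scheme` (`NA` where
#'   a volume is given). Each row must have exactly one of volume / bin.
#' @slot scheme the [SizeBinScheme-class] that bin indices refer to.
#' @slot qpcrTotal numeric(1), total ribosomal gene copies per sample
#'   unit (e.g. copies per cm^2 from qPCR), or `NA`.
#'
#' @param taxon,freq,volume,qpcrTotal see slots.
#' @param diameter spherical-equivalent cell diameters in um; converted
#'   to bin assignments via [binAssign()] for rows without a volume.
#' @param bin explicit bin indices (alternative to `diameter`).
#' @param scheme binning scheme used to resolve `diameter`/`bin`.
#'
#' @return `communityProfile()` returns a `CommunityProfile` object.
#' @seealso [cellFractions()], [correctProfile()], [readCommunityProfile()]
#' @examples
#' communityProfile(c("small", "large"), freq = c(0.5, 0.5),
#'                  volume = c(1, 1000))
#' @aliases CommunityProfile
#' @export communityProfile
#' @exportClass CommunityProfile
setClass("CommunityProfile",
  representation(taxon = "character", freq = "numeric", volume = "numeric",
                 bin = "integer", scheme = "SizeBinScheme",
                 qpcrTotal = "numeric"))

setValidity("CommunityProfile", function(object) {
  n <- length(object@taxon)
  msg <- character()
  if (n == 0L) msg <- c(msg, "profile has no taxa")
  if (anyDuplicated(object@taxon))
    msg <- c(msg, "taxon identifiers must be unique")
  if (length(object@freq) != n || length(object@volume) != n ||
      length(object@bin) != n)
    msg <- c(msg, "'freq', 'volume' and 'bin' must match 'taxon' in length")
  if (any(!is.na(object@freq) & object@freq < 0))
    msg <- c(msg, "frequencies must be non-negative")
  if (!any(object@freq > 0)) msg <- c(msg, "all frequencies are zero")
  hasV <- !is.na(object@volume)
  hasB <- !is.na(object@bin)
  if (any(hasV & hasB) || any(!hasV & !hasB))
    msg <- c(msg, "each taxon needs exactly one of volume or bin")
  if (any(object@volume[hasV] <= 0))
    msg <- c(msg, "volumes must be positive")
  nb <- length(object@scheme@breaks) - 1L
  if (any(object@bin[hasB] < 1L | object@bin[hasB] > nb))
    msg <- c(msg, sprintf("bin indices must lie in 1..%d", nb))
  if (length(object@qpcrTotal) != 1L)
    msg <- c(msg, "'qpcrTotal' must be a single number (or NA)")
  else if (!is.na(object@qpcrTotal) && object@qpcrTotal <= 0)
    msg <- c(msg, "'qpcrTotal' must be positive when given")
  if (length(msg)) msg else TRUE
})

communityProfile <- function(taxon, freq, volume = NULL, diameter = NULL,
                             bin = NULL, qpcrTotal = NA_real_,
                             scheme = sizeBinScheme()) {
  n <- length(taxon)
  vol <- if (is.null(volume)) rep(NA_real_, n) else as.numeric(volume)
  b <- if (is.null(bin)) rep(NA_integer_, n) else as.integer(bin)
  if (!is.null(diameter)) {
    d <- as.numeric(diameter)
    idx <- is.na(vol) & !is.na(d)
    b[idx] <- binAssign(d[idx], scheme, what = "diameter")
  }
  new("CommunityProfile", taxon = as.character(taxon),
      freq = as.numeric(freq), volume = vol, bin = b, scheme = scheme,
      qpcrTotal = as.numeric(qpcrTotal))
}

## ---------------------------------------------------------------------------
## CorrectedProfile
## ---------------------------------------------------------------------------

#' Copy-number- and size-corrected community profile
#'
#' The result of translating ribosomal gene frequencies `F_r` into
#' community structure: per taxon, the ribosomal gene copies per cell
#' `R_c(i)` predicted by the allometric model, the cell-number fraction
#' `F_c(i)` and the biovolume fraction `F_v(i)`, and -- when a qPCR total
#' `R_s` is available -- the absolute copies `R(i)`, cells `C(i)` and
#' biovolume `V(i)` per sample unit together with their totals.
#'
#' Slots not yet filled by the corresponding step ([cellFractions()],
#' [biovolumeFractions()], [absolutize()]) hold `NA`.
#'
#' @slot taxon character vector of taxon identifiers.
#' @slot freq normalized ribosomal gene frequencies `F_r` (sum to 1).
#' @slot rc predicted ribosomal gene copies per cell, `R_c(i)`.
#' @slot volume resolved cell volumes in um^3 (bin-representative values
#'   for binned taxa).
#' @slot cellFrac cell-number fractions `F_c(i)` (sum to 1).
#' @slot biovolFrac biovolume fractions `F_v(i)` (sum to 1).
#' @slot copies absolute ribosomal gene copies `R(i)` per sample unit.
#' @slot cells absolute cell numbers `C(i) = R(i) / R_c(i)`.
#' @slot biovol absolute biovolumes `V(i) = C(i) V_c(i)`, um^3.
#' @slot totalCells numeric(1), `sum(C(i))`.
#' @slot totalBiovol numeric(1), `sum(V(i))`, um^3 per sample unit.
#' @slot qpcrTotal numeric(1), the `R_s` used (or `NA`).
#' @slot model the [AllometricModel-class] used for `R_c`.
#'
#' @seealso [correctProfile()], [cellFractions()], [absolutize()]
#' @aliases CorrectedProfile
#' @exportClass CorrectedProfile
setClass("CorrectedProfile",
  representation(taxon = "character", freq = "numeric", rc = "numeric",
                 volume = "numeric", cellFrac = "numeric",
                 biovolFrac = "numeric", copies = "numeric",
                 cells = "numeric", biovol = "numeric",
                 totalCells = "numeric", totalBiovol = "numeric",
                 qpcrTotal = "numeric", model = "AllometricModel"))

setValidity("CorrectedProfile", function(object) {
  n <- length(object@taxon)
  lens <- c(length(object@freq), length(object@rc), length(object@volume),
            length(object@cellFrac), length(object@biovolFrac),
            length(object@copies), length(object@cells),
            length(object@biovol))
  msg <- character()
  if (any(lens != n)) msg <- c(msg, "per-taxon slots must share one length")
  if (abs(sum(object@freq) - 1) > 1e-6)
    msg <- c(msg, "'freq' must be normalized to sum to 1")
  if (any(object@rc <= 0)) msg <- c(msg, "'rc' must be positive")
  if (!all(is.na(object@cellFrac)) &&
      abs(sum(object@cellFrac) - 1) > 1e-9)
    msg <- c(msg, "'cellFrac' must sum to 1")
  if (!all(is.na(object@biovolFrac)) &&
      abs(sum(object@biovolFrac) - 1) > 1e-9)
    msg <- c(msg, "'biovolFrac' must sum to 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn allometricModel exponent of the model.
#' @export
setMethod("exponent", "AllometricModel", function(object) object@exponent)

#' @describeIn allometricModel normalization constant of the model.
#' @export
setMethod("normConst", "AllometricModel", function(object) object@normConst)

#' @rdname PowerLawFit-class
#' @param object a `PowerLawFit`.
#' @export
setMethod("exponent", "PowerLawFit", function(object) object@exponent)

#' @rdname PowerLawFit-class
#' @export
setMethod("normConst", "PowerLawFit", function(object) object@normConst)

#' @rdname PowerLawFit-class
#' @export
setMethod("rSquared", "PowerLawFit", function(object) object@rSquared)

#' @rdname asModel
#' @export
setMethod("asModel", "PowerLawFit", function(object)
  allometricModel(normConst = object@normConst, exponent = object@exponent))

#' @rdname asModel
#' @export
setMethod("asModel", "AllometricModel", function(object) object)

#' @rdname sizeBinScheme
#' @param object a `SizeBinScheme`.
#' @export
setMethod("nBins", "SizeBinScheme",
          function(object) length(object@breaks) - 1L)

#' @rdname sizeBinScheme
#' @export
setMethod("binBreaks", "SizeBinScheme", function(object) object@breaks)

#' @rdname communityProfile
#' @param object a `CommunityProfile`.
#' @export
setMethod("relFreq", "CommunityProfile", function(object)
  stats::setNames(object@freq, object@taxon))

#' @rdname communityProfile
#' @export
setMethod("qpcrTotal", "CommunityProfile", function(object) object@qpcrTotal)

#' @rdname CorrectedProfile-class
#' @param object a `CorrectedProfile`.
#' @export
setMethod("relFreq", "CorrectedProfile", function(object)
  stats::setNames(object@freq, object@taxon))

#' @rdname CorrectedProfile-class
#' @export
setMethod("qpcrTotal", "CorrectedProfile", function(object) object@qpcrTotal)

#' @rdname CorrectedProfile-class
#' @export
setMethod("cellFrac", "CorrectedProfile", function(object)
  stats::setNames(object@cellFrac, object@taxon))

#' @rdname CorrectedProfile-class
#' @export
setMethod("biovolFrac", "CorrectedProfile", function(object)
  stats::setNames(object@biovolFrac, object@taxon))

#' @rdname communityProfile
#' @param x a `CommunityProfile`.
#' @export
setMethod("length", "CommunityProfile", function(x) length(x@taxon))

#' @rdname CorrectedProfile-class
#' @param x a `CorrectedProfile`.
#' @export
setMethod("length", "CorrectedProfile", function(x) length(x@taxon))

setMethod("show", "AllometricModel", function(object) {
  cat(sprintf("AllometricModel: R_c = %.4g * V_c^%.4g  (V_c in um^3)\n",
              object@normConst, object@exponent))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit (ln-ln OLS, n = %d)\n", object@n))
  cat(sprintf("  y = %.4g * x^%.4g\n", object@normConst, object@exponent))
  cat(sprintf("  exponent b  : %.4f +/- %.4f (SE)\n",
              object@exponent, object@exponentSE))
  cat(sprintf("  constant a  : %.4f +/- %.4f (delta-method SE)\n",
              object@normConst, object@normConstSE))
  cat(sprintf("  R-squared   : %.4f   df: %d\n",
              object@rSquared, object@df))
})

setMethod("show", "SlopeComparison", function(object) {
  cat(sprintf("Slope comparison t test: t = %.4f, df = %d, p = %.4g\n",
              object@statistic, object@df, object@pValue))
})

setMethod("show", "SizeBinScheme", function(object) {
  n <- length(object@breaks) - 1L
  cat(sprintf("SizeBinScheme: %d diameter bins over %.3g-%.3g um\n",
              n, object@breaks[1L], object@breaks[length(object@breaks)]))
  lab <- paste0(format(object@breaks[-length(object@breaks)]), "-",
                format(object@breaks[-1L]))
  cat("  ", paste(lab, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CommunityProfile", function(object) {
  cat(sprintf("CommunityProfile: %d taxa", length(object@taxon)))
  if (!is.na(object@qpcrTotal))
    cat(sprintf(", qPCR total R_s = %.4g copies/sample unit",
                object@qpcrTotal))
  cat("\n")
  print(utils::head(as.data.frame(object), 8L))
  if (length(object@taxon) > 8L)
    cat(sprintf("  ... and %d more taxa\n", length(object@taxon) - 8L))
})

setMethod("show", "CorrectedProfile", function(object) {
  cat(sprintf("CorrectedProfile: %d taxa (model a = %.4g, b = %.4g)\n",
              length(object@taxon), object@model@normConst,
              object@model@exponent))
  print(utils::head(as.data.frame(object), 8L))
  if (length(object@taxon) > 8L)
    cat(sprintf("  ... and %d more taxa\n", length(object@taxon) - 8L))
  if (!is.na(object@totalCells))
    cat(sprintf("  totals: %.6g cells, %.6g um^3 biovolume per sample unit\n",
                object@totalCells, object@totalBiovol))
})

#' @rdname communityProfile
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
setMethod("as.data.frame", "CommunityProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(taxon_id = x@taxon, freq = x@freq, volume_um3 = x@volume,
               bin = x@bin, stringsAsFactors = FALSE)
  })

#' @rdname CorrectedProfile-class
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
setMethod("as.data.frame", "CorrectedProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    df <- data.frame(taxon_id = x@taxon, f_r = x@freq, rc = x@rc,
                     volume_um3 = x@volume, f_c = x@cellFrac,
                     f_v = x@biovolFrac, stringsAsFactors = FALSE)
    if (!all(is.na(x@copies))) {
      df$r_abs <- x@copies
      df$cells_abs <- x@cells
      df$biovol_abs_um3 <- x@biovol
    }
    df
  })
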