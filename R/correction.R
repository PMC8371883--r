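#' @include AllClasses.R bins.R
NULL

#' Predicted ribosomal gene copies per cell from cell volume
#'
#' Evaluates the allometric law \eqn{R_c = a V_c^b}. With the default
#' model this is \eqn{R_c = 9.58 \, V_c^{0.66}} (volume in um^3): a
#' 1-um^3 cell is predicted to carry about 9.6 SSU rRNA gene copies, a
#' 1000-um^3 cell about 915. The prediction subsumes both operon copy
#' number per genome and ploidy, so neither needs to be known.
#'
#' @param volume cell volumes \eqn{V_c} in um^3 (vectorized, all > 0).
#' @param model an [AllometricModel-class].
#' @return copies per cell.
#' @examples
#' rcFromVolume(1)      # 9.58
#' rcFromVolume(1000)   # about 915
#' @seealso [rcFromDiameter()], [cellFractions()]
#' @export
rcFromVolume <- function(volume, model = allometricModel()) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("cell volume must be positive and finite")
  model@normConst * volume^model@exponent
}

#' Predicted ribosomal gene copies per cell from cell diameter
#'
#' The volume law rewritten in terms of the spherical-equivalent
#' diameter: \eqn{R_c = a (\pi/6)^b (D_c^0)^{3b}}. With the default
#' constants the implied prefactor is \eqn{9.58 (\pi/6)^{0.66} \approx
#' 6.25} and the implied exponent \eqn{3 \times 0.66 = 1.98} -- i.e.
#' ribosomal gene content scales essentially with the cell's surface
#' area, not its volume. Defined so that
#' `rcFromDiameter(d) == rcFromVolume(sphereVolume(d))` exactly.
#'
#' @param diameter spherical-equivalent diameters in um (all > 0).
#' @param model an [AllometricModel-class].
#' @return copies per cell.
#' @examples
#' rcFromDiameter(1)  # about 6.25
#' diameterLaw()      # the implied (prefactor, exponent)
#' @export
rcFromDiameter <- function(diameter, model = allometricModel()) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("cell diameter must be positive and finite")
  rcFromVolume(sphereVolume(diameter), model)
}

#' Diameter-space form of an allometric model
#'
#' @param model an [AllometricModel-class].
#' @return named numeric vector `c(prefactor, exponent)` of the law
#'   \eqn{R_c = prefactor \cdot (D_c^0)^{exponent}}.
#' @rdname rcFromDiameter
#' @export
diameterLaw <- function(model = allometricModel()) {
  c(prefactor = model@normConst * (pi / 6)^model@exponent,
    exponent = 3 * model@exponent)
}

## Resolve per-taxon R_c and volume for a profile; renormalize F_r.
.resolveProfile <- function(profile, model) {
  vol <- profile@volume
  binned <- !is.na(profile@bin)
  if (any(binned))
    vol[binned] <- binRepVolume(profile@bin[binned], profile@scheme)
  rc <- rcFromVolume(vol, model)
  if (any(binned))
    rc[binned] <- binRc(profile@bin[binned], profile@scheme, model)
  fr <- profile@freq
  s <- sum(fr)
  if (s <= 0) stop("degenerate profile: all frequencies are zero")
  if (abs(s - 1) > 1e-6) {
    warning(sprintf(
      "frequencies sum to %.6g; renormalizing to relative frequencies", s))
  }
  list(freq = fr / s, rc = rc, volume = vol)
}

#' Cell-number fractions from ribosomal gene frequencies
#'
#' The core bias correction: a taxon's share of ribosomal gene copies
#' overstates its share of cells in proportion to its copies per cell,
#' so the cell-number fraction of taxon `i` is
#' \deqn{F_c(i) = \frac{F_r(i) / R_c(i)}{\sum_j F_r(j) / R_c(j)}}
#' with \eqn{R_c(i)} predicted from the taxon's cell volume (or size
#' bin) by the allometric model. Because \eqn{R_c} grows with roughly
#' the square of linear cell size, uncorrected read counts overestimate
#' large-celled taxa in cell terms and underestimate them in biomass
#' terms.
#'
#' @param profile a [CommunityProfile-class].
#' @param model an [AllometricModel-class].
#' @return a [CorrectedProfile-class] with `F_c` filled (biovolume
#'   fractions and absolute abundances still `NA`; see
#'   [biovolumeFractions()], [absolutize()], or [correctProfile()] for
#'   the full pipeline).
#' @examples
#' p <- communityProfile(c("small", "large"), freq = c(0.5, 0.5),
#'                       volume = c(1, 1000))
#' cellFrac(cellFractions(p))  # about (0.990, 0.010)
#' @export
cellFractions <- function(profile, model = allometricModel()) {
  stopifnot(is(profile, "CommunityProfile"))
  r <- .resolveProfile(profile, model)
  w <- r$freq / r$rc
  fc <- w / sum(w)
  n <- length(profile@taxon)
  new("CorrectedProfile", taxon = profile@taxon, freq = r$freq, rc = r$rc,
      volume = r$volume, cellFrac = fc, biovolFrac = rep(NA_real_, n),
      copies = rep(NA_real_, n), cells = rep(NA_real_, n),
      biovol = rep(NA_real_, n), totalCells = NA_real_,
      totalBiovol = NA_real_, qpcrTotal = profile@qpcrTotal, model = model)
}

#' Biovolume fractions from cell-number fractions
#'
#' Weights each taxon's cell-number fraction by its cell volume:
#' \deqn{F_v(i) = \frac{F_c(i) V_c(i)}{\sum_j F_c(j) V_c(j)}}
#' Biovolume is the natural biomass proxy under the assumption of
#' near-constant cell density (~1.008 g/ml).
#'
#' @param corrected a [CorrectedProfile-class] with `F_c` filled (from
#'   [cellFractions()]).
#' @return the profile with `F_v` filled.
#' @examples
#' p <- communityProfile(c("small", "large"), freq = c(0.5, 0.5),
#'                       volume = c(1, 1000))
#' biovolFrac(biovolumeFractions(cellFractions(p)))  # about (0.087, 0.913)
#' @export
biovolumeFractions <- function(corrected) {
  stopifnot(is(corrected, "CorrectedProfile"))
  if (all(is.na(corrected@cellFrac)))
    stop("cell fractions must be computed first (see cellFractions())")
  miss <- is.na(corrected@volume)
  if (any(miss))
    stop("missing cell volume for taxon: ",
         paste(corrected@taxon[miss], collapse = ", "))
  w <- corrected@cellFrac * corrected@volume
  corrected@biovolFrac <- w / sum(w)
  validObject(corrected)
  corrected
}

#' Absolute cell numbers and biovolumes from a qPCR total
#'
#' When the total number of ribosomal gene copies per sample unit,
#' \eqn{R_s} (e.g. from qPCR, in copies per gram, ml or cm^2), is known,
#' relative frequencies convert to absolute abundances:
#' \eqn{R(i) = F_r(i) R_s}, \eqn{C(i) = R(i)/R_c(i)} cells and
#' \eqn{V(i) = C(i) V_c(i)} um^3 per sample unit. The totals
#' \eqn{\sum C(i)} and \eqn{\sum V(i)} estimate community-wide cell
#' number and biovolume; by construction \eqn{\sum R(i) = R_s},
#' \eqn{C(i)/\sum C = F_c(i)} and \eqn{V(i)/\sum V = F_v(i)}.
#'
#' @param profile a [CommunityProfile-class] carrying a qPCR total, or a
#'   [CorrectedProfile-class] from [cellFractions()] /
#'   [biovolumeFractions()].
#' @param model an [AllometricModel-class] (ignored when `profile` is
#'   already corrected).
#' @param qpcrTotal override / supply \eqn{R_s} (> 0) if the profile
#'   carries none.
#' @return a [CorrectedProfile-class] with `R(i)`, `C(i)`, `V(i)` and
#'   totals filled (and `F_c`, `F_v` filled as a side effect).
#' @examples
#' p <- communityProfile("only", freq = 1, volume = 1,
#'                       qpcrTotal = 9.58e6)
#' absolutize(p)  # one million 1-um^3 cells per sample unit
#' @export
absolutize <- function(profile, model = allometricModel(),
                       qpcrTotal = NULL) {
  if (is(profile, "CommunityProfile"))
    profile <- biovolumeFractions(cellFractions(profile, model))
  stopifnot(is(profile, "CorrectedProfile"))
  if (all(is.na(profile@biovolFrac)))
    profile <- biovolumeFractions(profile)
  rs <- if (!is.null(qpcrTotal)) as.numeric(qpcrTotal) else profile@qpcrTotal
  if (is.na(rs) || length(rs) != 1L || rs <= 0)
    stop("a positive qPCR total R_s is required to absolutize a profile")
  profile@qpcrTotal <- rs
  profile@copies <- profile@freq * rs
  profile@cells <- profile@copies / profile@rc
  profile@biovol <- profile@cells * profile@volume
  profile@totalCells <- sum(profile@cells)
  profile@totalBiovol <- sum(profile@biovol)
  validObject(profile)
  profile
}

#' Full copy-number correction of a community profile
#'
#' Runs [cellFractions()], [biovolumeFractions()] and -- if a qPCR total
#' is available -- [absolutize()] in sequence.
#'
#' @param profile a [CommunityProfile-class].
#' @param model an [AllometricModel-class].
#' @param qpcrTotal optional \eqn{R_s} overriding the profile's own.
#' @return a [CorrectedProfile-class].
#' @examples
#' p <- communityProfile(c("a", "b"), freq = c(0.5, 0.5),
#'                       volume = c(1, 1000), qpcrTotal = 1000)
#' as.data.frame(correctProfile(p))
#' @export
correctProfile <- function(profile, model = allometricModel(),
                           qpcrTotal = NULL) {
  out <- biovolumeFractions(cellFractions(profile, model))
  rs <- if (!is.null(qpcrTotal)) as.numeric(qpcrTotal) else profile@qpcrTotal
  if (!is.na(rs)) out <- absolutize(out, qpcrTotal = rs)
  out
}
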