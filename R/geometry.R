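#' @include AllClasses.R
NULL

#' Cell volume from a simple shape descriptor
#'
#' Computes cell volume in \eqn{\mu m^3} from the geometric idealizations
#' conventionally used to size microbial cells from micrographs:
#'
#' * `sphere`: \eqn{(\pi/6) d^3} -- needs diameter `d` only;
#' * `cylinder`: \eqn{(\pi/4) d^2 l} -- needs diameter `d` and length `l`;
#' * `capsule`: a cylinder of length `l` closed by two hemispherical caps,
#'   \eqn{(\pi/4) d^2 l + (\pi/6) d^3} (`l` is the cylindrical section
#'   only; `l = 0` degenerates to a sphere) -- the usual model for rods;
#' * `composite`: the sum of the volumes of a list of parts (no overlap
#'   correction).
#'
#' @param kind one of `"sphere"`, `"cylinder"`, `"capsule"`,
#'   `"composite"`, or a list with elements `kind`, `d`, `l`, `parts`
#'   (a parsed shape descriptor), in which case the remaining arguments
#'   are ignored.
#' @param d cell diameter, um (> 0).
#' @param l cell length, um (cylinder: > 0; capsule: >= 0).
#' @param parts for `composite`, a non-empty list of shape descriptors,
#'   each itself a list with `kind`/`d`/`l`/`parts`.
#' @return volume in um^3 (single numeric).
#' @examples
#' shapeVolume("sphere", d = 1)            # pi/6
#' shapeVolume("cylinder", d = 1, l = 1)   # pi/4
#' shapeVolume("capsule", d = 1, l = 0)    # pi/6 (degenerate sphere)
#' shapeVolume("composite", parts = list(
#'   list(kind = "sphere", d = 2),
#'   list(kind = "cylinder", d = 0.5, l = 10)))
#' @seealso [equivalentDiameter()], [sphereVolume()]
#' @export
shapeVolume <- function(kind, d = NULL, l = NULL, parts = NULL) {
  if (is.list(kind)) {
    spec <- kind
    kind <- spec$kind
    d <- spec$d
    l <- spec$l
    parts <- spec$parts
  }
  if (!is.character(kind) || length(kind) != 1L)
    stop("'kind' must be a single shape name")
  kind <- match.arg(kind, c("sphere", "cylinder", "capsule", "composite"))
  needDim <- function(x, name, minOpen = TRUE) {
    if (is.null(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("shape '%s' needs a finite dimension '%s'", kind, name))
    if (if (minOpen) x <= 0 else x < 0)
      stop(sprintf("dimension '%s' of shape '%s' must be %s", name, kind,
                   if (minOpen) "positive" else "non-negative"))
    as.numeric(x)
  }
  switch(kind,
    sphere = {
      d <- needDim(d, "d")
      pi / 6 * d^3
    },
    cylinder = {
      d <- needDim(d, "d")
      l <- needDim(l, "l")
      pi / 4 * d^2 * l
    },
    capsule = {
      d <- needDim(d, "d")
      l <- needDim(l, "l", minOpen = FALSE)
      pi / 4 * d^2 * l + pi / 6 * d^3
    },
    composite = {
      if (is.null(parts) || !is.list(parts) || length(parts) == 0L)
        stop("composite shape needs a non-empty 'parts' list")
      sum(vapply(parts, shapeVolume, numeric(1)))
    })
}

#' Volume of a spherical cell
#'
#' @param d diameter, um (vectorized, all > 0).
#' @return \eqn{(\pi/6) d^3} in um^3.
#' @examples
#' sphereVolume(1)  # pi/6
#' @export
sphereVolume <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameter must be positive and finite")
  pi / 6 * d^3
}

#' Spherical-equivalent cell diameter
#'
#' The diameter \eqn{D_c^0} of the sphere having the cell's volume,
#' \eqn{D_c^0 = 2 (3 V_c / 4\pi)^{1/3}}. It is the exact inverse of
#' [sphereVolume()]: `equivalentDiameter(sphereVolume(d)) == d`.
#'
#' @param volume cell volume \eqn{V_c} in um^3 (vectorized, all > 0).
#' @return diameter in um.
#' @examples
#' equivalentDiameter(pi / 6)    # 1
#' equivalentDiameter(4 * pi / 3)  # 2 (unit-radius sphere)
#' @export
equivalentDiameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive and finite")
  2 * (3 * volume / (4 * pi))^(1 / 3)
}
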