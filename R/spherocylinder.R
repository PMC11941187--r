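#' Rigid spherocylindrical particle
#'
#' A spherocylinder (capsule) is a cylinder of length `l` capped by two
#' hemispheres of radius `r`; geometrically the Minkowski sum of an axial line
#' segment and a ball of radius `r`. Total mass is fixed at 1 by convention,
#' with uniform density. `l = 0` is a sphere.
#'
#' @param l length of the cylindrical part (`l >= 0`).
#' @param r hemisphere / cylinder radius (`r > 0`).
#' @return An object of class `"spherocylinder"`.
#' @examples
#' spherocylinder(l = 7, r = 0.05)
#' @export
spherocylinder <- function(l, r) {
  stopifnot(is.numeric(l), is.numeric(r), length(l) == 1, length(r) == 1)
  if (!(r > 0)) stop("particle radius r must be positive")
  if (l < 0) stop("cylindrical-part length l must be non-negative")
  structure(list(l = l, r = r), class = "spherocylinder")
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf("<spherocylinder> l = %g, r = %g (aspect l/2r = %g)\n",
              x$l, x$r, x$l / (2 * x$r)))
  invisible(x)
}

#' Particle configuration: position and orientation
#'
#' Bundles the center-of-mass position and the unit orientation vector of the
#' particle's long axis (in the channel frame, `z` along the axis, origin at
#' the wide end). The orientation is renormalized on construction and treated
#' as a director (`u` and `-u` describe the same body).
#'
#' @param c numeric length-3 center-of-mass position.
#' @param u numeric length-3 orientation; must have norm within `1e-6` of a
#'   unit vector before renormalization.
#' @return An object of class `"particle_state"`.
#' @export
particle_state <- function(c = c(0, 0, 0), u = c(0, 0, 1)) {
  stopifnot(is.numeric(c), length(c) == 3, is.numeric(u), length(u) == 3)
  n <- sqrt(sum(u^2))
  if (!is.finite(n) || n < 1e-12) stop("orientation vector must be non-zero")
  structure(list(c = as.numeric(c), u = as.numeric(u) / n),
            class = "particle_state")
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("<particle_state> c = (%.4g, %.4g, %.4g), u = (%.4g, %.4g, %.4g)\n",
              x$c[1], x$c[2], x$c[3], x$u[1], x$u[2], x$u[3]))
  invisible(x)
}
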