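#' Conical channel geometry
#'
#' Constructs an axisymmetric pore whose radius varies linearly from `R0` at
#' the wide end (`z = 0`, reflecting) to `RL` at the narrow end (`z = L`,
#' absorbing). The default geometry has a wide-end diameter equal to the unit
#' length and a narrow end half as wide; `R0 = RL` gives the cylindrical
#' control case.
#'
#' @param L channel length along the axis (simulation length units).
#' @param R0 radius at `z = 0` (wide end).
#' @param RL radius at `z = L` (narrow end); must satisfy `RL <= R0`.
#' @return An object of class `"channel"` with fields `L`, `R0`, `RL` and the
#'   derived wall `slope = (RL - R0)/L`.
#' @examples
#' ch <- channel()
#' radius_at(ch, c(0, 7.5, 15))
#' @export
channel <- function(L = 15, R0 = 0.5, RL = 0.25) {
  stopifnot(is.numeric(L), is.numeric(R0), is.numeric(RL),
            length(L) == 1, length(R0) == 1, length(RL) == 1)
  if (!(L > 0)) stop("channel length L must be positive")
  if (!(R0 > 0) || !(RL > 0)) stop("channel radii must be positive")
  if (RL > R0) stop("narrow-end radius RL must not exceed wide-end radius R0")
  structure(list(L = L, R0 = R0, RL = RL, slope = (RL - R0) / L),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  kind <- if (x$slope == 0) "cylindrical" else "conical"
  cat(sprintf("<channel> %s: L = %g, R0 = %g, RL = %g, slope = %g\n",
              kind, x$L, x$R0, x$RL, x$slope))
  invisible(x)
}

#' Wall radius at an axial position
#'
#' Evaluates the linear wall profile `R(z) = R0 + slope * z`. The wall is
#' extrapolated beyond `[0, L]` so that a particle body overhanging either end
#' plane still sees a consistent boundary.
#'
#' @param ch a [channel()].
#' @param z axial position(s); may lie outside `[0, L]`.
#' @return Wall radius at each `z`.
#' @export
radius_at <- function(ch, z) {
  stopifnot(inherits(ch, "channel"), is.numeric(z))
  out <- ch$R0 + ch$slope * z
  if (any(out <= 0))
    stop("extrapolated wall radius is non-positive at z = ",
         paste(signif(z[out <= 0], 6), collapse = ", "),
         " (invalid geometry)")
  out
}

#' Perpendicular clearance from a point to the channel wall
#'
#' Signed 3D distance from a point to the (extrapolated) cone surface,
#' positive when the point is radially inside the wall. For a point at
#' cylindrical radius `rho` and height `z` this equals
#' `(R(z) - rho) / sqrt(1 + slope^2)`; the `sqrt(1 + slope^2)` factor converts
#' the horizontal gap into the true perpendicular distance.
#'
#' @param ch a [channel()].
#' @param p a length-3 numeric position, or an `n x 3` matrix of positions.
#' @return Signed clearance(s).
#' @export
wall_clearance <- function(ch, p) {
  stopifnot(inherits(ch, "channel"))
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    p <- matrix(p, nrow = 1)
  }
  stopifnot(ncol(p) == 3)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  (ch$R0 + ch$slope * p[, 3] - rho) / sqrt(1 + ch$slope^2)
}
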