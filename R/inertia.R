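#' Mass partition of a unit-mass spherocylinder
#'
#' For uniform density the cylinder mass `m1` and single-hemisphere mass `m2`
#' satisfy `m1/m2 = 3l/(2r)` (the volume ratio) together with total mass
#' `m1 + 2 m2 = 1`, giving the closed form `m1 = 3l/(3l + 4r)`,
#' `m2 = 2r/(3l + 4r)`.
#'
#' @param l cylindrical-part length (`l >= 0`).
#' @param r hemisphere radius (`r > 0`).
#' @return Named numeric vector `c(m1 = ..., m2 = ...)`.
#' @examples
#' component_masses(l = 0.2, r = 0.1)  # l = 2r: c(0.6, 0.2)
#' @export
component_masses <- function(l, r) {
  if (!is.numeric(r) || any(r <= 0)) stop("particle radius r must be positive")
  if (!is.numeric(l) || any(l < 0)) stop("length l must be non-negative")
  m1 <- 3 * l / (3 * l + 4 * r)
  m2 <- 2 * r / (3 * l + 4 * r)
  c(m1 = m1, m2 = m2)
}

#' Moment-of-inertia components of a unit-mass spherocylinder
#'
#' Body-frame principal moments about the geometric center, `z` along the long
#' axis:
#' \deqn{M_{xx} = M_{yy} = m_1(l^2/12 + r^2/4) +
#'   2 m_2(2r^2/5 + l^2/4 + 3lr/8),}
#' \deqn{M_{zz} = (m_1/2 + 4 m_2/5)\, r^2,}
#' with the uniform-density masses from [component_masses()]. At `l = 0` both
#' reduce to the solid-sphere value `0.4 r^2`; as `r -> 0` at fixed `l`,
#' `Mxx -> l^2/12` (thin rod) and `Mzz -> 0`.
#'
#' @inheritParams component_masses
#' @return Named numeric vector `c(Mxx = ..., Mzz = ...)`.
#' @export
inertia_tensor <- function(l, r) {
  m <- component_masses(l, r)
  Mxx <- m[["m1"]] * (l^2 / 12 + r^2 / 4) +
    2 * m[["m2"]] * (2 * r^2 / 5 + l^2 / 4 + 3 * l * r / 8)
  Mzz <- (m[["m1"]] / 2 + 4 * m[["m2"]] / 5) * r^2
  c(Mxx = Mxx, Mzz = Mzz)
}

#' Full inertia model for a particle
#'
#' Convenience bundle of [component_masses()] and [inertia_tensor()].
#'
#' @param l,r particle dimensions, or pass a [spherocylinder()] as `l`.
#' @return An object of class `"inertia_model"` with fields `m1`, `m2`, `Mxx`,
#'   `Mzz`, `l`, `r`.
#' @export
inertia_model <- function(l, r) {
  if (inherits(l, "spherocylinder")) {
    r <- l$r
    l <- l$l
  }
  m <- component_masses(l, r)
  mi <- inertia_tensor(l, r)
  structure(list(m1 = m[["m1"]], m2 = m[["m2"]],
                 Mxx = mi[["Mxx"]], Mzz = mi[["Mzz"]], l = l, r = r),
            class = "inertia_model")
}

#' @export
print.inertia_model <- function(x, ...) {
  cat(sprintf("<inertia_model> l = %g, r = %g\n", x$l, x$r))
  cat(sprintf("  masses: m1 = %.6g, m2 = %.6g (m1 + 2 m2 = %.6g)\n",
              x$m1, x$m2, x$m1 + 2 * x$m2))
  cat(sprintf("  moments: Mxx = Myy = %.6g, Mzz = %.6g\n", x$Mxx, x$Mzz))
  invisible(x)
}

#' Moment of inertia about an arbitrary axis through the center
#'
#' For the axisymmetric tensor (`Mxx = Myy`) only the angle between the
#' rotation axis and the particle's long axis matters:
#' `M(axis) = Mxx (1 - cos^2 psi) + Mzz cos^2 psi`, where `cos_psi` is the dot
#' product of the unit rotation axis and the unit molecular axis.
#'
#' @param model an [inertia_model()].
#' @param cos_psi cosine of the angle between rotation axis and long axis;
#'   `|cos_psi| <= 1`.
#' @return Moment of inertia about the axis.
#' @export
moment_about_axis <- function(model, cos_psi) {
  stopifnot(inherits(model, "inertia_model"), is.numeric(cos_psi))
  if (any(abs(cos_psi) > 1 + 1e-9))
    stop("|cos_psi| must not exceed 1 (axis and orientation must be unit vectors)")
  cp <- pmin(pmax(cos_psi, -1), 1)
  model$Mxx * (1 - cp^2) + model$Mzz * cp^2
}

#' Rotational noise scale from energy equipartition
#'
#' Links the rotation-angle standard deviation to the translational one by
#' equipartition of kinetic energy between translational and rotational
#' degrees of freedom: `sigma_phi = sigma_x / sqrt(M(axis))`, with the moment
#' of inertia evaluated about the freshly drawn rotation axis. Units follow
#' the simulation convention (unit particle mass, unit step time).
#'
#' @param sigma_x translational noise scale (`> 0`).
#' @param moment moment of inertia about the rotation axis (`> 0`).
#' @return Rotation-angle standard deviation in radians.
#' @export
sigma_phi <- function(sigma_x, moment) {
  stopifnot(is.numeric(sigma_x), is.numeric(moment))
  if (any(sigma_x < 0)) stop("sigma_x must be non-negative")
  if (any(moment <= 0)) stop("moment of inertia must be positive")
  sigma_x / sqrt(moment)
}
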