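#' Sample translation proposals
#'
#' Draws displacement vectors whose three components are independent
#' Gaussians with mean 0 and standard deviation `sigma_x` (the Euler-Maruyama
#' update with unit step time). Uses R's RNG; seed with [set.seed()] for
#' reproducibility. The compiled ensemble driver uses its own substreamed
#' generator, of which this is the R-level counterpart for testing and
#' exploration.
#'
#' @param n number of proposals.
#' @param sigma_x translational noise scale (`>= 0`).
#' @return An `n x 3` numeric matrix.
#' @export
sample_translation <- function(n, sigma_x) {
  stopifnot(is.numeric(sigma_x), sigma_x >= 0)
  matrix(rnorm(3 * n, sd = sigma_x), ncol = 3)
}

#' Sample rotation axes uniformly on the sphere
#'
#' Draws unit vectors uniformly distributed over directions, as normalized
#' triples of independent standard Gaussians (resampled on underflow).
#'
#' @param n number of axes.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sample_rotation_axis <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm < 1e-12
  while (any(bad)) {
    m[bad, ] <- rnorm(3 * sum(bad))
    nrm[bad] <- sqrt(rowSums(m[bad, , drop = FALSE]^2))
    bad <- nrm < 1e-12
  }
  m / nrm
}

#' Rotate a vector about an axis (Rodrigues formula)
#'
#' Rotates unit vector `u` about unit `axis` by `angle` radians
#' (right-hand convention), renormalizing the result to unit length.
#'
#' @param u length-3 unit vector.
#' @param axis length-3 unit rotation axis.
#' @param angle rotation angle in radians.
#' @return The rotated unit vector.
#' @export
rotate_axis_angle <- function(u, axis, angle) {
  stopifnot(length(u) == 3, length(axis) == 3, length(angle) == 1)
  if (abs(sum(u^2) - 1) > 1e-6 || abs(sum(axis^2) - 1) > 1e-6)
    stop("u and axis must be unit vectors")
  co <- cos(angle)
  si <- sin(angle)
  cr <- c(axis[2] * u[3] - axis[3] * u[2],
          axis[3] * u[1] - axis[1] * u[3],
          axis[1] * u[2] - axis[2] * u[1])
  v <- u * co + cr * si + axis * sum(axis * u) * (1 - co)
  v / sqrt(sum(v^2))
}

#' Draw a feasible initial configuration
#'
#' Insertion at the wide end: center of mass on-axis at `z = 0`, orientation
#' drawn uniformly on the sphere and redrawn until the whole body fits inside
#' the (extrapolated) wall. Uses R's RNG; the compiled driver performs the
#' same procedure on its own substream.
#'
#' @param ch a [channel()].
#' @param particle a [spherocylinder()].
#' @param max_draws rejection-sampling cap before declaring the particle
#'   infeasible.
#' @return A [particle_state()].
#' @export
initial_state <- function(ch, particle, max_draws = 1e6) {
  stopifnot(inherits(ch, "channel"), inherits(particle, "spherocylinder"))
  if (particle$r >= ch$RL)
    stop("particle radius must be smaller than the narrow-end radius RL")
  for (i in seq_len(max_draws)) {
    u <- drop(sample_rotation_axis(1))
    st <- particle_state(c = c(0, 0, 0), u = u)
    if (spherocylinder_inside(ch, particle, st)) return(st)
  }
  stop("no feasible initial orientation found (infeasible particle)")
}
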