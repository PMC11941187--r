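state_matrix <- function(state) {
  if (inherits(state, "particle_state")) {
    matrix(c(state$c, state$u), nrow = 1)
  } else {
    stopifnot(is.matrix(state), ncol(state) == 6)
    state
  }
}

#' Is the whole particle body inside the channel wall?
#'
#' Decides wall containment for a spherocylinder: the full body (axis segment
#' from `c - (l/2) u` to `c + (l/2) u` dilated by radius `r`) avoids the wall
#' surface iff the perpendicular [wall_clearance()] is at least `r` at *both*
#' axis-segment endpoints. This endpoint reduction is exact because the
#' clearance along the segment is a concave function of the segment parameter
#' (linear wall radius minus convex radial distance), so its minimum is
#' attained at an endpoint.
#'
#' Containment here concerns only the lateral wall; the channel end planes are
#' handled separately (center-of-mass rules) by the dynamics.
#'
#' @param ch a [channel()].
#' @param particle a [spherocylinder()].
#' @param state a [particle_state()], or an `n x 6` matrix with columns
#'   `(cx, cy, cz, ux, uy, uz)` for vectorized queries.
#' @return Logical: `TRUE` iff the body does not intersect the wall.
#' @seealso [collision_oracle()] for a brute-force cross-check.
#' @export
spherocylinder_inside <- function(ch, particle, state) {
  stopifnot(inherits(ch, "channel"), inherits(particle, "spherocylinder"))
  m <- state_matrix(state)
  hl <- particle$l / 2
  e1 <- m[, 1:3, drop = FALSE] + hl * m[, 4:6, drop = FALSE]
  e2 <- m[, 1:3, drop = FALSE] - hl * m[, 4:6, drop = FALSE]
  wall_clearance(ch, e1) >= particle$r & wall_clearance(ch, e2) >= particle$r
}

#' Brute-force surface-sampling containment oracle
#'
#' Test-support reference for [spherocylinder_inside()]: samples
#' `n_samples` area-weighted random points on the capsule surface
#' (cylindrical shell plus the two hemispherical caps) and reports `TRUE` iff
#' every sampled point lies radially inside the wall. Near-boundary
#' disagreements within the sampling resolution are expected; the analytic
#' predicate is authoritative there.
#'
#' @inheritParams spherocylinder_inside
#' @param n_samples number of surface points (`>= 1000`).
#' @param seed integer seed for the sampling stream.
#' @return Logical vector, one entry per state.
#' @export
collision_oracle <- function(ch, particle, state, n_samples = 10000,
                             seed = 1) {
  stopifnot(inherits(ch, "channel"), inherits(particle, "spherocylinder"))
  if (n_samples < 1000) stop("n_samples must be at least 1000")
  m <- state_matrix(state)
  cpp_collision_oracle(ch$L, ch$R0, ch$RL, particle$l, particle$r, m,
                       as.integer(n_samples), as.numeric(seed))
}
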