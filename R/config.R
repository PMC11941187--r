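#' Log-spaced state-sampling schedule
#'
#' Strictly increasing integer step indices, approximately log-uniform between
#' 1 and `max_steps`, with at most `per_decade` points per decade. Trajectories
#' can run for millions of steps; a logarithmic grid keeps mean-squared
#' displacement curves dense on a log-log scale at bounded memory.
#'
#' @param max_steps largest step index.
#' @param per_decade cap on grid points per decade.
#' @return Increasing integer vector within `[1, max_steps]`.
#' @export
log_sample_times <- function(max_steps, per_decade = 200) {
  stopifnot(max_steps >= 1, per_decade >= 1)
  n_dec <- log10(max_steps)
  n <- max(2, ceiling(n_dec * per_decade) + 1)
  tt <- unique(round(10^seq(0, n_dec, length.out = n)))
  tt[tt >= 1 & tt <= max_steps]
}

#' Simulation run configuration
#'
#' Bundles channel, particle and run parameters and validates them. Defaults
#' follow the reference setup: channel `L = 15`, `R0 = 0.5`, `RL = 0.25`,
#' translational noise `sigma_x = 0.05`, ensemble size `n_rep = 1000`.
#'
#' @param channel a [channel()].
#' @param particle a [spherocylinder()]; its radius must be smaller than the
#'   narrow-end radius `RL` so that exit is feasible.
#' @param sigma_x translational noise scale per step (`> 0`).
#' @param n_rep number of independent trajectories (`>= 1`).
#' @param seed integer seed; trajectory `i` uses RNG substream
#'   `stream_offset + i - 1`, so results are bit-reproducible and independent
#'   of execution order.
#' @param max_steps censoring cap on trajectory length. The default `5e7`
#'   comfortably exceeds the first-passage times of the largest reference
#'   particles (escape rates around `5e-7` per step).
#' @param sample_times strictly increasing integer step indices at which the
#'   full state is recorded; defaults to [log_sample_times()] of `max_steps`.
#' @param occ_per_traj number of linear-stride occupation samples `(z, |u_z|)`
#'   accumulated per trajectory for time-weighted position/orientation
#'   histograms.
#' @param stream_offset first RNG substream index (used by parameter scans to
#'   keep cells on disjoint streams).
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(particle = spherocylinder(l = 0.25, r = 0.05),
#'                   n_rep = 10, seed = 1, max_steps = 1e5)
#' @export
sim_config <- function(channel = conediff::channel(),
                       particle,
                       sigma_x = 0.05,
                       n_rep = 1000,
                       seed = 1,
                       max_steps = 5e7,
                       sample_times = NULL,
                       occ_per_traj = 2000,
                       stream_offset = 0) {
  stopifnot(inherits(channel, "channel"), inherits(particle, "spherocylinder"))
  if (!(sigma_x > 0)) stop("sigma_x must be positive")
  if (n_rep < 1) stop("n_rep must be at least 1")
  if (max_steps < 1) stop("max_steps must be at least 1")
  if (particle$r >= channel$RL)
    stop(sprintf("infeasible particle: r = %g must be smaller than RL = %g",
                 particle$r, channel$RL))
  # the wall is extrapolated past z = L while the body straddles the
  # absorbing plane; it must remain an open channel out to the farthest
  # reachable endpoint
  radius_at(channel, channel$L + particle$l / 2)
  if (is.null(sample_times)) sample_times <- log_sample_times(max_steps)
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 1 || any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  if (any(sample_times < 1 | sample_times > max_steps))
    stop("sample_times must lie within [1, max_steps]")
  if (any(sample_times != round(sample_times)))
    stop("sample_times must be integer step indices")
  structure(list(channel = channel, particle = particle, sigma_x = sigma_x,
                 n_rep = as.integer(n_rep), seed = as.numeric(seed),
                 max_steps = as.numeric(max_steps),
                 sample_times = sample_times,
                 occ_per_traj = as.integer(occ_per_traj),
                 stream_offset = as.numeric(stream_offset)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  print(x$channel)
  print(x$particle)
  cat(sprintf("  sigma_x = %g, n_rep = %d, seed = %g, max_steps = %g\n",
              x$sigma_x, x$n_rep, x$seed, x$max_steps))
  cat(sprintf("  %d sample times in [%g, %g]; %d occupation samples/trajectory; streams from %g\n",
              length(x$sample_times), min(x$sample_times),
              max(x$sample_times), x$occ_per_traj, x$stream_offset))
  invisible(x)
}
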