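#' Run an ensemble of trajectories
#'
#' Simulates `n_rep` independent trajectories of the rejection-based
#' Brownian dynamics: each discrete step is one Gaussian translation attempt
#' (rejected on wall collision or on entrance ejection, proposed
#' center-of-mass `z < 0`) followed by one rotation attempt about a uniformly
#' random axis with equipartition angle scale (rejected on wall collision).
#' Time advances by exactly 1 per step whatever was accepted. A trajectory
#' terminates when the center of mass first reaches `z >= L` (that step index
#' is the first passage time) or is right-censored at `max_steps`.
#'
#' @param config a [sim_config()].
#' @return An object of class `"ensemble_result"`: a list with
#'   \describe{
#'     \item{config}{the configuration echo.}
#'     \item{fpt}{numeric first passage times, `NA` where censored.}
#'     \item{censored}{logical censoring flags.}
#'     \item{accepted_translations, accepted_rotations}{per-trajectory
#'       acceptance counts.}
#'     \item{steps_run}{steps actually executed per trajectory.}
#'     \item{stream_id}{RNG substream identifier per trajectory.}
#'     \item{times}{recorded step indices (including `t = 0`).}
#'     \item{x, y, z, ux, uy, uz}{state matrices, `length(times)` rows by
#'       `n_rep` columns, `NA` from absorption/censoring onward.}
#'     \item{occ}{pooled pre-absorption occupation samples, columns
#'       `z` and `|u_z|`, taken every `occ_stride` steps.}
#'   }
#' @examples
#' cfg <- sim_config(particle = spherocylinder(l = 0, r = 0.05),
#'                   n_rep = 5, seed = 1, max_steps = 2e4)
#' res <- run_ensemble(cfg)
#' summary(res$fpt)
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ch <- config$channel
  p <- config$particle
  occ_stride <- max(1, ceiling(config$max_steps / config$occ_per_traj))
  raw <- cpp_run_ensemble(ch$L, ch$R0, ch$RL, p$l, p$r, config$sigma_x,
                          config$n_rep, config$seed, config$max_steps,
                          config$sample_times, occ_stride,
                          config$occ_per_traj, config$stream_offset)
  occ <- raw$occ[seq_len(raw$n_occ), , drop = FALSE]
  colnames(occ) <- c("z", "abs_uz")
  structure(list(config = config,
                 fpt = raw$fpt,
                 censored = is.na(raw$fpt),
                 accepted_translations = raw$accepted_translations,
                 accepted_rotations = raw$accepted_rotations,
                 steps_run = raw$steps_run,
                 stream_id = raw$stream_id,
                 times = c(0, config$sample_times),
                 x = raw$x, y = raw$y, z = raw$z,
                 ux = raw$ux, uy = raw$uy, uz = raw$uz,
                 occ = occ,
                 occ_stride = occ_stride),
            class = "ensemble_result")
}

#' Run a single trajectory
#'
#' Convenience wrapper: an ensemble of size 1 on substream `stream_offset`.
#'
#' @inheritParams run_ensemble
#' @return An `"ensemble_result"` with `n_rep = 1`.
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_rep <- 1L
  run_ensemble(config)
}

#' @export
print.ensemble_result <- function(x, ...) {
  n <- length(x$fpt)
  nc <- sum(x$censored)
  cat(sprintf("<ensemble_result> %d trajectories (%d censored at %g steps)\n",
              n, nc, x$config$max_steps))
  if (any(!x$censored)) {
    f <- x$fpt[!x$censored]
    cat(sprintf("  first passage times: min %g, median %g, max %g\n",
                min(f), median(f), max(f)))
  }
  rate_t <- sum(x$accepted_translations) / sum(x$steps_run)
  rate_r <- sum(x$accepted_rotations) / sum(x$steps_run)
  cat(sprintf("  acceptance rates: translation %.3f, rotation %.3f\n",
              rate_t, rate_r))
  cat(sprintf("  %d recorded times, %d occupation samples\n",
              length(x$times), nrow(x$occ)))
  invisible(x)
}
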