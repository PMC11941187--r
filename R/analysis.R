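#' Survivor-averaged mean squared displacement
#'
#' At each recorded time `t`, averages `|c(t) - c(0)|^2` (all three
#' coordinates) over the trajectories still inside the channel at `t`:
#' a tracer that has already reached the narrow end no longer contributes.
#' Censored trajectories contribute until `max_steps`. Times with no
#' survivors are omitted.
#'
#' @param result an [run_ensemble()] result.
#' @return An object of class `"msd_curve"`: data frame with columns `t`,
#'   `msd`, `n_alive`.
#' @export
ensemble_msd <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  if (length(result$times) < 2)
    stop("need at least two recorded times to form an MSD curve")
  dx <- sweep(result$x, 2, result$x[1, ])
  dy <- sweep(result$y, 2, result$y[1, ])
  dz <- sweep(result$z, 2, result$z[1, ])
  sq <- dx^2 + dy^2 + dz^2
  n_alive <- rowSums(!is.na(sq))
  msd <- rowMeans(sq, na.rm = TRUE)
  keep <- n_alive > 0
  out <- data.frame(t = result$times[keep], msd = msd[keep],
                    n_alive = n_alive[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Earliest first passage time in the ensemble
#'
#' The time at which the "fastest" tracer reached the narrow end: the minimum
#' uncensored first passage time. Used as the upper edge of the
#' power-law fitting window (only data collected before any tracer crossed
#' the whole channel enter the fit).
#'
#' @param result an [run_ensemble()] result.
#' @return The minimum first passage time (a step index).
#' @export
find_tmin <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  f <- result$fpt[!is.na(result$fpt)]
  if (length(f) == 0)
    stop("no trajectory was absorbed; cannot determine tmin")
  min(f)
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Least squares of `msd = D * t^alpha` in linear space over the window
#' `[0.01 * t_min, t_min]`, initialized from (and also reporting) a log-log
#' linear regression. `alpha = 1` is normal diffusion, `alpha < 1`
#' subdiffusion.
#'
#' With the default `weighting = "interval"` each curve point is weighted by
#' the width of the time interval it represents, so the fit approximates a
#' least-squares fit over *every* time step inside the window (the natural
#' reading of fitting a fully stored MSD curve) and is invariant to the
#' density of the sampling grid. `weighting = "none"` weights recorded points
#' equally, which on a log-spaced grid emphasizes early times.
#'
#' @param curve an [ensemble_msd()] curve.
#' @param t_min upper window edge, usually [find_tmin()] of the ensemble.
#' @param window_frac lower window edge as a fraction of `t_min`.
#' @param weighting `"interval"` (default) or `"none"`, see Details.
#' @return An object of class `"power_law_fit"` with fields `D`, `alpha`,
#'   `window`, `residual_norm`, `D_loglog`, `alpha_loglog`, `n_points`.
#' @export
fit_power_law <- function(curve, t_min, window_frac = 0.01,
                          weighting = c("interval", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(curve, "msd_curve") || is.data.frame(curve))
  stopifnot(is.numeric(t_min), t_min > 0)
  lo <- window_frac * t_min
  sel <- curve$t >= lo & curve$t <= t_min & curve$msd > 0
  d <- curve[sel, , drop = FALSE]
  if (nrow(d) < 5)
    stop(sprintf("insufficient data: only %d MSD points in [%g, %g] (need >= 5)",
                 nrow(d), lo, t_min))
  w <- if (weighting == "interval") pmax(diff(c(lo, d$t)), 1e-12) else
    rep(1, nrow(d))
  ll <- lm(log(msd) ~ log(t), data = d, weights = w)
  a0 <- unname(coef(ll)[2])
  D0 <- exp(unname(coef(ll)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ D * t^alpha, data = d, weights = w,
                      start = list(D = D0, alpha = a0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear fit did not converge; reporting log-log estimates")
    D <- D0
    alpha <- a0
    rss <- sqrt(sum((d$msd - D * d$t^alpha)^2))
  } else {
    cf <- coef(fit)
    D <- unname(cf["D"])
    alpha <- unname(cf["alpha"])
    rss <- sqrt(sum(residuals(fit)^2))
  }
  structure(list(D = D, alpha = alpha, window = c(t_lo = lo, t_hi = t_min),
                 residual_norm = rss, D_loglog = D0, alpha_loglog = a0,
                 n_points = nrow(d)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> msd ~ D t^alpha: D = %.6g, alpha = %.4f\n",
              x$D, x$alpha))
  cat(sprintf("  window [%g, %g], %d points, residual norm %.4g (log-log alpha %.4f)\n",
              x$window[1], x$window[2], x$n_points, x$residual_norm,
              x$alpha_loglog))
  invisible(x)
}

#' Median first passage time
#'
#' Sample median (midpoint convention) of the uncensored first passage
#' times, a robust location summary of the escape-time distribution. Errors
#' when more than `max_censored_frac` of trajectories are censored, since the
#' median could then be biased downward.
#'
#' @param result an [run_ensemble()] result.
#' @param max_censored_frac tolerated censored fraction.
#' @return The median first passage time.
#' @export
fpt_median <- function(result, max_censored_frac = 0.1) {
  stopifnot(inherits(result, "ensemble_result"))
  f <- result$fpt[!is.na(result$fpt)]
  if (length(f) == 0)
    stop("no trajectory was absorbed; median first passage time undefined")
  cf <- mean(is.na(result$fpt))
  if (cf > max_censored_frac)
    stop(sprintf("censored fraction %.3f exceeds %.3f; median would be unreliable",
                 cf, max_censored_frac))
  median(f)
}

#' Survival probability curve
#'
#' `S(t)` is the fraction of trajectories whose center of mass is still
#' inside the channel at time `t`. Censored trajectories count as surviving
#' up to the censoring cap.
#'
#' @param result an [run_ensemble()] result.
#' @param t_grid increasing vector of times at which to evaluate `S`.
#' @return Data frame with columns `t` and `S`.
#' @export
survival_curve <- function(result, t_grid) {
  stopifnot(inherits(result, "ensemble_result"), is.numeric(t_grid))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (any(t_grid > result$config$max_steps) && any(result$censored))
    warning("t_grid extends beyond the censoring cap; S is unknown there")
  fpt_eff <- ifelse(is.na(result$fpt), Inf, result$fpt)
  S <- vapply(t_grid, function(t) mean(fpt_eff > t), numeric(1))
  data.frame(t = t_grid, S = S)
}

#' Fit an exponential decay to the survival probability
#'
#' Linear least squares of `log S` against `t` over the band
#' `S in [s_lo, s_hi]` (default `[0.01, 0.9]`, excluding the early
#' non-exponential transient and the noisy tail), giving
#' `S(t) = A exp(-lambda t)`.
#'
#' @param S survival values, or the data frame from [survival_curve()] (then
#'   `t_grid` may be omitted).
#' @param t_grid times matching `S`.
#' @param s_lo,s_hi fitting band on `S`.
#' @return An object of class `"survival_fit"` with fields `A`, `lam`,
#'   `window`, `r_squared`, `n_points`.
#' @export
fit_exponential <- function(S, t_grid = NULL, s_lo = 0.01, s_hi = 0.9) {
  if (is.data.frame(S)) {
    t_grid <- S$t
    S <- S$S
  }
  stopifnot(length(S) == length(t_grid))
  sel <- S >= s_lo & S <= s_hi & S > 0
  if (sum(sel) < 5)
    stop(sprintf("insufficient data: only %d survival points with S in [%g, %g] (need >= 5)",
                 sum(sel), s_lo, s_hi))
  tt <- t_grid[sel]
  ls <- log(S[sel])
  fit <- lm(ls ~ tt)
  lam <- -unname(coef(fit)[2])
  A <- exp(unname(coef(fit)[1]))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact inputs fit perfectly
  structure(list(A = A, lam = lam,
                 window = c(t_lo = min(tt), t_hi = max(tt),
                            s_lo = s_lo, s_hi = s_hi),
                 r_squared = r2, n_points = length(tt)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> S(t) ~ A exp(-lambda t): A = %.4f, lambda = %.4g per step\n",
              x$A, x$lam))
  cat(sprintf("  band S in [%g, %g], t in [%g, %g], %d points, R^2 = %.4f\n",
              x$window["s_lo"], x$window["s_hi"], x$window["t_lo"],
              x$window["t_hi"], x$n_points, x$r_squared))
  invisible(x)
}

#' Orientation histogram
#'
#' Distribution of the angle `theta = acos(|u_z|)` between the particle axis
#' and the channel axis, folded into `[0, pi/2]` because the molecular axis
#' is a director (`u` and `-u` are the same body). Pooled over the
#' linear-stride pre-absorption occupation samples of all trajectories and
#' normalized to integrate to 1. The column `density_over_sin` additionally
#' divides by `sin(theta)`, the isotropic (uniform-sphere) measure, so an
#' isotropic ensemble gives a flat `density_over_sin`.
#'
#' @param result an [run_ensemble()] result.
#' @param n_bins number of equal-width bins on `[0, pi/2]`.
#' @return An object of class `"orientation_histogram"`: data frame with
#'   `theta_lo`, `theta_hi`, `theta_mid`, `count`, `density`,
#'   `density_over_sin`; attribute `n_total`.
#' @export
orientation_histogram <- function(result, n_bins = 30) {
  stopifnot(inherits(result, "ensemble_result"), n_bins >= 2)
  if (nrow(result$occ) == 0) stop("no occupation samples recorded")
  theta <- acos(pmin(1, result$occ[, "abs_uz"]))
  breaks <- seq(0, pi / 2, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(theta, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  width <- diff(breaks)
  dens <- cnt / (sum(cnt) * width)
  mid <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  out <- data.frame(theta_lo = breaks[-(n_bins + 1)], theta_hi = breaks[-1],
                    theta_mid = mid, count = cnt, density = dens,
                    density_over_sin = dens / sin(mid))
  attr(out, "n_total") <- sum(cnt)
  class(out) <- c("orientation_histogram", "data.frame")
  out
}

#' Axial position histogram (occupation fraction)
#'
#' Normalized density `f(z)` of the center-of-mass axial position over all
#' pre-absorption occupation samples pooled across trajectories, on
#' equal-width bins spanning `[0, L]`. Because samples are taken on a linear
#' time stride, `f(z)` estimates the fraction of time spent at `z`, i.e. the
#' occupation probability density `p(z)`.
#'
#' @param result an [run_ensemble()] result.
#' @param n_bins number of equal-width bins on `[0, L]`.
#' @return An object of class `"position_histogram"`: data frame with `z_lo`,
#'   `z_hi`, `z_mid`, `count`, `density`; attribute `n_total`.
#' @export
position_histogram <- function(result, n_bins = 30) {
  stopifnot(inherits(result, "ensemble_result"), n_bins >= 2)
  if (nrow(result$occ) == 0) stop("no occupation samples recorded")
  L <- result$config$channel$L
  z <- result$occ[, "z"]
  breaks <- seq(0, L, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  width <- diff(breaks)
  dens <- cnt / (sum(cnt) * width)
  mid <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  out <- data.frame(z_lo = breaks[-(n_bins + 1)], z_hi = breaks[-1],
                    z_mid = mid, count = cnt, density = dens)
  attr(out, "n_total") <- sum(cnt)
  class(out) <- c("position_histogram", "data.frame")
  out
}

#' Entropic force profile from an occupation histogram
#'
#' The entropic force is proportional to the gradient of the entropy, i.e.
#' of the log occupation density: `F_S(z) ~ d ln f / dz` (proportionality
#' constant set to 1, units of inverse length). Estimated by central finite
#' differences of `ln f` at the bin centers, one-sided at the two edges.
#' Negative values push the particle back toward the wide end.
#'
#' @param hist a [position_histogram()] with strictly positive interior
#'   densities.
#' @return Data frame with columns `z` (bin centers) and `force`.
#' @export
entropic_force <- function(hist) {
  stopifnot(inherits(hist, "position_histogram") || is.data.frame(hist))
  f <- hist$density
  z <- hist$z_mid
  n <- length(f)
  if (n < 3) stop("need at least 3 bins for a force profile")
  if (any(f[2:(n - 1)] <= 0))
    stop("zero occupation density in an interior bin; entropic force undefined there")
  lf <- log(f)
  force <- numeric(n)
  force[1] <- if (f[1] > 0) (lf[2] - lf[1]) / (z[2] - z[1]) else NA_real_
  force[n] <- if (f[n] > 0) (lf[n] - lf[n - 1]) / (z[n] - z[n - 1]) else NA_real_
  i <- 2:(n - 1)
  force[i] <- (lf[i + 1] - lf[i - 1]) / (z[i + 1] - z[i - 1])
  data.frame(z = z, force = force)
}

#' Run the full analysis toolchain on an ensemble
#'
#' Computes the survivor-averaged MSD and its power-law fit over
#' `[0.01 tmin, tmin]`, the median first passage time, the survival curve and
#' its exponential fit, orientation and position histograms, and the entropic
#' force profile. Components whose preconditions fail (e.g. the median under
#' heavy censoring) are returned as `NULL` with the reason in `notes`.
#'
#' @param result an [run_ensemble()] result.
#' @param n_bins_z,n_bins_theta histogram bin counts.
#' @param surv_grid_n number of points of the linear survival grid.
#' @param s_band exponential-fit band on `S`.
#' @return An object of class `"ensemble_analysis"`.
#' @export
analyze_ensemble <- function(result, n_bins_z = 30, n_bins_theta = 30,
                             surv_grid_n = 200, s_band = c(0.01, 0.9)) {
  stopifnot(inherits(result, "ensemble_result"))
  notes <- character(0)
  grab <- function(expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
  }
  msd <- grab(ensemble_msd(result))
  tmin <- grab(find_tmin(result))
  msd_fit <- if (!is.null(msd) && !is.null(tmin))
    grab(fit_power_law(msd, tmin)) else NULL
  med <- grab(fpt_median(result))
  t_hi <- max(result$fpt, result$config$max_steps * any(result$censored),
              na.rm = TRUE)
  grid <- unique(round(seq(0, t_hi, length.out = surv_grid_n + 1)))
  surv <- grab(survival_curve(result, grid[-1]))
  surv_fit <- if (!is.null(surv))
    grab(fit_exponential(surv, s_lo = s_band[1], s_hi = s_band[2])) else NULL
  hist_theta <- grab(orientation_histogram(result, n_bins_theta))
  hist_z <- grab(position_histogram(result, n_bins_z))
  force <- if (!is.null(hist_z)) grab(entropic_force(hist_z)) else NULL
  structure(list(msd = msd, tmin = tmin, msd_fit = msd_fit,
                 median_fpt = med,
                 censored_frac = mean(result$censored),
                 survival = surv, surv_fit = surv_fit,
                 hist_theta = hist_theta, hist_z = hist_z, force = force,
                 notes = notes),
            class = "ensemble_analysis")
}

#' @export
print.ensemble_analysis <- function(x, ...) {
  cat("<ensemble_analysis>\n")
  if (!is.null(x$msd_fit))
    cat(sprintf("  MSD fit: alpha = %.4f, D = %.6g (window up to tmin = %g)\n",
                x$msd_fit$alpha, x$msd_fit$D, x$tmin))
  if (!is.null(x$median_fpt))
    cat(sprintf("  median first passage time: %g steps (censored fraction %.3f)\n",
                x$median_fpt, x$censored_frac))
  if (!is.null(x$surv_fit))
    cat(sprintf("  survival fit: A = %.4f, lambda = %.4g per step, R^2 = %.4f\n",
                x$surv_fit$A, x$surv_fit$lam, x$surv_fit$r_squared))
  if (length(x$notes))
    cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$t[x$t > 0], x$msd[x$t > 0], log = "xy", type = "l",
       xlab = "t (steps)", ylab = "mean squared displacement", ...)
  invisible(x)
}
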