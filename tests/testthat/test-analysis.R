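make_times <- function(tt) c(0, tt)

test_that("survivor-averaged MSD handles frozen, ballistic and censored cases", {
  tt <- make_times(c(1, 2, 5, 10, 20, 50))
  n <- length(tt)
  zero <- matrix(0, n, 1)
  frozen <- fake_ensemble(tt, zero, zero, zero, fpt = NA)
  expect_true(all(ensemble_msd(frozen)$msd == 0))
  # straight-line walk c(t) = (v t, 0, 0): msd = v^2 t^2
  v <- 0.3
  ball <- fake_ensemble(tt, matrix(v * tt, n, 1), zero, zero, fpt = NA)
  curve <- ensemble_msd(ball)
  expect_equal(curve$msd, (v * curve$t)^2, tolerance = 1e-12)
  fit <- fit_power_law(curve, t_min = 50)
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$D, v^2, tolerance = 1e-6)
  # absorbed trajectories drop out of the average from absorption onward
  x2 <- cbind(c(0, 1, 1, 1, NA, NA, NA), c(0, 3, 3, 3, 3, 3, 3))
  z2 <- matrix(0, n, 2)
  mix <- fake_ensemble(tt, x2, z2, z2, fpt = c(6, NA))
  curve2 <- ensemble_msd(mix)
  expect_equal(curve2$n_alive, c(2, 2, 2, 2, 1, 1, 1))
  expect_equal(curve2$msd, c(0, 5, 5, 5, 9, 9, 9))
})

test_that("MSD of a free Gaussian walk grows as 3 sigma^2 t", {
  set.seed(42)
  n_rep <- 800
  tt <- c(1, 2, 5, 10, 20, 50, 100)
  walk <- function() apply(sample_translation(100, 0.05), 2, cumsum)
  x <- matrix(NA_real_, length(tt) + 1, n_rep)
  y <- x; z <- x
  for (j in seq_len(n_rep)) {
    w <- walk()
    x[, j] <- c(0, w[tt, 1]); y[, j] <- c(0, w[tt, 2]); z[, j] <- c(0, w[tt, 3])
  }
  ens <- fake_ensemble(make_times(tt), x, y, z, fpt = rep(NA, n_rep),
                       max_steps = 200)
  curve <- ensemble_msd(ens)
  for (i in which(curve$t > 0)) {
    th <- 3 * 0.05^2 * curve$t[i]
    # var of a mean of n chi-square-like terms: s.e. = th * sqrt(2/3) / sqrt(n)
    se <- th * sqrt(2 / 3) / sqrt(n_rep)
    expect_lt(abs(curve$msd[i] - th), 3.5 * se)
  }
  fit <- fit_power_law(curve, t_min = 100)
  expect_gt(fit$alpha, 0.93)
  expect_lt(fit$alpha, 1.07)
})

test_that("tmin is the fastest uncensored passage", {
  tt <- make_times(c(1, 2))
  z <- matrix(0, 3, 3)
  ens <- fake_ensemble(tt, z, z, z, fpt = c(100, 250, 90))
  expect_equal(find_tmin(ens), 90)
  ens2 <- fake_ensemble(tt, z, z, z, fpt = c(NA, 2000, 1500))
  expect_equal(find_tmin(ens2), 1500)
  ens3 <- fake_ensemble(tt, z, z, z, fpt = c(NA, NA, NA))
  expect_error(find_tmin(ens3), "absorbed")
})

test_that("power-law fits recover noiseless curves exactly", {
  tt <- round(10^seq(0, 3, length.out = 40))
  tt <- unique(tt)
  curve <- data.frame(t = tt, msd = 2 * tt^0.8, n_alive = 100)
  class(curve) <- c("msd_curve", "data.frame")
  fit <- fit_power_law(curve, t_min = 1000)
  expect_equal(fit$alpha, 0.8, tolerance = 1e-6)
  expect_equal(fit$D, 2, tolerance = 1e-6)
  lin <- data.frame(t = tt, msd = 0.0075 * tt, n_alive = 100)
  class(lin) <- c("msd_curve", "data.frame")
  fit2 <- fit_power_law(lin, t_min = 1000)
  expect_equal(fit2$alpha, 1, tolerance = 1e-6)
  expect_equal(fit2$D, 0.0075, tolerance = 1e-6)
  expect_error(fit_power_law(curve[1:3, ], t_min = 1000), "insufficient")
})

test_that("median passage time uses midpoints and guards against censoring", {
  tt <- make_times(c(1, 2))
  z3 <- matrix(0, 3, 3); z4 <- matrix(0, 3, 4)
  expect_equal(fpt_median(fake_ensemble(tt, z3, z3, z3, fpt = c(1, 2, 3))), 2)
  expect_equal(fpt_median(fake_ensemble(tt, z4, z4, z4,
                                        fpt = c(1, 2, 3, 100))), 2.5)
  heavy <- fake_ensemble(tt, z4, z4, z4, fpt = c(1, 2, NA, NA))
  expect_error(fpt_median(heavy), "censored")
  none <- fake_ensemble(tt, z3, z3, z3, fpt = c(NA, NA, NA))
  expect_error(fpt_median(none), "absorbed")
})

test_that("survival curve counts censored walkers as still inside", {
  tt <- make_times(c(1, 2))
  z <- matrix(0, 3, 4)
  ens <- fake_ensemble(tt, z, z, z, fpt = c(10, 20, 30, 40), max_steps = 100)
  expect_equal(survival_curve(ens, c(5, 25, 50))$S, c(1, 0.5, 0))
  cen <- fake_ensemble(tt, z, z, z, fpt = c(10, 20, NA, NA), max_steps = 100)
  expect_equal(survival_curve(cen, c(25, 90))$S, c(0.5, 0.5))
  expect_error(survival_curve(ens, c(5, 5)), "increasing")
})

test_that("exponential survival fits are exact on their model family", {
  t_grid <- seq(100, 8000, by = 100)
  S <- exp(-1e-3 * t_grid)
  fit <- fit_exponential(S, t_grid)
  expect_equal(fit$A, 1, tolerance = 1e-9)
  expect_equal(fit$lam, 1e-3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # prefactor recovery with the band trimming the early transient
  S2 <- 2 * exp(-1e-3 * t_grid)
  fit2 <- fit_exponential(S2[S2 <= 0.9], t_grid[S2 <= 0.9])
  expect_equal(fit2$A, 2, tolerance = 1e-9)
  expect_error(fit_exponential(c(0.5, 0.4), c(1, 2)), "insufficient")
})

test_that("orientation histograms fold the director angle onto [0, pi/2]", {
  tt <- make_times(c(1, 2))
  z <- matrix(0, 3, 1)
  ax <- fake_ensemble(tt, z, z, z, fpt = NA,
                      occ = cbind(z = rep(1, 50), abs_uz = rep(1, 50)))
  h <- orientation_histogram(ax, n_bins = 10)
  expect_equal(h$count[1], 50)
  expect_true(all(h$count[-1] == 0))
  perp <- fake_ensemble(tt, z, z, z, fpt = NA,
                        occ = cbind(z = rep(1, 50), abs_uz = rep(0, 50)))
  h2 <- orientation_histogram(perp, n_bins = 10)
  expect_equal(h2$count[10], 50)
  # isotropic directors: density proportional to sin(theta)
  set.seed(42)
  u <- sample_rotation_axis(2e5)
  iso <- fake_ensemble(tt, z, z, z, fpt = NA,
                       occ = cbind(z = rep(1, 2e5), abs_uz = abs(u[, 3])))
  h3 <- orientation_histogram(iso, n_bins = 12)
  p_bin <- cos(h3$theta_lo) - cos(h3$theta_hi)  # exact isotropic bin mass
  expect_true(all(abs(h3$count / 2e5 - p_bin) <
                    3.5 * sqrt(p_bin * (1 - p_bin) / 2e5)))
  # densities integrate to one
  expect_equal(sum(h3$density * (h3$theta_hi - h3$theta_lo)), 1,
               tolerance = 1e-9)
})

test_that("position histograms are time-weighted occupation densities", {
  tt <- make_times(c(1, 2))
  zm <- matrix(0, 3, 1)
  one <- fake_ensemble(tt, zm, zm, zm, fpt = NA,
                       occ = cbind(z = rep(7.1, 40), abs_uz = rep(1, 40)))
  h <- position_histogram(one, n_bins = 15)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(h$z_mid[h$count > 0], 7.5)
  set.seed(43)
  unif <- fake_ensemble(tt, zm, zm, zm, fpt = NA,
                        occ = cbind(z = runif(1e5, 0, 15),
                                    abs_uz = rep(1, 1e5)))
  h2 <- position_histogram(unif, n_bins = 10)
  expect_true(all(abs(h2$density - 1 / 15) < 3.5 *
                    sqrt((1 / 10) * (9 / 10) / 1e5) / 1.5))
  expect_equal(sum(h2$density * (h2$z_hi - h2$z_lo)), 1, tolerance = 1e-9)
})

test_that("entropic force is the log-density gradient", {
  z_mid <- seq(0.5, 14.5, by = 1)
  mk_hist <- function(dens) {
    h <- data.frame(z_lo = z_mid - 0.5, z_hi = z_mid + 0.5, z_mid = z_mid,
                    count = 1, density = dens)
    class(h) <- c("position_histogram", "data.frame")
    h
  }
  # f ~ exp(-z): force identically -1 (central differences are exact for
  # log-linear densities)
  f <- entropic_force(mk_hist(exp(-z_mid) / sum(exp(-z_mid))))
  expect_equal(f$force, rep(-1, length(z_mid)), tolerance = 1e-9)
  # flat density: zero force
  f2 <- entropic_force(mk_hist(rep(1 / 15, length(z_mid))))
  expect_equal(f2$force, rep(0, length(z_mid)))
  # equilibrium occupation proportional to the cross-section area R(z)^2
  ch <- reference_cone()
  fr <- entropic_force(mk_hist(radius_at(ch, z_mid)^2))
  analytic <- 2 * ch$slope / radius_at(ch, z_mid)
  expect_true(all(fr$force < 0))
  expect_equal(fr$force[2:14], analytic[2:14], tolerance = 5e-3)
  bad <- mk_hist(c(0.1, 0.1, 0, rep(0.1, 12)))
  expect_error(entropic_force(bad), "interior")
})
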