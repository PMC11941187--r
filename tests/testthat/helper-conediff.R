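# Shared fixtures and independent oracles, all built in code at test time.

reference_cone <- function() channel(L = 15, R0 = 0.5, RL = 0.25)

# Wide cylinder in which the wall is effectively unreachable: isolates the
# axial entrance/absorption dynamics for comparison with the 1D oracle.
open_channel <- function(L = 5) channel(L = L, R0 = 50, RL = 50)

# Short channel so that absorption happens within a few 1e4 steps; used where
# analysis tests need uncensored first passage times quickly.
short_cone <- function() channel(L = 5, R0 = 0.5, RL = 0.25)

# Independent 1D oracle: rejection random walk on [0, L], Gaussian steps of
# s.d. sigma, proposals below 0 rejected, absorption at z >= L. Returns the
# vector of first passage times. Vectorized over walkers.
walk_1d_fpt <- function(n, L, sigma, seed, max_steps = 5e6) {
  set.seed(seed)
  z <- numeric(n)
  fpt <- rep(NA_real_, n)
  alive <- seq_len(n)
  t <- 0
  while (length(alive) > 0 && t < max_steps) {
    t <- t + 1
    prop <- z[alive] + rnorm(length(alive), sd = sigma)
    ok <- prop >= 0
    z[alive[ok]] <- prop[ok]
    done <- z[alive] >= L
    if (any(done)) {
      fpt[alive[done]] <- t
      alive <- alive[!done]
    }
  }
  fpt
}

# Monte-Carlo oracle for the spherocylinder inertia integrals: uniform points
# in the solid; returns per-sample squared distances from the transverse and
# long axes, from which moments and their standard errors follow.
mc_inertia_samples <- function(n, l, r, seed) {
  set.seed(seed)
  v_cyl <- pi * r^2 * l
  v_sph <- 4 / 3 * pi * r^3
  in_cyl <- runif(n) < v_cyl / (v_cyl + v_sph)
  n_cyl <- sum(in_cyl)
  n_sph <- n - n_cyl
  # cylinder: uniform in axial position and over the disk
  rho_c <- r * sqrt(runif(n_cyl))
  phi_c <- runif(n_cyl, 0, 2 * pi)
  z_c <- runif(n_cyl, -l / 2, l / 2)
  x_c <- rho_c * cos(phi_c)
  y_c <- rho_c * sin(phi_c)
  # hemispheres: uniform in the ball, axial coordinate folded outward and
  # shifted to the caps
  rad <- r * runif(n_sph)^(1 / 3)
  u <- matrix(rnorm(3 * n_sph), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  x_s <- rad * u[, 1]
  y_s <- rad * u[, 2]
  zb <- abs(rad * u[, 3])
  side <- sample(c(-1, 1), n_sph, replace = TRUE)
  z_s <- side * (l / 2 + zb)
  x <- c(x_c, x_s); y <- c(y_c, y_s); z <- c(z_c, z_s)
  list(sq_transverse = y^2 + z^2,  # integrand of Mxx (axis = body x)
       sq_axial = x^2 + y^2)       # integrand of Mzz (axis = body z)
}

# Minimal clearance margin of a particle state: min over the two axis-segment
# endpoints of (wall clearance - r). Positive inside, negative outside.
clearance_margin <- function(ch, particle, states) {
  hl <- particle$l / 2
  e1 <- states[, 1:3, drop = FALSE] + hl * states[, 4:6, drop = FALSE]
  e2 <- states[, 1:3, drop = FALSE] - hl * states[, 4:6, drop = FALSE]
  pmin(wall_clearance(ch, e1), wall_clearance(ch, e2)) - particle$r
}

# Random particle states: centers uniform in a box spanning the channel
# (including the overhang regions), orientations uniform on the sphere.
random_states <- function(n, ch, particle, seed) {
  set.seed(seed)
  cx <- runif(n, -ch$R0, ch$R0)
  cy <- runif(n, -ch$R0, ch$R0)
  cz <- runif(n, -particle$l, ch$L + particle$l)
  u <- sample_rotation_axis(n)
  cbind(cx, cy, cz, u)
}

# Hand-built ensemble_result for unit-testing the analysis layer in isolation.
fake_ensemble <- function(times, x, y, z, fpt, uz = NULL, occ = NULL,
                          max_steps = max(times) + 1, L = 15) {
  n_rep <- ncol(x)
  cfg <- sim_config(channel = channel(L = L),
                    particle = spherocylinder(0, 0.01),
                    n_rep = n_rep, seed = 1, max_steps = max_steps,
                    sample_times = times[times > 0])
  if (is.null(uz)) uz <- matrix(1, nrow = nrow(x), ncol = n_rep)
  if (is.null(occ)) occ <- cbind(z = as.vector(z[!is.na(z)]),
                                 abs_uz = rep(1, sum(!is.na(z))))
  colnames(occ) <- c("z", "abs_uz")
  structure(list(config = cfg, fpt = fpt, censored = is.na(fpt),
                 accepted_translations = rep(0, n_rep),
                 accepted_rotations = rep(0, n_rep),
                 steps_run = ifelse(is.na(fpt), max_steps, fpt),
                 stream_id = seq_len(n_rep) - 1,
                 times = times, x = x, y = y, z = z,
                 ux = uz * 0, uy = uz * 0, uz = uz,
                 occ = occ, occ_stride = 1),
            class = "ensemble_result")
}
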