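test_that("identical configurations reproduce bit-for-bit", {
  cfg <- sim_config(channel = short_cone(),
                    particle = spherocylinder(0.25, 0.05),
                    n_rep = 20, seed = 42, max_steps = 5e4)
  a <- run_ensemble(cfg)
  b <- run_ensemble(cfg)
  expect_identical(a$fpt, b$fpt)
  expect_identical(a$x, b$x)
  expect_identical(a$uz, b$uz)
  expect_identical(a$occ, b$occ)
})

test_that("trajectories live on independent substreams", {
  cfg <- sim_config(channel = short_cone(),
                    particle = spherocylinder(0.25, 0.05),
                    n_rep = 5, seed = 42, max_steps = 2e4)
  ens <- run_ensemble(cfg)
  # a single run on substream 0 equals the first ensemble trajectory
  one <- run_single(cfg)
  expect_identical(one$fpt[1], ens$fpt[1])
  expect_identical(one$x[, 1], ens$x[, 1])
  # substream k alone equals trajectory k+1 of the ensemble
  cfg3 <- sim_config(channel = short_cone(),
                     particle = spherocylinder(0.25, 0.05),
                     n_rep = 1, seed = 42, max_steps = 2e4,
                     stream_offset = 2)
  third <- run_ensemble(cfg3)
  expect_identical(third$fpt[1], ens$fpt[3])
  expect_identical(third$z[, 1], ens$z[, 3])
  # different seeds decorrelate
  cfg_b <- sim_config(channel = short_cone(),
                      particle = spherocylinder(0.25, 0.05),
                      n_rep = 5, seed = 43, max_steps = 2e4)
  expect_false(identical(run_ensemble(cfg_b)$fpt, ens$fpt))
})

test_that("recorded states always satisfy the containment and entrance rules", {
  cfg <- sim_config(channel = short_cone(),
                    particle = spherocylinder(0.5, 0.08),
                    n_rep = 30, seed = 42, max_steps = 5e4)
  res <- run_ensemble(cfg)
  p <- cfg$particle
  ok <- !is.na(res$z)
  states <- cbind(res$x[ok], res$y[ok], res$z[ok],
                  res$ux[ok], res$uy[ok], res$uz[ok])
  expect_true(all(spherocylinder_inside(short_cone(), p, states)))
  expect_true(all(res$z[ok] >= 0))
  expect_true(all(res$z[ok] < short_cone()$L))
  # orientations stay unit vectors after millions of incremental rotations
  norms <- sqrt(res$ux[ok]^2 + res$uy[ok]^2 + res$uz[ok]^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  # occupation samples obey the same bounds
  expect_true(all(res$occ[, "z"] >= 0 & res$occ[, "z"] < short_cone()$L))
  expect_true(all(res$occ[, "abs_uz"] >= 0 & res$occ[, "abs_uz"] <= 1))
})

test_that("time accounting counts rejected attempts and censors at the cap", {
  cfg <- sim_config(channel = short_cone(),
                    particle = spherocylinder(0.25, 0.05),
                    n_rep = 25, seed = 42, max_steps = 4e4)
  res <- run_ensemble(cfg)
  absorbed <- !res$censored
  expect_true(any(absorbed))
  expect_identical(res$steps_run[absorbed], res$fpt[absorbed])
  expect_true(all(res$steps_run[res$censored] == cfg$max_steps))
  expect_true(all(res$accepted_translations <= res$steps_run))
  expect_true(all(res$accepted_rotations <= res$steps_run))
  # crude lower bound: crossing L takes many steps even at 3-sigma moves
  expect_true(all(res$fpt[absorbed] >= short_cone()$L / (3 * cfg$sigma_x)))
  # a cap below any plausible passage time censors everything
  cfg_short <- sim_config(channel = short_cone(),
                          particle = spherocylinder(0.25, 0.05),
                          n_rep = 5, seed = 42, max_steps = 50)
  expect_true(all(run_ensemble(cfg_short)$censored))
})

test_that("a sphere never has a rotation rejected", {
  cfg <- sim_config(channel = short_cone(), particle = spherocylinder(0, 0.05),
                    n_rep = 10, seed = 42, max_steps = 2e4)
  res <- run_ensemble(cfg)
  expect_identical(res$accepted_rotations, res$steps_run)
})

test_that("vanishing noise freezes the dynamics", {
  cfg <- sim_config(channel = short_cone(), particle = spherocylinder(0, 0.05),
                    sigma_x = 1e-13, n_rep = 3, seed = 42, max_steps = 1e4)
  res <- run_ensemble(cfg)
  expect_true(all(res$censored))
  ok <- !is.na(res$z)
  expect_true(all(abs(res$z[ok]) < 1e-8))
  expect_true(all(abs(res$x[ok]) < 1e-8))
})

test_that("axial first passage matches the 1D rejection-walk oracle", {
  # wall at radius 50 is unreachable: the model reduces exactly to the 1D
  # rejection walk in z with reflecting entrance and absorbing exit
  L <- 5
  cfg <- sim_config(channel = open_channel(L),
                    particle = spherocylinder(0, 0.01),
                    n_rep = 300, seed = 42, max_steps = 5e5)
  res <- run_ensemble(cfg)
  expect_true(all(!res$censored))
  oracle <- walk_1d_fpt(300, L, 0.05, seed = 99)
  m_sim <- mean(res$fpt)
  m_or <- mean(oracle)
  se <- sqrt(var(res$fpt) / 300 + var(oracle) / 300)
  expect_lt(abs(m_sim - m_or), 3 * se)
  # and both sit near the continuum mean first passage time L^2 / sigma^2
  expect_lt(abs(m_sim - L^2 / 0.05^2), 0.1 * L^2 / 0.05^2)
  med_se <- 1.25 * sqrt(var(res$fpt) / 300 + var(oracle) / 300)
  expect_lt(abs(median(res$fpt) - median(oracle)), 3 * med_se)
})

test_that("independent seeds give statistically consistent passage medians", {
  cfgs <- lapply(c(42, 43), function(s)
    sim_config(channel = open_channel(5), particle = spherocylinder(0, 0.01),
               n_rep = 200, seed = s, max_steps = 5e5))
  meds <- numeric(2)
  ses <- numeric(2)
  for (i in 1:2) {
    f <- run_ensemble(cfgs[[i]])$fpt
    meds[i] <- median(f)
    ses[i] <- 1.25 * sd(f) / sqrt(length(f))  # asymptotic s.e. of a median
  }
  expect_lt(abs(meds[1] - meds[2]), 3 * sqrt(sum(ses^2)))
})
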