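test_that("zero-noise SgLV paths agree with the deterministic solution", {
  p <- glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027)
  x0 <- c(10, 20)
  st <- simulate_sglv(p, x0, horizon = 5, dt = 1e-3, seed = 1)
  dt_sol <- simulate_glv(p, x0, horizon = 5, n_out = nrow(st))
  # O(dt) global error on the shared grid
  expect_lt(max(abs(sglv:::traj_states(st) - sglv:::traj_states(dt_sol))),
            0.2)
  # and the error shrinks with dt (first-order scheme)
  st2 <- simulate_sglv(p, x0, horizon = 5, dt = 1e-2, seed = 1)
  dt2 <- simulate_glv(p, x0, horizon = 5, n_out = nrow(st2))
  err_coarse <- max(abs(sglv:::traj_states(st2) - sglv:::traj_states(dt2)))
  err_fine <- max(abs(sglv:::traj_states(st) - sglv:::traj_states(dt_sol)))
  expect_lt(err_fine, err_coarse / 3)
})

test_that("stochastic paths are strictly positive and seed-deterministic", {
  s <- glv_scenario(2)  # the high-noise scenario stresses positivity hardest
  a <- simulate_sglv(s$params, c(1e-3, 200), horizon = 2, dt = 1e-3, seed = 7)
  expect_true(all(sglv:::traj_states(a) > 0))
  b <- simulate_sglv(s$params, c(1e-3, 200), horizon = 2, dt = 1e-3, seed = 7)
  expect_identical(sglv:::traj_states(a), sglv:::traj_states(b))
  c2 <- simulate_sglv(s$params, c(1e-3, 200), horizon = 2, dt = 1e-3, seed = 8)
  expect_false(identical(sglv:::traj_states(a), sglv:::traj_states(c2)))
})

test_that("mutualistic blow-up is caught by the abundance cap", {
  p <- glv_params_2sp(2, 2, b11 = 0.1, b12 = 0.5, b21 = 0.5, b22 = 0.1,
                      tau = diag(2) * 0.05)
  expect_error(simulate_sglv(p, c(100, 100), horizon = 50, dt = 1e-3,
                             seed = 3),
               "blow-up|mutualistic")
})

test_that("deterministic boundary faces are invariant and equilibria are fixed", {
  p <- glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027)
  z <- simulate_glv(p, c(0, 0), horizon = 3)
  expect_equal(max(abs(sglv:::traj_states(z))), 0)
  # with the coupling removed, species 1 sits at its carrying capacity 120
  p1 <- glv_params_2sp(6, 4, 0.05, 0, 0, 0.027)
  cc <- simulate_glv(p1, c(120, 0), horizon = 3)
  expect_equal(sglv:::traj_states(cc)[, 1], rep(120, nrow(cc)),
               tolerance = 1e-8)
  expect_equal(sglv:::traj_states(cc)[, 2], rep(0, nrow(cc)))
  # interior start converges to E* = (40, 133.333)
  tr <- simulate_glv(p, c(10, 10), horizon = 40)
  expect_equal(unname(tail(sglv:::traj_states(tr), 1)[1, ]),
               c(40, 400 / 3), tolerance = 1e-5)
})

test_that("stationary_mean averages with batch-means errors", {
  # constant path: mean is the value, mc_se is zero
  p <- glv_params_2sp(6, 4, 0.05, 0, 0, 0.027)
  cc <- simulate_glv(p, c(120, 4 / 0.027), horizon = 10, n_out = 501)
  est <- stationary_mean(cc, burn_in = 1)
  expect_equal(est$mean, c(120, 4 / 0.027), tolerance = 1e-6)
  expect_lt(max(est$mc_se), 1e-6)
  expect_error(stationary_mean(cc, burn_in = 11), "burn_in|horizon")
})

test_that("1-D logistic SDE time average converges to the Gamma mean", {
  # alpha = 6, b = 0.05, sigma = 0.000325: stationary law is
  # Gamma(2 alpha/sigma - 1, sigma/(2b)) with mean (alpha - sigma/2)/b
  sigma <- 0.000325
  gmean <- (6 - sigma / 2) / 0.05
  p <- glv_params(6, matrix(-0.05), matrix(sqrt(sigma)))
  for (dt in c(1e-2, 1e-3)) {
    tr <- simulate_sglv(p, 120, horizon = 2000, dt = dt, seed = 11)
    est <- stationary_mean(tr, burn_in = 200)
    expect_lt(abs(est$mean - gmean), 3 * est$mc_se)
  }
})

test_that("pulses displace additively and guard positivity", {
  expect_equal(apply_pulse(c(38.7, 135.4), c(10, 15)), c(48.7, 150.4))
  expect_equal(apply_pulse(c(5, 5), c(0, 0)), c(5, 5))
  expect_error(apply_pulse(c(5, 5), c(-6, 0)), "infeasible")
})

test_that("trajectories round-trip through CSV with metadata", {
  s <- glv_scenario(1)
  tr <- simulate_sglv(s$params, c(40, 130), horizon = 0.1, dt = 1e-3,
                      seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(unname(sglv:::traj_states(back)),
               unname(sglv:::traj_states(tr)), tolerance = 1e-12)
  expect_identical(attr(back, "scheme"), "log-euler-maruyama")
  expect_equal(attr(back, "seed"), 2)
})
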