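# explicit-coefficient competitive pair used throughout this file
p_comp <- function() glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027,
                                    tau = c(0.01, 0.015, 0.01, 0.02))

test_that("equilibrium enumeration finds all boundary and interior points", {
  eq <- enumerate_equilibria(p_comp())
  expect_equal(nrow(eq), 4L)
  coords <- do.call(rbind, eq$coords)
  # origin, the two axis carrying capacities, and the interior linear solve
  expect_equal(coords[eq$label == "origin", ], c(0, 0))
  expect_equal(sort(coords[eq$label == "boundary", 1]), c(0, 120),
               tolerance = 1e-10)
  expect_equal(sort(coords[eq$label == "boundary", 2]), c(0, 4 / 0.027),
               tolerance = 1e-10)
  expect_equal(coords[eq$label == "interior", ], c(40, 400 / 3),
               tolerance = 1e-10)
  expect_true(all(lengths(eq$eigenvalues) == 2L))

  # single logistic species: {0, alpha/b}
  eq1 <- enumerate_equilibria(glv_params(1, matrix(-1)))
  expect_equal(sort(unlist(eq1$coords)), c(0, 1))

  # singular interior subsystem contributes nothing but is recorded
  psing <- glv_params(c(1, 1), matrix(c(-1, 2, 2, -4), 2, 2, byrow = TRUE))
  eqs <- enumerate_equilibria(psing)
  expect_false("interior" %in% eqs$label)
  expect_length(attr(eqs, "skipped"), 1L)
})

test_that("deterministic classification separates persistence and extinction", {
  det <- classify_deterministic(p_comp())
  expect_identical(det$verdict, "persistent")
  ints <- det$equilibria[det$equilibria$label == "interior", ]
  expect_true(ints$stable)

  # negative growth everywhere: origin attracts, rates are the alphas
  pneg <- glv_params(c(-1, -1), diag(-1, 2))
  detn <- classify_deterministic(pneg)
  expect_identical(detn$verdict, "extinction")
  org <- detn$attracting[detn$attracting$label == "origin", ]
  expect_equal(sort(org$rates[[1]]), c(-1, -1))

  expect_identical(classify_deterministic(glv_params(1, matrix(-1)))$verdict,
                   "persistent")
})

test_that("single-species boundary law is the stated Gamma distribution", {
  gl <- boundary_gamma(6, 0.05, 0.000325)
  expect_true(gl$exists)
  expect_equal(gl$shape, 2 * 6 / 0.000325 - 1, tolerance = 1e-12)  # 36922.08
  expect_equal(gl$scale, 0.00325, tolerance = 1e-12)
  expect_equal(gl$mean, (6 - 0.000325 / 2) / 0.05, tolerance = 1e-12)
  # threshold alpha = sigma/2 counts as extinction
  expect_false(boundary_gamma(0.5, 1, 1)$exists)
  # small-noise limit recovers the deterministic carrying capacity
  expect_equal(boundary_gamma(6, 0.05, 1e-10)$mean, 120, tolerance = 1e-9)
  expect_error(boundary_gamma(6, 0.05, 0), "positive")
})

test_that("simulated logistic moments match the Gamma law", {
  gl <- boundary_gamma(2, 0.5, 0.02)
  p <- glv_params(2, matrix(-0.5), matrix(sqrt(0.02)))
  tr <- simulate_sglv(p, gl$mean, horizon = 3000, dt = 1e-3, seed = 21)
  x <- sglv:::traj_states(tr)[tr$time >= 300, 1]
  est <- stationary_mean(tr, burn_in = 300)
  expect_lt(abs(est$mean - gl$mean), 3 * est$mc_se)
  # variance = shape * scale^2, with a generous moment-of-moment error band
  expect_equal(var(x), gl$shape * gl$scale^2, tolerance = 0.1)
})

test_that("analytic two-species invasion rates follow the closed-form expressions", {
  s <- glv_scenario(1)
  tab <- lyapunov_2sp(s$params)
  get <- function(mu, i) tab$lambda[tab$measure == mu & tab$species == i]
  expect_equal(get("mu0", 1), 6 - 0.000325 / 2)  # 5.9998375
  expect_equal(get("mu0", 2), 4 - 0.0005 / 2)
  # own-support exponents vanish exactly
  expect_identical(get("mu1", 1), 0)
  expect_identical(get("mu2", 2), 0)
  # lambda2(mu1) = a2 - s2/2 + (b21/b11)(a1 - s1/2), signed b21 = -0.01
  expect_equal(get("mu1", 2),
               (4 - 0.00025) + (-0.01 / 0.05) * (6 - 0.0001625),
               tolerance = 1e-12)

  # zero-noise reduction: deterministic invasion criterion
  p0 <- glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027)
  t0 <- lyapunov_2sp(p0)
  expect_equal(t0$lambda[t0$measure == "mu0" & t0$species == 1], 6)
  expect_equal(t0$lambda[t0$measure == "mu1" & t0$species == 2],
               4 + (-0.01 / 0.05) * 6)
})

test_that("Monte-Carlo invasion rates agree with the analytic formulas", {
  s <- glv_scenario(1)
  tab <- lyapunov_2sp(s$params)
  lam_ref <- tab$lambda[tab$measure == "mu1" & tab$species == 2]
  est <- estimate_invasion_rate(s$params, resident = 1L, invader = 2L,
                                horizon = 1500, dt = 1e-3, seed = 31)
  expect_identical(est$method, "monte-carlo")
  expect_lt(abs(est$lambda - lam_ref), 3 * est$mc_se)

  # empty resident support: exact average over the Dirac mass at the origin
  e0 <- estimate_invasion_rate(s$params, resident = integer(0), invader = 2L)
  expect_identical(e0$method, "exact")
  expect_equal(e0$lambda, 4 - 0.00025)

  # zero-noise resident pinned at its equilibrium: f_invader(E) exactly
  p0 <- glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027)
  ez <- estimate_invasion_rate(p0, resident = 1L, invader = 2L,
                               horizon = 50, dt = 1e-3, seed = 1)
  expect_equal(ez$lambda, 4 - 0.01 * 120, tolerance = 1e-9)
})

test_that("stochastic two-species classification reproduces the case table", {
  expect_identical(classify_stochastic_2sp(glv_scenario(1)$params)$case,
                   "C4i")
  # C1: negative growth at the origin for both species
  pc1 <- glv_params_2sp(-1, -1, 1, -0.1, -0.1, 1, tau = diag(2) * 0.05)
  v1 <- classify_stochastic_2sp(pc1)
  expect_identical(v1$case, "C1")
  expect_false(v1$persistent)
  # C2ii: species 1 viable alone, species 2 not even with the resident
  pc2 <- glv_params_2sp(1, -0.5, 1, -0.1, -0.5, 1, tau = diag(2) * 0.1)
  v2 <- classify_stochastic_2sp(pc2)
  expect_identical(v2$case, "C2ii")
  expect_match(v2$outcome, "species 2")
  # marginal guard: a decisive rate at exactly zero
  pm <- glv_params_2sp(0.02, 1, 1, -0.1, -0.1, 1,
                       tau = matrix(c(0.2, 0, 0, 0.1), 2, 2))
  expect_identical(classify_stochastic_2sp(pm)$case, "marginal")
  # refusals
  pmut <- glv_params_2sp(1, 1, 1, 0.5, 0.5, 1, tau = diag(2) * 0.1)
  expect_error(classify_stochastic_2sp(pmut), "mutualistic")
  expect_error(classify_stochastic_2sp(random_glv(3, seed = 1)), "2")
})

test_that("small-noise stochastic verdicts agree with the deterministic ones", {
  for (seed in 1:8) {
    p <- random_glv(2, interaction_type = "competitive",
                    noise_scale = 1e-4, seed = seed)
    det <- classify_deterministic(p)
    v <- classify_stochastic_2sp(p)
    if (det$verdict == "persistent" && v$case != "marginal") {
      expect_true(v$persistent,
                  label = sprintf("seed %d stochastic persistence", seed))
    }
  }
})
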