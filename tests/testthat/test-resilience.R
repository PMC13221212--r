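test_that("return-rate curves reduce to the decay rate in the scalar case", {
  # Gamma = 0, Theta = 0, A = [a]: W = u^2 e^{2at}, both curves constant -a
  ls <- linearized_system(1, 0, matrix(-0.8), matrix(0), "test")
  mp <- moment_path(ls, u = 3, horizon = 4, n_out = 81)
  ins <- return_rate_instantaneous(mp)
  ave <- return_rate_average(mp)
  expect_equal(ins$rate, rep(0.8, 81), tolerance = 1e-8)
  expect_equal(ave$rate, rep(0.8, 81), tolerance = 1e-8)
  expect_identical(ave$rate[1], ins$rate[1])
  expect_true(is.na(return_time(mp)))  # monotone W never turns around
})

test_that("convergence rates from the reference tables match the reference values", {
  ref <- c(1.2635, 1.2539, 2.3488, 2.3307)
  for (k in 1:4) {
    rc <- convergence_rate(stability_matrix(table_linsys(k)))
    expect_lt(abs(rc - ref[k]), 5e-4)
  }
  # zero noise: half the top Kronecker-sum eigenvalue, sign flipped
  ls0 <- table_linsys(1)
  ls0$B_list <- list(diag(0, 2), diag(0, 2))
  rc0 <- convergence_rate(stability_matrix(ls0))
  expect_equal(rc0, -max(Re(eigen(ls0$A, only.values = TRUE)$values)),
               tolerance = 1e-10)
})

test_that("zero-noise resilience collapses to the deterministic rates", {
  # R_c = R_inf = -max Re lambda(A) for random Hurwitz systems
  for (cfg in list(c(2, 201), c(3, 301))) {
    ls <- random_hurwitz_linsys(cfg[1], seed = cfg[2])
    rate <- -max(Re(eigen(ls$A, only.values = TRUE)$values))
    op <- stability_matrix(ls)
    expect_equal(convergence_rate(op), rate, tolerance = 1e-6)
    u <- slow_eigvec(ls$A)
    mp <- moment_path(ls, u = u, horizon = 6 / rate, n_out = 201)
    r_tail <- asymptotic_resilience(mp, estimator = "tail-decay")
    r_ave <- asymptotic_resilience(mp, estimator = "average-at-horizon")
    expect_equal(as.numeric(r_tail), rate, tolerance = 1e-6)
    expect_equal(as.numeric(r_ave), rate, tolerance = 1e-6)
  }
})

test_that("noisy systems plateau: the average rate decays toward zero", {
  ls <- table_linsys(1)
  mp <- moment_path(ls, u = c(10, 15), horizon = 15, n_out = 301)
  ave <- return_rate_average(mp)
  rc <- convergence_rate(stability_matrix(ls))
  r5 <- ave$rate[which.min(abs(ave$time - 5))]
  r15 <- ave$rate[301]
  expect_gt(r5, r15)        # decaying toward 0 once W plateaus
  expect_lt(r15, rc)        # inside the (R_inf, R_c) gap
  expect_gt(r15, 0)
  # the horizon and estimator are recorded with the value
  ri <- asymptotic_resilience(mp, horizon = 10)
  expect_identical(attr(ri, "estimator"), "average-at-horizon")
  expect_identical(attr(ri, "horizon"), 10)
  expect_error(asymptotic_resilience(mp, horizon = 99), "beyond")
})

test_that("return times react to noise as the moment dynamics dictate", {
  rts <- vapply(1:4, function(k) {
    mp <- moment_path(table_linsys(k), u = c(10, 15), horizon = 15,
                      n_out = 3001)
    return_time(mp)
  }, numeric(1))
  # strong interaction: the five-fold noise increase shortens the return time
  expect_false(is.na(rts[1]) || is.na(rts[2]))
  expect_gt(rts[1], rts[2])
  # weak interaction: W(t) relaxes into its plateau from above without a
  # minimum, so no zero crossing of the instantaneous rate exists
  expect_true(is.na(rts[3]) && is.na(rts[4]))
})

test_that("spectral perturbation by the noise term is bounded", {
  for (k in c(1L, 2L)) {
    ls <- table_linsys(k)
    op <- stability_matrix(ls)
    ls0 <- ls
    ls0$B_list <- list(diag(0, 2), diag(0, 2))
    op0 <- stability_matrix(ls0)
    noise_norm <- norm(sglv:::kron_noise(ls), "2")
    expect_lte(abs(convergence_rate(op) - convergence_rate(op0)),
               noise_norm)
  }
})

test_that("the end-to-end report gates on persistence and collects all parts", {
  s <- glv_scenario(1)
  rep <- resilience(s$params, u = s$pulse, m = s$ref_mean)
  expect_s3_class(rep, "resilience_report")
  expect_equal(rep$curves$W[1], 325)  # |u|^2 = 10^2 + 15^2
  expect_lt(abs(rep$R_c - 1.2635), 5e-4)
  g <- glance(rep)
  expect_identical(g$m_provenance, "supplied")
  expect_equal(g$return_time, 2.4234, tolerance = 1e-3)
  td <- tidy(rep)
  expect_setequal(unique(td$measure), c("R_ins", "R_ave"))

  # a non-persistent community is refused with an explanatory error
  pc1 <- glv_params_2sp(-1, -1, 1, -0.1, -0.1, 1, tau = diag(2) * 0.05)
  expect_error(resilience(pc1, u = c(1, 1)), "not .*persistent")
})

test_that("reports serialize and plot", {
  s <- glv_scenario(3)
  rep <- resilience(s$params, u = s$pulse, m = s$ref_mean)
  prefix <- withr::local_tempfile()
  paths <- write_report(rep, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".json", "_curves.csv")))))
  rec <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(rec$R_c, rep$R_c, tolerance = 1e-10)
  expect_null(rec$return_time)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
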