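new_trajectory <- function(times, states, scheme, dt, seed, params) {
  n <- ncol(states)
  df <- as.data.frame(states)
  names(df) <- paste0("X", seq_len(n))
  out <- tibble(time = times)
  out <- as_tibble(cbind(out, df))
  structure(
    out,
    scheme = scheme, dt = dt, seed = seed, params = params,
    class = c("sglv_trajectory", class(out))
  )
}

traj_states <- function(traj) {
  as.matrix(traj[, grep("^X[0-9]+$", names(traj)), drop = FALSE])
}

#' Simulate the stochastic generalized Lotka-Volterra model
#'
#' Integrates the SgLV by Euler-Maruyama on the log scale,
#' \deqn{d\log X_i = \Big(f_i(X) - \tfrac12\sum_j \tau_{ij}^2\Big)dt
#'       + \sum_j \tau_{ij} dW_j,}
#' where \eqn{f_i(X) = \alpha_i + \sum_j B_{ij}X_j}. The Ito correction makes
#' the noise part of the step exact in distribution, and exponentiating back
#' keeps every abundance strictly positive: the scheme cannot produce the
#' negative excursions that naive Euler on \eqn{X} suffers. All species share
#' the same N-dimensional Brownian increment each step, loaded through
#' \eqn{\Gamma}.
#'
#' @param params A [glv_params] object.
#' @param x0 Strictly positive initial abundances.
#' @param horizon Total simulated time.
#' @param dt Step size (default `1e-3` time units).
#' @param seed Optional integer seed; identical seeds give bitwise-identical
#'   paths.
#' @param thin Record every `thin`-th step (step 0 is always recorded).
#' @param cap Blow-up guard: simulation aborts if any abundance exceeds `cap`.
#'   Defaults to \eqn{10^{12}} times the largest single-species carrying
#'   capacity \eqn{\alpha_i/|B_{ii}|} (mutualistic parameter sets can diverge
#'   in finite time; the cap turns that into a clean error).
#' @return A tibble of class `sglv_trajectory` with columns `time`,
#'   `X1`, ..., `XN` and attributes `scheme`, `dt`, `seed`, `params`.
#' @examples
#' s <- glv_scenario(1)
#' tr <- simulate_sglv(s$params, x0 = c(40, 130), horizon = 10, seed = 1)
#' stationary_mean(tr, burn_in = 1)
#' @export
simulate_sglv <- function(params, x0, horizon, dt = 1e-3, seed = NULL,
                          thin = 1L, cap = NULL) {
  stopifnot(inherits(params, "glv_params"))
  x0 <- as.numeric(x0)
  if (length(x0) != params$n) abort("`x0` must have one entry per species.")
  if (any(x0 <= 0)) abort("`x0` must be strictly positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (horizon < dt) abort("`horizon` must be at least one step `dt`.")
  if (is.null(cap)) {
    K <- params$alpha / -diag(params$interaction)
    K <- K[K > 0]
    cap <- 1e12 * max(c(K, x0))
  }
  nsteps <- floor(horizon / dt + 1e-9)
  thin <- max(1L, as.integer(thin))
  if (!is.null(seed)) set.seed(seed)
  states <- sim_glv_em_cpp(params$alpha, params$interaction, params$tau,
                           x0, dt, nsteps, thin, cap)
  times <- seq(0, by = dt * thin, length.out = nrow(states))
  new_trajectory(times, states, "log-euler-maruyama", dt, seed, params)
}

#' Simulate the deterministic gLV system
#'
#' Adaptive Runge-Kutta integration of \eqn{dX/dt = h(X)} with
#' \eqn{h_i(X) = X_i(\alpha_i + \sum_j B_{ij}X_j)}. Components that start at
#' exactly zero stay at zero (boundary faces are invariant).
#'
#' @inheritParams simulate_sglv
#' @param x0 Nonnegative initial abundances.
#' @param n_out Number of output rows on a uniform grid.
#' @return An `sglv_trajectory` tibble with scheme `"deterministic-rk"`.
#' @export
simulate_glv <- function(params, x0, horizon, n_out = 1001L) {
  stopifnot(inherits(params, "glv_params"))
  x0 <- as.numeric(x0)
  if (length(x0) != params$n) abort("`x0` must have one entry per species.")
  if (any(x0 < 0)) abort("`x0` must be nonnegative.")
  zero <- x0 == 0
  times <- seq(0, horizon, length.out = n_out)
  rhs <- function(t, y, p) {
    dy <- glv_drift(params, y)
    dy[zero] <- 0
    list(dy)
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0) {
    abort("deterministic integration failed; see deSolve diagnostics.")
  }
  new_trajectory(sol[, 1L], sol[, -1L, drop = FALSE], "deterministic-rk",
                 diff(times)[1L], NULL, params)
}

#' Ergodic estimate of the stationary mean
#'
#' For a strongly stochastically persistent community the time average
#' \eqn{\frac1t\int_0^t X_i(s)\,ds} converges to the mean \eqn{m_i} of the
#' unique stationary distribution \eqn{\pi^*}. This estimator discards a
#' burn-in, then takes the trapezoidal time average of each component; the
#' Monte-Carlo standard error uses batch means (the retained window is cut
#' into `n_batches` equal blocks whose means are treated as approximately
#' independent, which absorbs the autocorrelation of the path).
#'
#' @param traj An `sglv_trajectory`.
#' @param burn_in Initial time span to discard; defaults to 10% of the
#'   horizon.
#' @param n_batches Number of batches for the standard error (default 50).
#' @return A tibble of class `stationary_estimate` with columns `species`,
#'   `mean`, `mc_se`, and attributes `burn_in` and `horizon`.
#' @export
stationary_mean <- function(traj, burn_in = NULL, n_batches = 50L) {
  stopifnot(inherits(traj, "sglv_trajectory"))
  horizon <- max(traj$time)
  if (is.null(burn_in)) burn_in <- 0.1 * horizon
  if (burn_in >= horizon) abort("`burn_in` must be smaller than the horizon.")
  keep <- traj$time >= burn_in
  if (sum(keep) < 2L * n_batches) {
    abort("trajectory too short after burn-in for the requested batch count.")
  }
  tt <- traj$time[keep]
  xx <- traj_states(traj)[keep, , drop = FALSE]
  m <- unname(apply(xx, 2L, function(v) trapz_mean(tt, v)))
  idx <- cut(seq_along(tt), breaks = n_batches, labels = FALSE)
  bm <- vapply(seq_len(ncol(xx)), function(j) {
    means <- vapply(split(seq_along(tt), idx), function(ii) {
      trapz_mean(tt[ii], xx[ii, j])
    }, numeric(1))
    sd(means) / sqrt(length(means))
  }, numeric(1))
  out <- tibble(species = seq_along(m), mean = m, mc_se = bm)
  structure(out, burn_in = burn_in, horizon = horizon,
            class = c("stationary_estimate", class(out)))
}

# time-weighted trapezoidal mean of v over t
trapz_mean <- function(t, v) {
  if (length(t) < 2L) return(v[1L])
  dt <- diff(t)
  sum((v[-1L] + v[-length(v)]) / 2 * dt) / (t[length(t)] - t[1L])
}

#' Apply a pulse perturbation
#'
#' A pulse displaces the community state by `u` in abundance space at a
#' reference time; the perturbed state must remain strictly positive.
#'
#' @param state Strictly positive abundance vector.
#' @param u Displacement vector of the same length.
#' @return `state + u`.
#' @examples
#' apply_pulse(c(38.7, 135.4), c(10, 15))
#' @export
apply_pulse <- function(state, u) {
  state <- as.numeric(state)
  u <- as.numeric(u)
  if (length(state) != length(u)) abort("`state` and `u` lengths differ.")
  if (!all(is.finite(u))) abort("`u` must be finite.")
  out <- state + u
  if (any(out <= 0)) {
    abort("infeasible pulse: the perturbed state has a nonpositive component.")
  }
  out
}

#' @export
print.sglv_trajectory <- function(x, ...) {
  cat(sprintf("<sglv_trajectory> scheme = %s, dt = %g, %d rows%s\n",
              attr(x, "scheme"), attr(x, "dt"), nrow(x),
              if (!is.null(attr(x, "seed"))) {
                sprintf(", seed = %d", attr(x, "seed"))
              } else ""))
  NextMethod()
}
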