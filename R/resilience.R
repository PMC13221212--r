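#' Instantaneous return rate
#'
#' \deqn{\mathcal{R}^{ins}_t = -\frac{d}{dt}\ln W(t)^{1/2}
#'       = -\tfrac12\, W'(t)/W(t),}
#' computed from the analytic ODE right-hand side stored on the moment path
#' (never from finite differences of the W grid: the zero crossing defines
#' the return time and needs sub-grid accuracy).
#'
#' @param path A [moment_path()] result.
#' @return A tibble with columns `time` and `rate`.
#' @export
return_rate_instantaneous <- function(path) {
  stopifnot(inherits(path, "moment_path"))
  if (any(path$W <= 0)) {
    abort("W(t) reached zero; the return-rate curve is singular.")
  }
  tibble(time = path$time, rate = -0.5 * path$dW / path$W)
}

#' Average return rate
#'
#' \deqn{\mathcal{R}^{ave}_t = -\frac{\ln W(t)^{1/2} - \ln W(0)^{1/2}}{t},}
#' the mean exponential rate at which the squared distance to the stationary
#' state has decayed over \eqn{[0, t]}. At \eqn{t = 0} the curve is defined
#' by continuous extension to \eqn{\mathcal{R}^{ins}_0}.
#'
#' @param path A [moment_path()] result.
#' @return A tibble with columns `time` and `rate`.
#' @export
return_rate_average <- function(path) {
  stopifnot(inherits(path, "moment_path"))
  if (path$W[1L] <= 0 || any(path$W <= 0)) {
    abort("W must be positive on the whole grid.")
  }
  rate <- -(log(path$W) - log(path$W[1L])) / (2 * path$time)
  rate[path$time == 0] <- -0.5 * path$dW[1L] / path$W[1L]
  tibble(time = path$time, rate = rate)
}

#' Convergence rate
#'
#' \eqn{\mathcal{R}_c = -\tfrac12\,\alpha(S)}, minus half the spectral
#' abscissa of the mean-square stability matrix: the slowest exponential rate
#' at which any entry of the second-moment matrix approaches its stationary
#' value. Positive iff the stationary second moment is mean-square stable.
#'
#' @param S_op A [stability_matrix()] result.
#' @return A scalar (per unit time).
#' @examples
#' s <- glv_scenario(1)
#' convergence_rate(stability_matrix(linearize(s$params, s$ref_mean)))
#' @export
convergence_rate <- function(S_op) {
  stopifnot(inherits(S_op, "stability_operator"))
  -0.5 * S_op$spectral_abscissa
}

#' Asymptotic resilience
#'
#' \eqn{\mathcal{R}_\infty = \lim_{t\to\infty} \mathcal{R}^{ave}_t}. With
#' noise the literal limit is zero whenever W plateaus at a positive
#' stationary value, so a finite evaluation is required and is recorded with
#' the result. Two estimators are provided:
#' \describe{
#'   \item{`"average-at-horizon"`}{evaluates \eqn{\mathcal{R}^{ave}} at the
#'     configured horizon (the default; the horizon defaults to the end of
#'     the path).}
#'   \item{`"tail-decay"`}{fits the exponential decay rate of
#'     \eqn{W(t) - W_\infty} on the tail of the window and reports half that
#'     rate (\eqn{W_\infty} from [stationary_moments()]; at zero noise
#'     \eqn{W_\infty = 0} and the estimator recovers \eqn{\mathcal{R}_c}).}
#' }
#'
#' @param path A [moment_path()] result.
#' @param estimator `"average-at-horizon"` or `"tail-decay"`.
#' @param horizon Evaluation time; must not exceed the path window. Defaults
#'   to the end of the path.
#' @param tail_frac Fraction of the window used by the tail fit.
#' @return A scalar with attributes `estimator` and `horizon`.
#' @export
asymptotic_resilience <- function(path,
                                  estimator = c("average-at-horizon",
                                                "tail-decay"),
                                  horizon = NULL, tail_frac = 0.3) {
  stopifnot(inherits(path, "moment_path"))
  estimator <- match.arg(estimator)
  if (is.null(horizon)) horizon <- max(path$time)
  if (horizon > max(path$time) + 1e-9) {
    abort("`horizon` lies beyond the computed moment path.")
  }
  if (estimator == "average-at-horizon") {
    ave <- return_rate_average(path)
    k <- which.min(abs(ave$time - horizon))
    val <- ave$rate[k]
  } else {
    sm <- stationary_moments(attr(path, "linsys"))
    W_inf <- if (sm$stable) sm$W_inf else 0
    keep <- path$time >= (1 - tail_frac) * horizon & path$time <= horizon &
      (path$W - W_inf) > 0
    if (sum(keep) < 5L) {
      abort("tail of W(t) is too close to its plateau for a decay fit.")
    }
    fit <- lm(log(path$W[keep] - W_inf) ~ path$time[keep])
    val <- -coef(fit)[[2L]] / 2
  }
  structure(val, estimator = estimator, horizon = horizon)
}

#' Return time after a pulse
#'
#' The first time the instantaneous return rate crosses zero, i.e. the first
#' root of \eqn{W'(t)}: the moment at which the mean squared distance to the
#' stationary state stops shrinking. The root is bracketed on the output grid
#' and then located by root finding on the analytic \eqn{W'} expression, so
#' its accuracy is not limited by the grid. Returns `NA` when W decreases
#' monotonically over the whole window (no crossing).
#'
#' @param path A [moment_path()] result.
#' @return The crossing time, or `NA_real_` if none occurs in the window.
#' @export
return_time <- function(path) {
  stopifnot(inherits(path, "moment_path"))
  dW <- path$dW
  k <- which(dW[-length(dW)] <= 0 & dW[-1L] > 0)
  # reject crossings whose upswing is at the integrator noise floor: when W
  # approaches its plateau from above, roundoff in Z produces sign flips in
  # dW at ~atol scale that are not genuine minima of W
  floor_dW <- 1e-8 * max(abs(dW))
  k <- k[vapply(k, function(kk) {
    any(dW[seq(kk + 1L, length(dW))] > floor_dW)
  }, logical(1))]
  if (length(k) == 0L) return(NA_real_)
  k <- k[1L]
  if (dW[k] == 0) return(path$time[k])
  uniroot(function(t) wprime_at(path, t),
          lower = path$time[k], upper = path$time[k + 1L],
          f.lower = dW[k], f.upper = dW[k + 1L],
          tol = 1e-10)$root
}

#' Pulse-perturbation resilience analysis of an SgLV community
#'
#' Runs the full four-step pipeline: (1) obtain the stationary mean m (either
#' supplied or estimated by long-run simulation), (2) linearize the SgLV at
#' the stationary distribution, (3) propagate the first and second moments of
#' the deviation through the Kronecker-vectorized ODE systems, and (4) report
#' the four resilience measures and the return time for a pulse perturbation
#' `u`.
#'
#' Communities whose stochastic classification is not persistent are refused
#' (the stationary distribution the linearization needs does not exist);
#' pass `gate = FALSE` to skip the check for systems you know converge.
#'
#' @param params A [glv_params] object.
#' @param u Pulse displacement vector.
#' @param m Optional stationary mean. When missing, it is estimated by
#'   simulation with settings from `stationary` (a list with elements
#'   `horizon`, `dt`, `burn_in`, `seed`, `x0`).
#' @param horizon Moment-path window (time units).
#' @param n_out Output grid size for the curves.
#' @param rinf_estimator,rinf_horizon Passed to [asymptotic_resilience()];
#'   the default horizon is \eqn{5/\mathcal{R}_c} (five times the slowest
#'   mean-square relaxation timescale), capped at the path window.
#' @param gate Refuse non-persistent communities (default `TRUE`).
#' @param stationary Simulation settings used only when `m` is missing.
#' @return A list of class `resilience_report`: `curves` (tibble with `time`,
#'   `R_ins`, `R_ave`, `W`), `R_c`, `R_inf`, `return_time`, `pulse`,
#'   `linsys`, `S_op`, `stationary_estimate` (when simulated), `verdict`.
#' @examples
#' s <- glv_scenario(1)
#' rep <- resilience(s$params, u = s$pulse, m = s$ref_mean)
#' glance(rep)
#' @export
resilience <- function(params, u, m = NULL, horizon = 15, n_out = 3001L,
                       rinf_estimator = "average-at-horizon",
                       rinf_horizon = NULL, gate = TRUE,
                       stationary = list()) {
  stopifnot(inherits(params, "glv_params"))
  verdict <- NULL
  if (gate) {
    if (params$n == 2L && any(params$tau != 0)) {
      verdict <- classify_stochastic_2sp(params)
      if (!isTRUE(verdict$persistent)) {
        abort(sprintf(
          "community is not stochastically persistent (case %s: %s); no stationary distribution to linearize at.",
          verdict$case, verdict$outcome))
      }
    } else {
      det <- classify_deterministic(params)
      if (det$verdict != "persistent") {
        abort(sprintf("community is not persistent (deterministic verdict: %s).",
                      det$verdict))
      }
    }
  }
  est <- NULL
  if (is.null(m)) {
    cfg <- modifyList(list(horizon = 5000, dt = 1e-3, burn_in = NULL,
                           seed = NULL, x0 = NULL), stationary)
    x0 <- cfg$x0
    if (is.null(x0)) {
      x0 <- tryCatch(solve(params$interaction, -params$alpha),
                     error = function(e) NULL)
      if (is.null(x0) || any(x0 <= 0)) x0 <- rep(1, params$n)
    }
    traj <- simulate_sglv(params, x0 = x0, horizon = cfg$horizon,
                          dt = cfg$dt, seed = cfg$seed)
    est <- stationary_mean(traj, burn_in = cfg$burn_in)
    m <- est$mean
    linsys <- linearize(params, m, provenance = "simulated")
  } else {
    linsys <- linearize(params, m, provenance = "supplied")
  }
  state <- apply_pulse(linsys$m, u)  # positivity guard on the pulsed state
  path <- moment_path(linsys, u = u, horizon = horizon, n_out = n_out)
  S_op <- attr(path, "S_op")
  R_c <- convergence_rate(S_op)
  if (is.null(rinf_horizon)) rinf_horizon <- min(5 / R_c, max(path$time))
  R_inf <- asymptotic_resilience(path, estimator = rinf_estimator,
                                 horizon = rinf_horizon)
  ins <- return_rate_instantaneous(path)
  ave <- return_rate_average(path)
  structure(
    list(
      curves = tibble(time = path$time, R_ins = ins$rate, R_ave = ave$rate,
                      W = path$W),
      R_c = R_c,
      R_inf = R_inf,
      return_time = return_time(path),
      pulse = u,
      pulsed_state = state,
      linsys = linsys,
      S_op = S_op,
      path = path,
      stationary_estimate = est,
      verdict = verdict,
      label = params$label
    ),
    class = "resilience_report"
  )
}

#' @export
print.resilience_report <- function(x, ...) {
  cat(sprintf("<resilience_report>%s\n",
              if (!is.null(x$label)) paste0(" ", x$label) else ""))
  cat(sprintf("  pulse u = (%s), m from %s\n",
              paste(signif(x$pulse, 4), collapse = ", "),
              x$linsys$provenance))
  cat(sprintf("  convergence rate R_c    = %.4f per unit time\n", x$R_c))
  cat(sprintf("  asymptotic resilience   = %.4g (%s at t = %.3g)\n",
              as.numeric(x$R_inf), attr(x$R_inf, "estimator"),
              attr(x$R_inf, "horizon")))
  cat(sprintf("  return time (R_ins = 0) = %s\n",
              if (is.na(x$return_time)) "none within window"
              else sprintf("%.3f", x$return_time)))
  invisible(x)
}
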