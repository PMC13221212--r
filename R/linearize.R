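#' Assemble a linearized system from explicit coefficients
#'
#' Builds a `linearized_system` directly from a stationary mean, drift offset,
#' community matrix and noise intensity matrix — for example from a published
#' coefficient table — without re-deriving them from a parameter set.
#'
#' @param m Stationary mean vector.
#' @param Theta Drift offset vector.
#' @param A Community matrix (row i acts on the deviation in species i's
#'   drift).
#' @param tau Noise intensity matrix; the diagonal diffusion factor \eqn{B_i}
#'   is built from its column i.
#' @param provenance Free-text source tag.
#' @param label Optional label.
#' @return A `linearized_system`.
#' @export
linearized_system <- function(m, Theta, A, tau, provenance = "supplied",
                              label = NULL) {
  m <- as.numeric(m)
  n <- length(m)
  stopifnot(length(Theta) == n, all(dim(as.matrix(A)) == n),
            all(dim(as.matrix(tau)) == n))
  new_linearized_system(m, as.numeric(Theta), as.matrix(A), as.matrix(tau),
                        provenance, label)
}

new_linearized_system <- function(m, Theta, A, tau, provenance, label = NULL) {
  n <- length(m)
  B_list <- lapply(seq_len(n), function(i) diag(tau[, i], n))
  structure(
    list(m = m, Theta = Theta, A = A, B_list = B_list, tau = tau,
         provenance = provenance, label = label),
    class = "linearized_system"
  )
}

#' Statistical linearization of the SgLV at its stationary distribution
#'
#' Replaces the nonlinear drift \eqn{h_i(X) = X_i(\alpha_i + \sum_j B_{ij}X_j)}
#' by its tangent at the stationary mean \eqn{m = E_{\pi^*}X}, giving the
#' linear SDE
#' \deqn{d\tilde X = \big(\Theta + A(\tilde X - m)\big)dt
#'       + \sum_i B_i \tilde X\, dW_i,}
#' with drift offset \eqn{\Theta_i = h_i(m)}, community matrix
#' \eqn{A = \partial h/\partial x |_m}:
#' \deqn{\gamma_{ii} = \alpha_i + \sum_k B_{ik} m_k + B_{ii} m_i, \qquad
#'       \gamma_{ij} = B_{ij} m_i \ (i \neq j),}
#' and diagonal diffusion factors \eqn{B_i = \mathrm{diag}(\tau_{1i}, \ldots,
#' \tau_{Ni})} built from column i of \eqn{\Gamma} (one factor per Brownian
#' component). Note the diagonal carries the extra \eqn{B_{ii} m_i} term from
#' differentiating the quadratic self-interaction.
#'
#' @param params A [glv_params] object.
#' @param m Strictly positive stationary mean (from [stationary_mean()], a
#'   reference table, or the deterministic equilibrium).
#' @param provenance Recorded source of `m` (`"supplied"`, `"simulated"`,
#'   `"deterministic-E*"`).
#' @return An object of class `linearized_system` with fields `m`, `Theta`,
#'   `A`, `B_list`, `tau`, `provenance`.
#' @examples
#' s <- glv_scenario(1)
#' linearize(s$params, m = s$ref_mean)
#' @export
linearize <- function(params, m, provenance = "supplied") {
  stopifnot(inherits(params, "glv_params"))
  m <- as.numeric(m)
  if (length(m) != params$n) abort("`m` must have one entry per species.")
  if (any(m <= 0)) abort("`m` must be strictly positive.")
  B <- params$interaction
  Theta <- as.numeric(m * (params$alpha + B %*% m))
  A <- m * B
  diag(A) <- params$alpha + as.numeric(B %*% m) + diag(B) * m
  new_linearized_system(m, Theta, A, params$tau, provenance, params$label)
}

#' Deterministic linearization at the interior equilibrium
#'
#' Evaluates the same Jacobian construction at the interior equilibrium
#' \eqn{E^*} (the solution of \eqn{\alpha + B x = 0} in the open orthant).
#' Since \eqn{h(E^*) = 0} the offset vanishes, and the diffusion factors are
#' zeroed: this is the classical community-matrix linearization of the
#' deterministic model.
#'
#' @param params A [glv_params] object.
#' @return A `linearized_system` with `Theta = 0`, zero noise, and provenance
#'   `"deterministic-E*"`.
#' @export
linearize_deterministic <- function(params) {
  stopifnot(inherits(params, "glv_params"))
  estar <- tryCatch(solve(params$interaction, -params$alpha),
                    error = function(e) NULL)
  if (is.null(estar) || any(estar <= 0)) {
    abort("no positive interior equilibrium exists for these parameters.")
  }
  zero_tau <- matrix(0, params$n, params$n)
  ls <- linearize(glv_params(params$alpha, params$interaction, zero_tau,
                             label = params$label),
                  m = estar, provenance = "deterministic-E*")
  ls
}

#' Simulate the linearized SDE
#'
#' Euler-Maruyama integration of the linearized system in the original
#' coordinates,
#' \deqn{d\tilde X_i = \Big(\Theta_i + \sum_j \gamma_{ij}(\tilde X_j - m_j)
#'       \Big)dt + \tilde X_i \sum_j \tau_{ij} dW_j.}
#' The integrator consumes Brownian increments in exactly the same order as
#' [simulate_sglv()], so running both with the same seed, step and grid drives
#' them with identical noise — the two paths are couplable for overlay plots
#' of the recovery after a pulse.
#'
#' @param linsys A `linearized_system`.
#' @param y0 Initial state in original (abundance) coordinates.
#' @param horizon,dt,seed,thin As in [simulate_sglv()].
#' @return An `sglv_trajectory` tibble with scheme `"linear-euler-maruyama"`.
#' @export
simulate_linearized <- function(linsys, y0, horizon, dt = 1e-3, seed = NULL,
                                thin = 1L) {
  stopifnot(inherits(linsys, "linearized_system"))
  y0 <- as.numeric(y0)
  if (length(y0) != length(linsys$m)) abort("`y0` has the wrong length.")
  if (dt <= 0) abort("`dt` must be positive.")
  nsteps <- floor(horizon / dt + 1e-9)
  thin <- max(1L, as.integer(thin))
  if (!is.null(seed)) set.seed(seed)
  states <- sim_linear_em_cpp(linsys$A, linsys$Theta, linsys$m, linsys$tau,
                              y0, dt, nsteps, thin)
  times <- seq(0, by = dt * thin, length.out = nrow(states))
  new_trajectory(times, states, "linear-euler-maruyama", dt, seed, NULL)
}

#' @export
print.linearized_system <- function(x, ...) {
  cat(sprintf("<linearized_system> %d species (m from %s)\n",
              length(x$m), x$provenance))
  cat("m:     ", paste(signif(x$m, 6), collapse = "  "), "\n")
  cat("Theta: ", paste(signif(x$Theta, 6), collapse = "  "), "\n")
  cat("A:\n")
  print(signif(x$A, 6))
  invisible(x)
}

#' @rdname tidy_sglv
#' @export
tidy.linearized_system <- function(x, ...) {
  n <- length(x$m)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  bind_rows(
    tibble(term = paste0("m", seq_len(n)), estimate = x$m),
    tibble(term = paste0("Theta", seq_len(n)), estimate = x$Theta),
    tibble(term = paste0("gamma", grid$i, grid$j),
           estimate = x$A[cbind(grid$i, grid$j)])
  )
}
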