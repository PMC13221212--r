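#' Mean-square stability matrix
#'
#' Assembles the \eqn{N^2 \times N^2} operator governing the vectorized second
#' moment \eqn{Z = \mathrm{vec}(P)} of the linearized SDE,
#' \deqn{S = I \otimes A + A \otimes I + \sum_{i=1}^N B_i \otimes B_i,}
#' in the column-stacking vec convention (entry \eqn{(i,j)} of P sits at
#' position \eqn{(j-1)N + i} of Z). The stationary second moment is globally
#' asymptotically stable iff the spectral abscissa \eqn{\alpha(S) < 0}; at
#' zero noise the spectrum of S is exactly the set of pairwise sums
#' \eqn{\lambda_i(A) + \lambda_j(A)}.
#'
#' @param linsys A `linearized_system`.
#' @return A list of class `stability_operator` with `S`, `eigenvalues`, and
#'   `spectral_abscissa`.
#' @examples
#' s <- glv_scenario(1)
#' op <- stability_matrix(linearize(s$params, s$ref_mean))
#' -op$spectral_abscissa / 2  # convergence rate
#' @export
stability_matrix <- function(linsys) {
  stopifnot(inherits(linsys, "linearized_system"))
  n <- length(linsys$m)
  A <- linsys$A
  S <- diag(n) %x% A + A %x% diag(n)
  for (Bi in linsys$B_list) S <- S + Bi %x% Bi
  ev <- eigen(S, only.values = TRUE)$values
  structure(
    list(S = S, eigenvalues = ev, spectral_abscissa = max(Re(ev))),
    class = "stability_operator"
  )
}

#' @export
print.stability_operator <- function(x, ...) {
  cat(sprintf("<stability_operator> %d x %d, spectral abscissa %.6g\n",
              nrow(x$S), ncol(x$S), x$spectral_abscissa))
  invisible(x)
}

# sum of B_i (x) B_i as one N^2 x N^2 matrix
kron_noise <- function(linsys) {
  n <- length(linsys$m)
  out <- matrix(0, n^2, n^2)
  for (Bi in linsys$B_list) out <- out + Bi %x% Bi
  out
}

# forcing T(M) = vec(Theta M' + M Theta') + (sum B_i (x) B_i) vec(M m' + m M' + m m')
moment_forcing <- function(linsys, M, BB = kron_noise(linsys)) {
  m <- linsys$m
  Theta <- linsys$Theta
  as.numeric(tcrossprod(Theta, M) + tcrossprod(M, Theta)) +
    as.numeric(BB %*% as.numeric(tcrossprod(M, m) + tcrossprod(m, M) +
                                   tcrossprod(m)))
}

#' Mean and second-moment paths after a pulse
#'
#' Propagates the first two moments of the deviation \eqn{Y = \tilde X - m}
#' of the linearized SDE after a pulse \eqn{u = Y(0)} through the coupled
#' linear ODE systems
#' \deqn{\dot M = A M + \Theta, \qquad
#'       \dot Z = S Z + T(t),}
#' with \eqn{M(0) = u}, \eqn{Z(0) = \mathrm{vec}(u u^T)}, and time-varying
#' forcing
#' \eqn{T(t) = \mathrm{vec}(\Theta M^T + M \Theta^T) + \big(\sum_i B_i \otimes
#' B_i\big)\mathrm{vec}(M m^T + m M^T + m m^T)}. The scalar distance
#' \eqn{W(t) = \sum_i E\,Y_i^2(t) = \mathrm{trace}\,P(t)} and its analytic
#' derivative (taken from the ODE right-hand side, never from finite
#' differences) are attached; every resilience measure is a functional of
#' this \eqn{W}.
#'
#' The joint (M, Z) system is integrated with a stiff solver at tight
#' tolerances (`rtol = 1e-10`, `atol = 1e-12`): the eigenvalue spread of S is
#' moderate but the zero crossings of \eqn{dW/dt} need sub-grid accuracy.
#'
#' @param linsys A `linearized_system`.
#' @param u Pulse displacement vector \eqn{Y(0)}.
#' @param horizon End of the time window.
#' @param n_out Number of uniformly spaced output times (grid starts at 0).
#' @return A tibble of class `moment_path` with columns `time`, `M1..MN`,
#'   `W`, `dW` and attributes `Z` (the full \eqn{N^2}-column matrix),
#'   `linsys`, `u`, `S_op` ([stability_matrix()] output).
#' @examples
#' s <- glv_scenario(1)
#' mp <- moment_path(linearize(s$params, s$ref_mean), u = c(10, 15),
#'                   horizon = 2, n_out = 201)
#' head(mp)
#' @export
moment_path <- function(linsys, u, horizon, n_out = 1001L) {
  stopifnot(inherits(linsys, "linearized_system"))
  n <- length(linsys$m)
  u <- as.numeric(u)
  if (length(u) != n) abort("`u` must have one entry per species.")
  S_op <- stability_matrix(linsys)
  BB <- kron_noise(linsys)
  A <- linsys$A
  Theta <- linsys$Theta
  S <- S_op$S
  rhs <- function(t, y, p) {
    M <- y[seq_len(n)]
    Z <- y[-seq_len(n)]
    dM <- as.numeric(A %*% M) + Theta
    dZ <- as.numeric(S %*% Z) + moment_forcing(linsys, M, BB)
    list(c(dM, dZ))
  }
  times <- seq(0, horizon, length.out = n_out)
  y0 <- c(u, as.numeric(tcrossprod(u)))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0) abort("moment ODE integration failed.")
  M <- sol[, 1L + seq_len(n), drop = FALSE]
  Z <- sol[, -c(1L, 1L + seq_len(n)), drop = FALSE]
  # symmetry of the reconstructed P is a numeric-integrity invariant
  asym <- vapply(seq_len(nrow(Z)), function(k) {
    P <- matrix(Z[k, ], n, n)
    max(abs(P - t(P)))
  }, numeric(1))
  scale <- pmax(abs(rowSums(Z[, (seq_len(n) - 1L) * n + seq_len(n),
                              drop = FALSE])), 1)
  if (max(asym / scale) > 1e-6) {
    abort("second-moment matrix lost symmetry beyond tolerance.")
  }
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  W <- rowSums(Z[, diag_idx, drop = FALSE])
  dW <- vapply(seq_len(nrow(Z)), function(k) {
    d <- rhs(times[k], sol[k, -1L], NULL)[[1L]]
    sum(d[n + diag_idx])
  }, numeric(1))
  df <- tibble(time = times)
  Mdf <- as.data.frame(M)
  names(Mdf) <- paste0("M", seq_len(n))
  out <- as_tibble(cbind(df, Mdf, W = W, dW = dW))
  structure(out, Z = Z, linsys = linsys, u = u, S_op = S_op,
            class = c("moment_path", class(out)))
}

#' Matrix-form second-moment propagation (independent cross-check)
#'
#' Integrates the covariance dynamics in matrix form,
#' \deqn{\dot P = A P + P A^T + \sum_i B_i P B_i^T + \Theta M^T + M \Theta^T
#'       + \sum_i B_i (M m^T + m M^T + m m^T) B_i^T,}
#' without any Kronecker vectorization. This is an independent code path from
#' [moment_path()] (which integrates \eqn{\dot Z = SZ + T}); the two must
#' agree to integrator tolerance and are compared in the package tests.
#'
#' @inheritParams moment_path
#' @return A tibble with columns `time`, `W` plus attribute `P` (list of
#'   covariance matrices).
#' @export
moment_path_matrix <- function(linsys, u, horizon, n_out = 1001L) {
  stopifnot(inherits(linsys, "linearized_system"))
  n <- length(linsys$m)
  u <- as.numeric(u)
  A <- linsys$A
  Theta <- linsys$Theta
  m <- linsys$m
  rhs <- function(t, y, p) {
    M <- y[seq_len(n)]
    P <- matrix(y[-seq_len(n)], n, n)
    dM <- as.numeric(A %*% M) + Theta
    G <- tcrossprod(M, m) + tcrossprod(m, M) + tcrossprod(m)
    dP <- A %*% P + P %*% t(A) + tcrossprod(Theta, M) + tcrossprod(M, Theta)
    for (Bi in linsys$B_list) {
      dP <- dP + Bi %*% P %*% t(Bi) + Bi %*% G %*% t(Bi)
    }
    list(c(dM, as.numeric(dP)))
  }
  times <- seq(0, horizon, length.out = n_out)
  y0 <- c(u, as.numeric(tcrossprod(u)))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0) abort("matrix moment ODE failed.")
  Pmat <- sol[, -c(1L, 1L + seq_len(n)), drop = FALSE]
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  tibble(time = sol[, 1L], W = rowSums(Pmat[, diag_idx, drop = FALSE]))
}

#' Stationary moments of the linearized SDE
#'
#' When A is Hurwitz the mean settles at \eqn{M_\infty = -A^{-1}\Theta}, and
#' when additionally \eqn{\alpha(S) < 0} the vectorized second moment settles
#' at \eqn{Z_\infty = -S^{-1} T(M_\infty)}.
#'
#' @param linsys A `linearized_system`.
#' @return A list with `M_inf`, `Z_inf`, `W_inf` (trace of the stationary P),
#'   and `stable` (logical: \eqn{\alpha(S) < 0}).
#' @export
stationary_moments <- function(linsys) {
  S_op <- stability_matrix(linsys)
  n <- length(linsys$m)
  M_inf <- as.numeric(solve(linsys$A, -linsys$Theta))
  stable <- S_op$spectral_abscissa < 0
  Z_inf <- if (stable) {
    as.numeric(solve(S_op$S, -moment_forcing(linsys, M_inf)))
  } else {
    rep(NA_real_, n^2)
  }
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  list(M_inf = M_inf, Z_inf = Z_inf, W_inf = sum(Z_inf[diag_idx]),
       stable = stable)
}

# analytic dW/dt at an off-grid time t, by re-integrating the joint system
# from the nearest stored grid state at or before t
wprime_at <- function(path, t) {
  times <- path$time
  n <- length(attr(path, "u"))
  linsys <- attr(path, "linsys")
  S <- attr(path, "S_op")$S
  BB <- kron_noise(linsys)
  k <- max(which(times <= t + 1e-12))
  y0 <- c(as.numeric(as.matrix(path[k, paste0("M", seq_len(n))])),
          attr(path, "Z")[k, ])
  rhs <- function(tt, y, p) {
    M <- y[seq_len(n)]
    Z <- y[-seq_len(n)]
    list(c(as.numeric(linsys$A %*% M) + linsys$Theta,
           as.numeric(S %*% Z) + moment_forcing(linsys, M, BB)))
  }
  if (t > times[k] + 1e-12) {
    sol <- deSolve::lsoda(y0, c(times[k], t), rhs, parms = NULL,
                          rtol = 1e-12, atol = 1e-13)
    y0 <- sol[nrow(sol), -1L]
  }
  d <- rhs(t, y0, NULL)[[1L]]
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  sum(d[n + diag_idx])
}
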