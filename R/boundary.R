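#' Enumerate equilibria of the deterministic gLV system
#'
#' For each subset S of species, the candidate equilibrium solves the linear
#' system \eqn{\alpha_S + B_{SS} x_S = 0} with the off-subset species at zero;
#' only strictly positive solutions on the subset are kept. The full-system
#' Jacobian spectrum is attached to each equilibrium. The origin is always an
#' equilibrium. Singular subsystems contribute no equilibrium and are recorded
#' in the `skipped` attribute.
#'
#' @param params A [glv_params] object.
#' @param max_species Guard on N (the enumeration is over \eqn{2^N} subsets).
#' @return A tibble with one row per equilibrium: `label` (`"origin"`,
#'   `"boundary"`, `"interior"`), `support` (list of species indices),
#'   `coords` (list), `eigenvalues` (list, complex), `max_re`, `stable`.
#' @examples
#' p <- glv_params_2sp(6, 4, 0.05, -0.03, -0.01, 0.027)
#' enumerate_equilibria(p)
#' @export
enumerate_equilibria <- function(params, max_species = 12L) {
  stopifnot(inherits(params, "glv_params"))
  n <- params$n
  if (n > max_species) {
    abort(sprintf("N = %d exceeds `max_species` = %d (2^N subsets).",
                  n, max_species))
  }
  B <- params$interaction
  alpha <- params$alpha
  rows <- list()
  skipped <- list()
  for (mask in 0:(2^n - 1L)) {
    supp <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    x <- numeric(n)
    if (length(supp) > 0L) {
      sol <- tryCatch(
        solve(B[supp, supp, drop = FALSE], -alpha[supp]),
        error = function(e) NULL
      )
      if (is.null(sol)) {
        skipped[[length(skipped) + 1L]] <- supp
        next
      }
      if (any(sol <= 0)) next
      x[supp] <- sol
    }
    J <- glv_jacobian(params, x)
    ev <- eigen(J, only.values = TRUE)$values
    label <- if (length(supp) == 0L) "origin"
             else if (length(supp) == n) "interior" else "boundary"
    rows[[length(rows) + 1L]] <- tibble(
      label = label,
      support = list(supp),
      coords = list(x),
      eigenvalues = list(ev),
      max_re = max(Re(ev)),
      stable = max(Re(ev)) <= 0
    )
  }
  out <- bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

# Jacobian of the drift h at x: J_ij = delta_ij f_i(x) + x_i B_ij
glv_jacobian <- function(params, x) {
  f <- glv_percapita(params, x)
  diag(f, params$n) + x * params$interaction
}

#' Deterministic persistence verdict
#'
#' The deterministic community persists when every equilibrium on the boundary
#' of the positive orthant is unstable (\eqn{\max_i \mathrm{Re}\,\lambda_i(E) >
#' 0} for each boundary equilibrium E), equivalently when the interior
#' equilibrium is locally stable. When a boundary equilibrium attracts (all
#' off-support eigendirections decay), the off-support species converge to zero
#' and their convergence rates are the per-capita growth rates
#' \eqn{f_i(E) < 0} there.
#'
#' @param params A [glv_params] object.
#' @param tol Marginality tolerance: any boundary equilibrium whose leading
#'   real part is within `tol` of zero yields the verdict `"marginal"` rather
#'   than a silent sign decision.
#' @return A list with `verdict` (`"persistent"`, `"extinction"`,
#'   `"marginal"`), `equilibria` (the [enumerate_equilibria()] table), and
#'   `attracting` (tibble of attracting boundary equilibria with the
#'   off-support convergence rates).
#' @export
classify_deterministic <- function(params, tol = 1e-6) {
  eq <- enumerate_equilibria(params)
  bdry <- eq[eq$label != "interior", , drop = FALSE]
  if (any(abs(bdry$max_re) < tol)) {
    return(list(verdict = "marginal", equilibria = eq,
                attracting = NULL))
  }
  if (all(bdry$max_re > 0)) {
    return(list(verdict = "persistent", equilibria = eq, attracting = NULL))
  }
  attracting <- list()
  for (k in seq_len(nrow(bdry))) {
    supp <- bdry$support[[k]]
    x <- bdry$coords[[k]]
    off <- setdiff(seq_len(params$n), supp)
    rates <- glv_percapita(params, x)[off]
    if (length(off) > 0L && all(rates < -tol)) {
      attracting[[length(attracting) + 1L]] <- tibble(
        label = bdry$label[k],
        support = list(supp),
        extinct = list(off),
        rates = list(rates)
      )
    }
  }
  list(verdict = "extinction", equilibria = eq,
       attracting = bind_rows(attracting))
}

#' Single-species stationary Gamma law on a boundary axis
#'
#' When only one species is present, the SgLV reduces to a logistic SDE
#' \eqn{dX = X(\alpha - b X)dt + X\sqrt{\sigma}\,dW'} with
#' \eqn{\sigma = \sum_j \tau_{j}^2} the species' own noise row sum of squares.
#' A stationary law on the open axis exists iff \eqn{\alpha - \sigma/2 > 0},
#' and it is
#' \deqn{\mathrm{Gamma}\Big(\mathrm{shape} = \frac{2\alpha}{\sigma} - 1,\;
#'       \mathrm{scale} = \frac{\sigma}{2b}\Big),}
#' with mean \eqn{(\alpha - \sigma/2)/b}. Otherwise the species on that axis
#' converges to zero. The scale always uses the resident species' own noise
#' row.
#'
#' @param alpha Intrinsic growth rate.
#' @param b_self Positive self-limitation coefficient (\eqn{|B_{ii}|}).
#' @param sigma_row The species' noise row sum of squares
#'   \eqn{\sum_j \tau_{ij}^2}; must be positive (zero diffusion on the axis is
#'   degenerate).
#' @return A list of class `gamma_law`: `shape`, `scale`, `mean`, `exists`.
#' @examples
#' boundary_gamma(6, 0.05, 0.01^2 + 0.015^2)
#' @export
boundary_gamma <- function(alpha, b_self, sigma_row) {
  if (b_self <= 0) abort("`b_self` must be positive.")
  if (sigma_row <= 0) {
    abort("`sigma_row` must be positive: no diffusion on this axis.")
  }
  exists <- alpha - sigma_row / 2 > 0
  shape <- 2 * alpha / sigma_row - 1
  scale <- sigma_row / (2 * b_self)
  structure(
    list(
      shape = if (exists) shape else NA_real_,
      scale = if (exists) scale else NA_real_,
      mean = if (exists) shape * scale else NA_real_,
      exists = exists
    ),
    class = "gamma_law"
  )
}

#' Analytic two-species invasion rates
#'
#' The boundary of the two-species positive orthant carries at most three
#' ergodic measures: the Dirac mass \eqn{\mu_0} at the origin and the two
#' single-species Gamma laws \eqn{\mu_1} (species 1 axis) and \eqn{\mu_2}
#' (species 2 axis). The Lyapunov exponent (invasion rate) of species i
#' against a measure \eqn{\mu} is the \eqn{\mu}-average of its per-capita
#' growth minus the Ito correction:
#' \deqn{\lambda_i(\mu) = \int f_i \, d\mu - \tfrac12\sum_j \tau_{ij}^2.}
#' For two species this is fully explicit. With positive self-limitation
#' coefficients \eqn{b_{11}, b_{22}} and signed \eqn{b_{12}, b_{21}}:
#' \itemize{
#'   \item \eqn{\lambda_i(\mu_0) = \alpha_i - \sigma_i/2};
#'   \item \eqn{\lambda_2(\mu_1) = \alpha_2 - \sigma_2/2 +
#'     (b_{21}/b_{11})(\alpha_1 - \sigma_1/2)} when \eqn{\mu_1} exists;
#'   \item \eqn{\lambda_1(\mu_2) = \alpha_1 - \sigma_1/2 +
#'     (b_{12}/b_{22})(\alpha_2 - \sigma_2/2)} when \eqn{\mu_2} exists;
#' }
#' where \eqn{\sigma_i = \sum_j \tau_{ij}^2}. On its own support every
#' exponent is exactly zero.
#'
#' @param params A two-species [glv_params] object.
#' @return A tibble with columns `measure` (`"mu0"`, `"mu1"`, `"mu2"`),
#'   `species`, `lambda`, `exists` (whether the boundary measure itself
#'   exists), `method = "analytic"`.
#' @export
lyapunov_2sp <- function(params) {
  stopifnot(inherits(params, "glv_params"))
  if (params$n != 2L) abort("analytic invasion rates require exactly 2 species.")
  B <- params$interaction
  a <- params$alpha
  sig <- rowSums(params$tau^2)
  lam0 <- a - sig / 2
  b11 <- -B[1, 1]; b22 <- -B[2, 2]
  mu1_exists <- lam0[1] > 0
  mu2_exists <- lam0[2] > 0
  rows <- list(
    tibble(measure = "mu0", species = 1L, lambda = lam0[1], exists = TRUE),
    tibble(measure = "mu0", species = 2L, lambda = lam0[2], exists = TRUE),
    tibble(measure = "mu1", species = 1L, lambda = 0, exists = mu1_exists),
    tibble(measure = "mu1", species = 2L,
           lambda = if (mu1_exists) lam0[2] + B[2, 1] / b11 * lam0[1]
                    else NA_real_,
           exists = mu1_exists),
    tibble(measure = "mu2", species = 2L, lambda = 0, exists = mu2_exists),
    tibble(measure = "mu2", species = 1L,
           lambda = if (mu2_exists) lam0[1] + B[1, 2] / b22 * lam0[2]
                    else NA_real_,
           exists = mu2_exists)
  )
  out <- bind_rows(rows)
  out$method <- "analytic"
  out
}

#' Monte-Carlo estimate of an invasion rate
#'
#' Estimates the Lyapunov exponent of an absent species against the boundary
#' ergodic measure of a resident subcommunity: the resident subsystem is
#' simulated with the invader clamped at zero, and the invader's per-capita
#' growth rate \eqn{f_i(X) - \frac12\sum_j\tau_{ij}^2} is time-averaged after
#' burn-in, with a batch-means standard error.
#'
#' @param params A [glv_params] object.
#' @param resident Integer indices of the resident support (may be empty:
#'   the invasion rate against the Dirac mass at the origin is returned
#'   exactly).
#' @param invader Index of the invading species (not in `resident`).
#' @param horizon,dt,seed Simulation settings for the resident subsystem.
#' @param burn_in Discarded initial span (default 10% of `horizon`).
#' @param n_batches Batch count for the standard error.
#' @return A list with `lambda`, `mc_se`, `method` (`"monte-carlo"` or
#'   `"exact"`), and `resident_means`.
#' @export
estimate_invasion_rate <- function(params, resident, invader,
                                   horizon = 2000, dt = 1e-3, seed = NULL,
                                   burn_in = NULL, n_batches = 50L) {
  stopifnot(inherits(params, "glv_params"))
  resident <- as.integer(resident)
  invader <- as.integer(invader)
  if (invader %in% resident) abort("`invader` must not be in `resident`.")
  sig_i <- sum(params$tau[invader, ]^2)
  if (length(resident) == 0L) {
    return(list(lambda = params$alpha[invader] - sig_i / 2, mc_se = 0,
                method = "exact", resident_means = numeric(0)))
  }
  # the resident marginal law depends on the full noise rows only through
  # their covariance; re-factor it into a square loading matrix of resident size
  sig_sub <- tcrossprod(params$tau[resident, , drop = FALSE])
  es <- eigen(sig_sub, symmetric = TRUE)
  tau_sub <- es$vectors %*% diag(sqrt(pmax(es$values, 0)),
                                 length(resident))
  sub <- glv_params(
    alpha = params$alpha[resident],
    interaction = params$interaction[resident, resident, drop = FALSE],
    noise = tau_sub,
    label = "resident subsystem"
  )
  x0 <- sub$alpha / -diag(sub$interaction)
  x0[x0 <= 0] <- 1
  traj <- simulate_sglv(sub, x0 = x0, horizon = horizon, dt = dt, seed = seed)
  if (is.null(burn_in)) burn_in <- 0.1 * horizon
  est <- stationary_mean(traj, burn_in = burn_in, n_batches = n_batches)
  if (any(est$mean < 1e-6 * x0)) {
    abort("resident subsystem collapsed; the invasion-rate estimate is unreliable.")
  }
  keep <- traj$time >= burn_in
  tt <- traj$time[keep]
  xx <- traj_states(traj)[keep, , drop = FALSE]
  g <- params$alpha[invader] - sig_i / 2 +
    as.numeric(xx %*% params$interaction[invader, resident])
  lambda <- trapz_mean(tt, g)
  idx <- cut(seq_along(tt), breaks = n_batches, labels = FALSE)
  bmeans <- vapply(split(seq_along(tt), idx), function(ii) {
    trapz_mean(tt[ii], g[ii])
  }, numeric(1))
  list(lambda = lambda, mc_se = sd(bmeans) / sqrt(length(bmeans)),
       method = "monte-carlo", resident_means = est$mean)
}

#' Stochastic persistence/extinction classification for two species
#'
#' Decides the long-run fate of a two-species stochastic community from the
#' signs of the four decisive invasion rates \eqn{\lambda_1(\mu_0)},
#' \eqn{\lambda_2(\mu_0)}, \eqn{\lambda_2(\mu_1)}, \eqn{\lambda_1(\mu_2)}:
#' \describe{
#'   \item{C1}{both origin rates negative: both species go extinct almost
#'     surely.}
#'   \item{C2}{species 1 can grow at the origin, species 2 cannot: (i) if
#'     \eqn{\lambda_2(\mu_1) > 0} the community converges to a unique interior
#'     stationary law; (ii) otherwise species 2 goes extinct at rate
#'     \eqn{\lambda_2(\mu_1)}.}
#'   \item{C3}{the mirror image of C2 with the species swapped.}
#'   \item{C4}{both origin rates positive: (i) both axis measures invadable:
#'     strong stochastic persistence with a unique interior stationary law;
#'     (ii) neither invadable: bistable extinction, one of the two species
#'     dies out with path-dependent probabilities \eqn{p_1(x) + p_2(x) = 1};
#'     (iii)/(iv) exactly one invadable: the other species goes extinct.}
#' }
#' Mutualistic systems and degenerate noise are refused; any decisive rate
#' within `tol` of zero yields a `"marginal"` verdict.
#'
#' @param params A two-species [glv_params] object.
#' @param tol Marginality tolerance on the decisive rates.
#' @return A list of class `sglv_verdict` with `case`, `outcome` (text),
#'   `persistent` (logical or NA for marginal), and `rates` (the
#'   [lyapunov_2sp()] table).
#' @examples
#' classify_stochastic_2sp(glv_scenario(1)$params)
#' @export
classify_stochastic_2sp <- function(params, tol = 1e-6) {
  stopifnot(inherits(params, "glv_params"))
  if (params$n != 2L) {
    abort(paste("the full stochastic classification is only available for 2",
                "species; use estimate_invasion_rate() per boundary face",
                "for larger communities."))
  }
  val <- validate_params(params)
  if (!attr(val, "ok")) {
    abort("parameters failed validation; see validate_params().")
  }
  if (attr(val, "type") == "mutualistic") {
    abort("mutualistic systems are outside the supported persistence theory.")
  }
  tab <- lyapunov_2sp(params)
  get <- function(measure, species) {
    tab$lambda[tab$measure == measure & tab$species == species]
  }
  l10 <- get("mu0", 1L); l20 <- get("mu0", 2L)
  l21 <- get("mu1", 2L); l12 <- get("mu2", 1L)
  decisive <- c(l10, l20,
                if (l10 > 0) l21 else NULL,
                if (l20 > 0) l12 else NULL)
  if (any(abs(decisive) < tol, na.rm = TRUE)) {
    return(new_verdict("marginal", NA,
                       "a decisive invasion rate is within tolerance of zero",
                       tab))
  }
  res <- if (l10 < 0 && l20 < 0) {
    list("C1", FALSE, "both species converge to 0 almost surely")
  } else if (l10 > 0 && l20 < 0) {
    if (l21 > 0) {
      list("C2i", TRUE, paste("strong stochastic persistence: transition",
                              "probabilities converge to a unique interior",
                              "stationary distribution"))
    } else {
      list("C2ii", FALSE,
           sprintf("species 2 goes extinct at exponential rate %.6g", l21))
    }
  } else if (l10 < 0 && l20 > 0) {
    if (l12 > 0) {
      list("C3i", TRUE, paste("strong stochastic persistence: transition",
                              "probabilities converge to a unique interior",
                              "stationary distribution"))
    } else {
      list("C3ii", FALSE,
           sprintf("species 1 goes extinct at exponential rate %.6g", l12))
    }
  } else {
    if (l12 > 0 && l21 > 0) {
      list("C4i", TRUE, paste("strong stochastic persistence: unique interior",
                              "invariant probability measure"))
    } else if (l12 < 0 && l21 < 0) {
      list("C4ii", FALSE,
           paste("bistable extinction: one species dies out with",
                 "path-dependent probabilities p1(x) > 0, p2(x) > 0,",
                 "p1(x) + p2(x) = 1"))
    } else if (l12 > 0 && l21 < 0) {
      list("C4iii", FALSE,
           sprintf("species 2 goes extinct at exponential rate %.6g", l21))
    } else {
      list("C4iv", FALSE,
           sprintf("species 1 goes extinct at exponential rate %.6g", l12))
    }
  }
  new_verdict(res[[1]], res[[2]], res[[3]], tab)
}

new_verdict <- function(case, persistent, outcome, rates) {
  structure(list(case = case, persistent = persistent, outcome = outcome,
                 rates = rates),
            class = "sglv_verdict")
}

#' @export
print.sglv_verdict <- function(x, ...) {
  cat(sprintf("<sglv_verdict> case %s\n  %s\n", x$case, x$outcome))
  invisible(x)
}
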