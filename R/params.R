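#' Specify a stochastic generalized Lotka-Volterra model
#'
#' Bundles the three parameter blocks of an N-species SgLV community:
#' intrinsic growth rates \eqn{\alpha}, the signed per-capita interaction
#' matrix \eqn{B}, and the noise intensity matrix \eqn{\Gamma = (\tau_{ij})}.
#' The model is
#' \deqn{dX_i = X_i\Big(\alpha_i + \sum_j B_{ij} X_j\Big)\,dt
#'       + X_i \sum_j \tau_{ij}\, dW_j,}
#' with one shared N-dimensional Brownian motion \eqn{W}. Self-limitation
#' requires a strictly negative diagonal of \eqn{B}; all signs live in the
#' matrix itself (competition: negative off-diagonals, mutualism: positive,
#' predator-prey: mixed).
#'
#' @param alpha Numeric vector of intrinsic growth rates (per unit time).
#' @param interaction N x N signed interaction matrix \eqn{B} (per unit time
#'   per unit abundance). The diagonal must be strictly negative.
#' @param noise N x N noise intensity matrix \eqn{\Gamma}; row i scales how the
#'   N Brownian components load on species i (per square-root unit time).
#'   Defaults to zero noise.
#' @param label Optional free-text label carried through reports.
#'
#' @return An object of class `glv_params`: a list with elements `n`, `alpha`,
#'   `interaction`, `tau`, `sigma` (\eqn{\Sigma = \Gamma\Gamma^T}), and
#'   `label`.
#'
#' @examples
#' p <- glv_params(
#'   alpha = c(6, 4),
#'   interaction = matrix(c(-0.05, -0.03, -0.01, -0.027), 2, 2, byrow = TRUE),
#'   noise = matrix(c(0.01, 0.015, 0.01, 0.02), 2, 2, byrow = TRUE)
#' )
#' p
#' @seealso [glv_params_2sp()] for the two-species sign convention with
#'   positive self-limitation coefficients, [validate_params()],
#'   [glv_scenario()] for bundled benchmark parameter sets.
#' @export
glv_params <- function(alpha, interaction, noise = NULL, label = NULL) {
  alpha <- as.numeric(alpha)
  n <- length(alpha)
  if (n < 1L) abort("`alpha` must have at least one element.")
  interaction <- as.matrix(interaction)
  if (!all(dim(interaction) == n)) {
    abort(sprintf("`interaction` must be %d x %d to match `alpha`.", n, n))
  }
  if (is.null(noise)) noise <- matrix(0, n, n)
  noise <- as.matrix(noise)
  if (!all(dim(noise) == n)) {
    abort(sprintf("`noise` must be %d x %d to match `alpha`.", n, n))
  }
  if (!all(is.finite(alpha)) || !all(is.finite(interaction)) ||
      !all(is.finite(noise))) {
    abort("all parameter entries must be finite.")
  }
  if (any(diag(interaction) >= 0)) {
    abort("`interaction` must have a strictly negative diagonal (self-limitation).")
  }
  structure(
    list(
      n = n,
      alpha = alpha,
      interaction = interaction,
      tau = noise,
      sigma = diffusion_matrix(noise),
      label = label
    ),
    class = "glv_params"
  )
}

#' Two-species parameters in the positive-coefficient convention
#'
#' Two-species SgLV models are often written with the self-limitation signs
#' pulled out of the coefficients:
#' \deqn{dX_1 = X_1(\alpha_1 - b_{11} X_1 + b_{12} X_2)\,dt + \ldots}
#' so that \eqn{b_{11}, b_{22} > 0} while \eqn{b_{12}, b_{21}} carry the
#' interaction signs. This loader translates that convention into the signed
#' matrix used everywhere else in the package:
#' \eqn{B = \begin{pmatrix} -b_{11} & b_{12} \\ b_{21} & -b_{22} \end{pmatrix}}.
#'
#' @param alpha1,alpha2 Intrinsic growth rates.
#' @param b11,b22 Positive self-limitation coefficients.
#' @param b12,b21 Signed interspecific coefficients (negative = competition).
#' @param tau 2 x 2 noise intensity matrix, or a length-4 vector read row-wise
#'   as \eqn{(\tau_{11}, \tau_{12}, \tau_{21}, \tau_{22})}.
#' @inheritParams glv_params
#' @return A [glv_params] object.
#' @examples
#' glv_params_2sp(6, 4, b11 = 0.05, b12 = -0.03, b21 = -0.01, b22 = 0.027,
#'                tau = c(0.01, 0.015, 0.01, 0.02))
#' @export
glv_params_2sp <- function(alpha1, alpha2, b11, b12, b21, b22, tau = NULL,
                           label = NULL) {
  if (b11 <= 0 || b22 <= 0) {
    abort("`b11` and `b22` must be strictly positive in this convention.")
  }
  if (!is.null(tau) && !is.matrix(tau)) {
    tau <- matrix(as.numeric(tau), 2, 2, byrow = TRUE)
  }
  glv_params(
    alpha = c(alpha1, alpha2),
    interaction = matrix(c(-b11, b12, b21, -b22), 2, 2, byrow = TRUE),
    noise = tau,
    label = label
  )
}

#' Diffusion matrix of a noise intensity matrix
#'
#' Computes \eqn{\Sigma = \Gamma\Gamma^T}, entrywise
#' \eqn{\sigma_{ij} = \sum_k \tau_{ik}\tau_{jk}}. \eqn{\Sigma} is the
#' infinitesimal covariance of the per-capita noise; its positive definiteness
#' is what makes the stochastic community model nondegenerate.
#'
#' @param tau Square numeric matrix \eqn{\Gamma}.
#' @return The symmetric positive semidefinite matrix \eqn{\Sigma}.
#' @examples
#' diffusion_matrix(matrix(c(0.01, 0.015, 0.01, 0.02), 2, 2, byrow = TRUE))
#' @export
diffusion_matrix <- function(tau) {
  tau <- as.matrix(tau)
  if (nrow(tau) != ncol(tau)) abort("`tau` must be square.")
  if (!all(is.finite(tau))) abort("`tau` must be finite.")
  tcrossprod(tau)
}

#' Noise model summary
#'
#' @param tau Square noise intensity matrix.
#' @param tol Relative eigenvalue tolerance: \eqn{\Sigma} counts as positive
#'   definite when its smallest eigenvalue exceeds `tol` times its largest.
#' @return A list with `tau`, `sigma`, and `is_positive_definite`.
#' @export
noise_model <- function(tau, tol = 1e-12) {
  sigma <- diffusion_matrix(tau)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  list(
    tau = as.matrix(tau),
    sigma = sigma,
    is_positive_definite = length(ev) > 0 && min(ev) > tol * max(max(ev), 0)
  )
}

# drift h_i(x) = x_i (alpha_i + sum_j B_ij x_j); used by every downstream stage
glv_drift <- function(params, x) {
  as.numeric(x * (params$alpha + params$interaction %*% x))
}

# per-capita growth f_i(x) = alpha_i + sum_j B_ij x_j
glv_percapita <- function(params, x) {
  as.numeric(params$alpha + params$interaction %*% x)
}

#' Classify the interaction type from off-diagonal signs
#'
#' @param params A [glv_params] object.
#' @return One of `"competitive"`, `"mutualistic"`, `"predator-prey"`,
#'   `"uncoupled"`, or `"mixed"` (for N > 2 with more than one sign pattern).
#' @export
interaction_type <- function(params) {
  B <- params$interaction
  off <- B[row(B) != col(B)]
  if (length(off) == 0 || all(off == 0)) return("uncoupled")
  if (all(off < 0)) return("competitive")
  if (all(off > 0)) return("mutualistic")
  if (params$n == 2) return("predator-prey")
  "mixed"
}

#' Validate an SgLV parameter set
#'
#' Collects structural findings about a parameter set rather than erroring:
#' sign violations on the diagonal, degeneracy of the diffusion matrix
#' \eqn{\Sigma = \Gamma\Gamma^T}, and the interaction type. Mutualistic
#' coupling (both off-diagonals positive in a two-species model) is flagged
#' because solutions can blow up in finite time there, which puts such systems
#' outside the persistence theory the rest of the package relies on.
#'
#' For N = 2, positive definiteness of \eqn{\Sigma} is equivalent to the three
#' explicit conditions \eqn{\tau_{11}^2+\tau_{12}^2 > 0},
#' \eqn{\tau_{21}^2+\tau_{22}^2 > 0}, and
#' \eqn{\tau_{11}\tau_{22}-\tau_{12}\tau_{21} \neq 0}.
#'
#' @param params A [glv_params] object.
#' @param tol Relative tolerance for the positive-definiteness check.
#' @return A tibble of findings with columns `level` (`"error"`, `"warning"`,
#'   `"note"`), `code`, and `message`, with attributes `ok` (`TRUE` iff no
#'   error-level finding) and `type` (the interaction classification).
#' @examples
#' s <- glv_scenario(1)
#' v <- validate_params(s$params)
#' attr(v, "ok")
#' @export
validate_params <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "glv_params"))
  findings <- list()
  add <- function(level, code, message) {
    findings[[length(findings) + 1L]] <<- tibble(
      level = level, code = code, message = message
    )
  }
  if (any(diag(params$interaction) >= 0)) {
    add("error", "diagonal_sign",
        "interaction diagonal must be strictly negative (self-limitation)")
  }
  nm <- noise_model(params$tau, tol = tol)
  if (all(params$tau == 0)) {
    add("note", "zero_noise",
        "noise matrix is zero: the model is the deterministic gLV")
  } else if (!nm$is_positive_definite) {
    add("error", "degenerate_noise",
        paste("diffusion matrix Sigma = Gamma Gamma^T is not positive",
              "definite; the stochastic model is degenerate"))
  }
  type <- interaction_type(params)
  add("note", "interaction_type", paste("interaction type:", type))
  if (type == "mutualistic") {
    add("warning", "mutualistic",
        paste("mutualistic coupling is outside the supported persistence",
              "theory: abundances can blow up in finite time"))
  }
  out <- bind_rows(findings)
  attr(out, "ok") <- !any(out$level == "error")
  attr(out, "type") <- type
  class(out) <- c("glv_validation", class(out))
  out
}

#' @export
print.glv_params <- function(x, ...) {
  cat(sprintf("<glv_params> %d species%s\n", x$n,
              if (!is.null(x$label)) paste0(" - ", x$label) else ""))
  cat("alpha:      ", paste(signif(x$alpha, 6), collapse = "  "), "\n")
  cat("interaction:\n")
  print(signif(x$interaction, 6))
  if (all(x$tau == 0)) {
    cat("noise:       none (deterministic)\n")
  } else {
    cat("noise tau:\n")
    print(signif(x$tau, 6))
  }
  invisible(x)
}

#' @export
print.glv_validation <- function(x, ...) {
  cat(sprintf("<glv_validation> ok = %s\n", attr(x, "ok")))
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s: %s\n", x$level[k], x$code[k], x$message[k]))
  }
  invisible(x)
}
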