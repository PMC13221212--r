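#' Broom-style accessors for sglv results
#'
#' `tidy()` returns the time-resolved or term-level content of a result as a
#' tibble; `glance()` returns a one-row summary of the scalar measures.
#'
#' @param x A fitted/derived sglv object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_sglv
NULL

#' @rdname tidy_sglv
#' @export
tidy.resilience_report <- function(x, ...) {
  tidyr::pivot_longer(x$curves, cols = c("R_ins", "R_ave"),
                      names_to = "measure", values_to = "rate")
}

#' @rdname tidy_sglv
#' @export
glance.resilience_report <- function(x, ...) {
  tibble(
    R_c = x$R_c,
    R_inf = as.numeric(x$R_inf),
    R_inf_estimator = attr(x$R_inf, "estimator"),
    R_inf_horizon = attr(x$R_inf, "horizon"),
    return_time = x$return_time,
    W0 = x$curves$W[1L],
    m_provenance = x$linsys$provenance
  )
}

#' @rdname tidy_sglv
#' @export
tidy.sglv_verdict <- function(x, ...) x$rates

#' @rdname tidy_sglv
#' @export
glance.sglv_verdict <- function(x, ...) {
  tibble(case = x$case, persistent = x$persistent, outcome = x$outcome)
}

#' @rdname tidy_sglv
#' @export
tidy.sglv_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -"time",
                      names_to = "species", values_to = "abundance")
}

#' Plot methods
#'
#' `autoplot()` draws the natural ggplot for each result type: abundance
#' paths for trajectories, the W(t) distance and mean deviations for moment
#' paths, and the two return-rate curves with the \eqn{\mathcal{R}_c} /
#' \eqn{\mathcal{R}_\infty} reference lines for resilience reports.
#'
#' @param object An sglv result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_sglv
NULL

#' @rdname autoplot_sglv
#' @export
autoplot.sglv_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.sglv_trajectory(object),
                  ggplot2::aes(x = .data$time, y = .data$abundance,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "abundance",
                  title = attr(object, "scheme"))
}

#' @rdname autoplot_sglv
#' @export
autoplot.moment_path <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$W)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "W(t) = trace P(t)",
                  title = "mean squared distance to the stationary state")
}

#' @rdname autoplot_sglv
#' @export
autoplot.resilience_report <- function(object, ...) {
  ggplot2::ggplot(tidy.resilience_report(object),
                  ggplot2::aes(x = .data$time, y = .data$rate,
                               colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$R_c, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = as.numeric(object$R_inf),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "time since pulse", y = "return rate",
                  title = object$label)
}
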