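#' Read and write SgLV parameter files
#'
#' Parameters travel as structured JSON with keys `alpha` (list),
#' `interaction` (row-major nested list), `tau` (nested list), `convention`
#' (`"signed"` for the internal matrix with negative diagonal, or
#' `"two-species"` for the positive-coefficient convention with keys `b11`,
#' `b12`, `b21`, `b22`), and an optional free-text `label`.
#'
#' @param params A [glv_params] object.
#' @param path File path.
#' @param convention Convention to write (`"signed"` keeps the internal
#'   matrix).
#' @return `read_params()` returns a [glv_params] object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path, convention = "signed") {
  stopifnot(inherits(params, "glv_params"))
  rec <- list(
    convention = convention,
    alpha = params$alpha,
    tau = unname(apply(params$tau, 1L, as.list, simplify = FALSE)),
    label = params$label
  )
  if (convention == "two-species") {
    if (params$n != 2L) abort("two-species convention needs N = 2.")
    B <- params$interaction
    rec$b11 <- -B[1, 1]; rec$b12 <- B[1, 2]
    rec$b21 <- B[2, 1]; rec$b22 <- -B[2, 2]
  } else {
    rec$interaction <- unname(apply(params$interaction, 1L, as.list,
                                    simplify = FALSE))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  tau <- if (is.null(rec$tau)) NULL else as.matrix(rec$tau)
  if (identical(rec$convention, "two-species")) {
    glv_params_2sp(rec$alpha[1], rec$alpha[2], rec$b11, rec$b12,
                   rec$b21, rec$b22, tau = tau, label = rec$label)
  } else {
    glv_params(rec$alpha, as.matrix(rec$interaction), tau, label = rec$label)
  }
}

#' Read and write trajectories
#'
#' Trajectories are written as plain CSV with header `time,X1,...,XN` plus a
#' JSON sidecar `<path>.meta.json` holding the provenance (scheme, dt, seed,
#' and a hash of the generating parameters).
#'
#' @param traj An `sglv_trajectory`.
#' @param path CSV file path.
#' @return `read_trajectory()` returns an `sglv_trajectory` (without the
#'   original parameter object); `write_trajectory()` returns `path`
#'   invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sglv_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(
    scheme = attr(traj, "scheme"),
    dt = attr(traj, "dt"),
    seed = attr(traj, "seed"),
    params_hash = if (!is.null(attr(traj, "params"))) {
      hash(attr(traj, "params")[c("alpha", "interaction", "tau")])
    }
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(scheme = "unknown", dt = diff(df$time)[1L], seed = NULL)
  }
  new_trajectory(df$time, as.matrix(df[, -1L, drop = FALSE]),
                 meta$scheme, meta$dt, meta$seed, NULL)
}

#' Serialize a linearized system
#'
#' Flat key-value JSON record: `m`, `Theta`, `A` (row-major), `tau`,
#' `provenance`.
#'
#' @param linsys A `linearized_system`.
#' @param path File path.
#' @return `read_linearized()` returns a `linearized_system`;
#'   `write_linearized()` returns `path` invisibly.
#' @export
write_linearized <- function(linsys, path) {
  stopifnot(inherits(linsys, "linearized_system"))
  rec <- list(
    m = linsys$m, Theta = linsys$Theta,
    A = unname(apply(linsys$A, 1L, as.list, simplify = FALSE)),
    tau = unname(apply(linsys$tau, 1L, as.list, simplify = FALSE)),
    provenance = linsys$provenance, label = linsys$label
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_linearized
#' @export
read_linearized <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_linearized_system(rec$m, rec$Theta, as.matrix(rec$A),
                        as.matrix(rec$tau), rec$provenance, rec$label)
}

#' Write a resilience report
#'
#' Emits `<prefix>.json` with the scalar measures and provenance, and
#' `<prefix>_curves.csv` with the time-resolved return-rate curves and W.
#'
#' @param report A `resilience_report`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "resilience_report"))
  rec <- list(
    label = report$label,
    pulse = report$pulse,
    m = report$linsys$m,
    m_provenance = report$linsys$provenance,
    R_c = report$R_c,
    R_inf = as.numeric(report$R_inf),
    R_inf_estimator = attr(report$R_inf, "estimator"),
    R_inf_horizon = attr(report$R_inf, "horizon"),
    return_time = report$return_time,
    verdict = if (!is.null(report$verdict)) {
      list(case = report$verdict$case, outcome = report$verdict$outcome)
    }
  )
  json_path <- paste0(prefix, ".json")
  csv_path <- paste0(prefix, "_curves.csv")
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  write.csv(as.data.frame(report$curves), csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
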