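# linearized system built straight from a scenario's reference coefficient
# table (no re-derivation from the parameter set)
table_linsys <- function(set_id) {
  s <- glv_scenario(set_id)
  cf <- s$ref_coeffs
  linearized_system(
    m = s$ref_mean,
    Theta = cf[c("Phi1", "Phi2")],
    A = matrix(cf[c("gamma11", "gamma12", "gamma21", "gamma22")],
               2, 2, byrow = TRUE),
    tau = s$params$tau,
    provenance = "reference-table",
    label = s$label
  )
}

# random competitive/mixed system with zero noise whose community matrix has a
# real leading eigenvalue (retry until it does)
random_hurwitz_linsys <- function(n, seed) {
  for (k in 0:50) {
    p <- random_glv(n, interaction_type = "competitive", noise_scale = 0,
                    seed = seed + 1000L * k)
    ls <- linearize_deterministic(p)
    ev <- eigen(ls$A, only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    if (abs(Im(lead)) < 1e-12 && max(Re(ev)) < -1e-3) return(ls)
  }
  stop("no suitable draw found")
}

# slowest (real) eigendirection of A, for exact single-mode decay checks
slow_eigvec <- function(A) {
  e <- eigen(A)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v / sqrt(sum(v^2))
}
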