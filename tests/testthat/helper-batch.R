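# Vectorised long-time RK4 oracle: integrates many networks at once,
# coded directly from the model equations (independent of the package
# solver). MU: n x 6 edge coefficients; Y: n x 3 states.

batch_field <- function(Y, MU, mu_rp, parasite, phi) {
  term <- function(mu, yj, yi) ifelse(mu > 0, mu * yj * (1 - yi),
                                      mu * yj * yi)
  dR <- -phi * Y[, 1] + if (parasite) term(mu_rp, 1, Y[, 1]) else 0
  dES <- -phi * Y[, 2] + term(MU[, 1], Y[, 1], Y[, 2]) +
    term(MU[, 3], 1, Y[, 2]) + term(MU[, 5], Y[, 3], Y[, 2])
  dEN <- -phi * Y[, 3] + term(MU[, 2], Y[, 1], Y[, 3]) +
    term(MU[, 4], 1, Y[, 3]) + term(MU[, 6], Y[, 2], Y[, 3])
  cbind(dR, dES, dEN)
}

batch_rk4 <- function(MU, mu_rp, parasite, phi = 0.3, init = NULL,
                      t_end = 300, h = 0.05) {
  Y <- if (is.null(init)) matrix(0, nrow(MU), 3) else init
  for (s in seq_len(round(t_end / h))) {
    k1 <- batch_field(Y, MU, mu_rp, parasite, phi)
    k2 <- batch_field(Y + h / 2 * k1, MU, mu_rp, parasite, phi)
    k3 <- batch_field(Y + h / 2 * k2, MU, mu_rp, parasite, phi)
    k4 <- batch_field(Y + h * k3, MU, mu_rp, parasite, phi)
    Y <- Y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  Y
}

# Six per-host edge coefficients from a host bit matrix, recomputed here
# from the matching rule so the oracle path shares nothing with the
# compiled engine.
batch_edge_mu <- function(hosts, L = 10L) {
  edge_in <- c("E_S", "E_N", "E_S", "E_N", "E_S", "E_N")
  edge_out <- c("R", "R", "C", "C", "E_N", "E_S")
  sapply(1:6, function(e) {
    a <- hosts[, seq_cols(edge_in[e], "S_I", L), drop = FALSE]
    b <- hosts[, seq_cols(edge_out[e], "S_O", L), drop = FALSE]
    1 - 2 * rowSums(a != b) / L
  })
}

# Shared scaled-down coevolution runs (memoised so several acceptance
# checks can reuse the same simulations): 500 hosts and parasites, 3000
# generations with a 1500-generation burn-in, 5 replicates, cost and
# delay at the low displayed setting 0.2, master seed 42.
.acc_cache <- new.env(parent = emptyenv())
acceptance_run <- function(mode, p) {
  key <- paste(mode, p, sep = "_")
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  cfg <- sim_config(receptor_mode = mode, p_encounter = p, kappa = 0.2,
                    delta = 0.2, n_host = 500L, n_parasite = 500L,
                    generations = 3000L, burn_in = 1500L, replicates = 5L)
  res <- summarize_replicates(run_replicates(cfg, seed = 42))
  .acc_cache[[key]] <- res
  res
}
acc_stat <- function(s, name) s$mean[s$statistic == name]
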