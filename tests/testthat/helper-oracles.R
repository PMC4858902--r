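# Independent oracles for the network dynamics, written directly from
# the model equations and sharing no code with the package solver.

# Vector field of the three dynamic proteins (y_R, y_ES, y_EN) with
# sources y_C = 1 and, during infection, y_P = 1. mu6 order:
# ES<-R, EN<-R, ES<-C, EN<-C, ES<-EN, EN<-ES.
oracle_field <- function(y, mu6, mu_rp, parasite, phi) {
  piece <- function(mu, yj, yi) if (mu > 0) mu * yj * (1 - yi) else mu * yj * yi
  y <- unname(y); mu6 <- unname(mu6)
  c(-phi * y[1] + if (parasite) piece(mu_rp, 1, y[1]) else 0,
    -phi * y[2] + piece(mu6[1], y[1], y[2]) + piece(mu6[3], 1, y[2]) +
      piece(mu6[5], y[3], y[2]),
    -phi * y[3] + piece(mu6[2], y[1], y[3]) + piece(mu6[4], 1, y[3]) +
      piece(mu6[6], y[2], y[3]))
}

# Plain long-time RK4 integration to a fixed horizon (no convergence
# test), the reference the equilibrium solver is compared against.
oracle_rk4 <- function(mu6, mu_rp, parasite, phi, init = c(0, 0, 0),
                       t_end = 300, h = 0.05) {
  y <- init
  for (step in seq_len(round(t_end / h))) {
    k1 <- oracle_field(y, mu6, mu_rp, parasite, phi)
    k2 <- oracle_field(y + h / 2 * k1, mu6, mu_rp, parasite, phi)
    k3 <- oracle_field(y + h / 2 * k2, mu6, mu_rp, parasite, phi)
    k4 <- oracle_field(y + h * k3, mu6, mu_rp, parasite, phi)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# A random interaction matrix on the mu grid realizable at length L
random_interactions <- function(L = 10L) {
  list(mu = stats::setNames(1 - 2 * sample(0:L, 6, replace = TRUE) / L,
                            c("mu_ES_R", "mu_EN_R", "mu_ES_C", "mu_EN_C",
                              "mu_ES_EN", "mu_EN_ES")),
       mu_RP = sample(c(0, 0.2, 1), 1))
}

# Genome whose chosen sequences are all-ones/all-zeros so that every
# interaction coefficient is known exactly
uniform_host <- function(bit, L = 10L) {
  seqs <- function() list(S_N = rep(0L, L), S_I = rep(bit, L),
                          S_O = rep(1L, L))
  g <- list(R = seqs(), C = seqs(), E_S = seqs(), E_N = seqs())
  class(g) <- "host_genome"
  g
}
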