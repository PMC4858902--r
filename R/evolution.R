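# The individual-based coevolutionary loop: encounters, fitness
# evaluation, fitness-weighted lottery selection, reproduction with
# between-protein recombination (hosts) or clonally (parasites), and
# point mutation. The production path is the compiled engine behind
# run_simulation(); the R-level operations below define the reference
# semantics on small populations and are what the unit tests exercise.

#' Simulation configuration
#'
#' Defaults are the study conditions of the model: sequence length 10,
#' deactivation rate 0.3, mutation rate 0.01 per individual per
#' generation, host and parasite population size 2000, maximum virulence
#' 0.99, 10000 generations with a 5000-generation burn-in, 20
#' replicates. Cost `kappa` and delay `delta` default to the low setting
#' 0.2 of the displayed analyses.
#'
#' @param receptor_mode `"nonspecific"` (scenarios focused on effector
#'   specificity) or `"specific"` (specific detection).
#' @param p_encounter probability that a host is challenged by a single
#'   randomly chosen parasite.
#' @param kappa marginal cost of effector expression.
#' @param delta relative induction delay in `[0, 1]`.
#' @param nu maximum virulence in `[0, 1)`.
#' @param phi spontaneous deactivation rate.
#' @param L bitstring sequence length.
#' @param n_host,n_parasite population sizes (kept fixed).
#' @param mutation_rate per-individual, per-generation mutation
#'   probability.
#' @param generations number of generations to simulate.
#' @param burn_in generations excluded from headline averages.
#' @param replicates number of replicate simulations.
#' @param consensus_every record population consensus sequences every
#'   this many generations.
#' @param tol,t_max,step equilibrium-solver controls (see
#'   [solve_equilibrium()]).
#' @return a validated list with class `"sim_config"`.
#' @export
sim_config <- function(receptor_mode = c("nonspecific", "specific"),
                       p_encounter = 1, kappa = 0.2, delta = 0.2,
                       nu = 0.99, phi = 0.3, L = 10L,
                       n_host = 2000L, n_parasite = 2000L,
                       mutation_rate = 0.01, generations = 10000L,
                       burn_in = 5000L, replicates = 20L,
                       consensus_every = 10L, tol = 1e-8, t_max = 1000,
                       step = 0.05) {
  receptor_mode <- match.arg(receptor_mode)
  cfg <- list(receptor_mode = receptor_mode, p_encounter = p_encounter,
              kappa = kappa, delta = delta, nu = nu, phi = phi,
              L = as.integer(L), n_host = as.integer(n_host),
              n_parasite = as.integer(n_parasite),
              mutation_rate = mutation_rate,
              generations = as.integer(generations),
              burn_in = as.integer(burn_in),
              replicates = as.integer(replicates),
              consensus_every = as.integer(consensus_every),
              tol = tol, t_max = t_max, step = step)
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(p_encounter >= 0 && p_encounter <= 1, "p_encounter must be in [0, 1]")
  chk(kappa >= 0, "kappa must be non-negative")
  chk(delta >= 0 && delta <= 1, "delta must be in [0, 1]")
  chk(nu >= 0 && nu < 1, "nu must be in [0, 1)")
  chk(phi > 0, "phi must be positive")
  chk(cfg$L >= 1, "L must be a positive integer")
  chk(cfg$n_host >= 1 && cfg$n_parasite >= 1, "population sizes must be >= 1")
  chk(mutation_rate >= 0 && mutation_rate <= 1,
      "mutation_rate must be in [0, 1]")
  chk(cfg$generations >= 0, "generations must be non-negative")
  chk(cfg$burn_in >= 0 && cfg$burn_in <= cfg$generations,
      "burn_in must lie within the simulated generations")
  chk(cfg$replicates >= 1, "replicates must be >= 1")
  chk(cfg$consensus_every >= 1, "consensus_every must be >= 1")
  chk(tol > 0 && t_max > 0 && step > 0, "solver controls must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Assign parasite encounters to hosts
#'
#' Each host is independently challenged with probability `p_encounter`
#' and, if challenged, paired with one parasite drawn uniformly with
#' replacement. A host faces at most one parasite; a parasite may be
#' drawn by several hosts.
#'
#' @param n_host,n_parasite population sizes.
#' @param p_encounter encounter probability.
#' @return integer vector of length `n_host`: the index of the
#'   encountered parasite, or `NA` for unchallenged hosts.
#' @export
assign_encounters <- function(n_host, n_parasite, p_encounter) {
  stopifnot(p_encounter >= 0, p_encounter <= 1)
  enc <- rep(NA_integer_, n_host)
  challenged <- runif(n_host) < p_encounter
  n <- sum(challenged)
  if (n > 0)
    enc[challenged] <- sample.int(n_parasite, n, replace = TRUE)
  enc
}

#' Evaluate fitness of every host and parasite for one generation
#'
#' Computes each host's constitutive equilibrium, assigns encounters,
#' solves the induced equilibrium for every challenged pair and applies
#' the survival model; parasite fitness is the mean infection success
#' over its realized encounters, and parasites that were never drawn
#' receive the mean fitness of the encountered ones (selectively
#' neutral).
#'
#' @param hosts,parasites population bit matrices
#'   ([random_population()]).
#' @param config a [sim_config()].
#' @param encounters optional precomputed encounter vector
#'   ([assign_encounters()]); drawn internally when `NULL`.
#' @return list with `host_fitness`, `parasite_fitness`, `encounters`,
#'   and `components` (data frame of per-pair fitness components: E0,
#'   C0, Estar, Cstar, s0, sstar, mu_RP, plus the equilibrium
#'   activities).
#' @export
evaluate_generation <- function(hosts, parasites, config,
                                encounters = NULL) {
  nh <- nrow(hosts); np <- nrow(parasites)
  if (is.null(encounters))
    encounters <- assign_encounters(nh, np, config$p_encounter)
  host_g <- lapply(seq_len(nh), function(i) row_to_genome(hosts[i, ], "host"))
  para_g <- lapply(seq_len(np), function(j)
    row_to_genome(parasites[j, ], "parasite"))
  solver <- list(tol = config$tol, t_max = config$t_max, step = config$step)
  y0 <- t(vapply(host_g, function(g)
    do.call(constitutive_state, c(list(host = g, phi = config$phi), solver)),
    numeric(3L)))
  C0 <- config$kappa * (y0[, "y_ES"] + y0[, "y_EN"])
  s0 <- pmax(0, 1 - C0)
  W_host <- s0
  wsum <- numeric(np); cnt <- integer(np)
  comp <- list()
  for (i in which(!is.na(encounters))) {
    j <- encounters[i]
    xi_S <- effector_parasite_efficacy(host_g[[i]]$E_S, para_g[[j]], "E_S")
    xi_N <- 0.2
    ystar <- do.call(induced_state,
                     c(list(host = host_g[[i]], parasite = para_g[[j]],
                            receptor_mode = config$receptor_mode,
                            phi = config$phi), solver))
    e0 <- efficacy_and_cost(y0[i, "y_ES"], y0[i, "y_EN"], xi_S, xi_N,
                            config$kappa)
    es <- efficacy_and_cost(ystar[["y_ES"]], ystar[["y_EN"]], xi_S, xi_N,
                            config$kappa)
    sstar <- survival_infected(e0$E, e0$C, es$E, es$C, config$nu,
                               config$delta)
    W_host[i] <- host_fitness(e0$C, sstar, challenged = TRUE)
    w <- parasite_fitness(e0$E, es$E, config$delta)
    wsum[j] <- wsum[j] + w
    cnt[j] <- cnt[j] + 1L
    comp[[length(comp) + 1L]] <- data.frame(
      host = i, parasite = j,
      mu_RP = receptor_parasite_coefficient(host_g[[i]]$R, para_g[[j]],
                                            config$receptor_mode),
      xi_S = xi_S, xi_N = xi_N,
      y0_ES = y0[i, "y_ES"], y0_EN = y0[i, "y_EN"],
      ystar_R = ystar[["y_R"]], ystar_ES = ystar[["y_ES"]],
      ystar_EN = ystar[["y_EN"]],
      E0 = e0$E, C0 = e0$C, Estar = es$E, Cstar = es$C,
      s0 = s0[i], sstar = sstar, W_host = W_host[i], W_parasite = w)
  }
  W_par <- rep(NA_real_, np)
  enc_idx <- cnt > 0L
  W_par[enc_idx] <- wsum[enc_idx] / cnt[enc_idx]
  W_par[!enc_idx] <- if (any(enc_idx)) mean(W_par[enc_idx]) else 1
  list(host_fitness = W_host, parasite_fitness = W_par,
       encounters = encounters,
       components = if (length(comp)) do.call(rbind, comp) else NULL,
       constitutive = y0)
}

#' Mutate a population in place
#'
#' Vectorised form of [mutate_genome()] on a bit matrix: each individual
#' independently receives, with probability `rate`, exactly one bit flip
#' at a uniformly chosen position.
#'
#' @param pop population bit matrix.
#' @param rate per-individual mutation probability.
#' @return mutated bit matrix.
#' @export
mutate_population <- function(pop, rate = 0.01) {
  stopifnot(rate >= 0, rate <= 1)
  hit <- which(runif(nrow(pop)) < rate)
  if (length(hit)) {
    pos <- sample.int(ncol(pop), length(hit), replace = TRUE)
    idx <- cbind(hit, pos)
    pop[idx] <- 1L - pop[idx]
  }
  pop
}

#' Produce the next host generation
#'
#' For each of the `nrow(hosts)` offspring two parents are drawn by a
#' fitness-weighted lottery with replacement (they may coincide), each
#' of the four proteins is inherited intact from one parent or the other
#' with probability 1/2, and the offspring is then subjected to point
#' mutation. Population size is preserved exactly. If every fitness is
#' zero, parents are drawn uniformly (with a warning).
#'
#' @param hosts host bit matrix.
#' @param fitness non-negative fitness vector, one per host.
#' @param mutation_rate per-individual mutation probability.
#' @param L sequence length.
#' @return bit matrix of the offspring generation.
#' @export
reproduce_hosts <- function(hosts, fitness, mutation_rate = 0.01, L = 10L) {
  n <- nrow(hosts)
  stopifnot(length(fitness) == n, all(fitness >= 0))
  prob <- if (sum(fitness) > 0) fitness else {
    warning("all host fitness zero; sampling parents uniformly",
            call. = FALSE)
    rep(1, n)
  }
  pa <- sample.int(n, n, replace = TRUE, prob = prob)
  pb <- sample.int(n, n, replace = TRUE, prob = prob)
  off <- matrix(0L, n, ncol(hosts))
  for (p in 0:3) {
    cols <- p * 3L * L + seq_len(3L * L)
    from_a <- runif(n) < 0.5
    off[from_a, cols] <- hosts[pa[from_a], cols]
    off[!from_a, cols] <- hosts[pb[!from_a], cols]
  }
  mutate_population(off, mutation_rate)
}

#' Produce the next parasite generation
#'
#' Parasites reproduce asexually: each offspring is a clonal copy of a
#' parent drawn by a fitness-weighted lottery with replacement, then
#' subjected to point mutation.
#'
#' @param parasites parasite bit matrix.
#' @inheritParams reproduce_hosts
#' @return bit matrix of the offspring generation.
#' @export
reproduce_parasites <- function(parasites, fitness, mutation_rate = 0.01) {
  n <- nrow(parasites)
  stopifnot(length(fitness) == n, all(fitness >= 0))
  prob <- if (sum(fitness) > 0) fitness else {
    warning("all parasite fitness zero; sampling parents uniformly",
            call. = FALSE)
    rep(1, n)
  }
  src <- sample.int(n, n, replace = TRUE, prob = prob)
  mutate_population(parasites[src, , drop = FALSE], mutation_rate)
}

#' Run one coevolutionary simulation
#'
#' Runs the full individual-based loop in compiled code: every
#' generation each host's constitutive equilibrium is computed (cached
#' across hosts sharing interaction coefficients), encounters are
#' assigned, induced equilibria and the survival model give host and
#' parasite fitness, and both populations reproduce by fitness-weighted
#' lottery. Per-generation summaries and thinned population consensus
#' sequences are recorded. Deterministic given the R random seed in
#' effect (`set.seed()`).
#'
#' @param config a [sim_config()].
#' @param hosts,parasites optional initial bit matrices; random
#'   populations are generated when `NULL`.
#' @return an object of class `"immunet_sim"`: list with `summary`
#'   (data frame, one row per generation), `config`, `host_consensus`
#'   and `parasite_consensus` (bit matrices, one row per recorded
#'   generation), `consensus_generations`, final `hosts` and
#'   `parasites`, and `solver_failures`.
#' @export
run_simulation <- function(config, hosts = NULL, parasites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(hosts))
    hosts <- random_population(config$n_host, "host", config$L)
  if (is.null(parasites))
    parasites <- random_population(config$n_parasite, "parasite", config$L)
  stopifnot(ncol(hosts) == 12L * config$L,
            ncol(parasites) == 3L * config$L)
  res <- cpp_run_simulation(hosts, parasites, config$L,
                            config$receptor_mode == "specific",
                            config$p_encounter, config$kappa, config$delta,
                            config$nu, config$phi, config$mutation_rate,
                            config$generations, config$consensus_every,
                            config$step, config$tol, config$t_max)
  if (res$solver_failures > 0)
    warning(sprintf("%d equilibrium solves did not converge within t_max",
                    res$solver_failures), call. = FALSE)
  out <- list(summary = as.data.frame(res$summary), config = config,
              host_consensus = res$host_consensus,
              parasite_consensus = res$parasite_consensus,
              consensus_generations = as.integer(res$consensus_generations),
              hosts = res$hosts, parasites = res$parasites,
              solver_failures = res$solver_failures)
  class(out) <- "immunet_sim"
  out
}

#' @export
print.immunet_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<immunet_sim> %s receptor, p_encounter=%g, kappa=%g, delta=%g\n",
    cfg$receptor_mode, cfg$p_encounter, cfg$kappa, cfg$delta))
  cat(sprintf("  %d generations, %d hosts, %d parasites\n",
              cfg$generations, cfg$n_host, cfg$n_parasite))
  post <- x$summary$generation > cfg$burn_in
  if (any(post)) {
    cat(sprintf("  post-burn-in means: y0_EN=%.3f induced_EN=%.3f diversity=%.2f\n",
                mean(x$summary$y0_EN[post]),
                mean(x$summary$induced_EN[post], na.rm = TRUE),
                mean(x$summary$parasite_diversity[post])))
  }
  invisible(x)
}

#' Derive per-replicate seeds from a master seed
#'
#' Replicate r receives the r-th draw of `sample.int(2^31 - 1)` under
#' `set.seed(master_seed)`, so each replicate is independently
#' re-runnable from its own recorded seed.
#'
#' @param master_seed integer master seed.
#' @param replicates number of replicates.
#' @return integer vector of seeds.
#' @export
replicate_seeds <- function(master_seed, replicates) {
  set.seed(master_seed)
  sample.int(2147483647L, replicates)
}

#' Run replicate simulations
#'
#' @param config a [sim_config()] (its `replicates` field sets the
#'   default number of replicates).
#' @param seed master seed; per-replicate seeds are derived by
#'   [replicate_seeds()].
#' @param replicates optional override of `config$replicates`.
#' @return list with `summary` (data frame over all replicates, keyed by
#'   `replicate` and `generation`), `sims` (list of `immunet_sim`),
#'   `seeds`, and `config`.
#' @export
run_replicates <- function(config, seed, replicates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(replicates)) replicates <- config$replicates
  seeds <- replicate_seeds(seed, replicates)
  sims <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    sims[[r]] <- run_simulation(config)
  }
  tabs <- lapply(seq_len(replicates), function(r)
    cbind(replicate = r, sims[[r]]$summary))
  list(summary = do.call(rbind, tabs), sims = sims, seeds = seeds,
       config = config)
}
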