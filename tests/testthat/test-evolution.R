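small_config <- function(...) {
  args <- list(...)
  defaults <- list(p_encounter = 1, n_host = 40L, n_parasite = 40L,
                   generations = 10L, burn_in = 0L, replicates = 2L,
                   consensus_every = 5L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("configuration defaults match the model and validation rejects bad values", {
  cfg <- sim_config()
  expect_equal(cfg$L, 10L)
  expect_equal(cfg$phi, 0.3)
  expect_equal(cfg$nu, 0.99)
  expect_equal(cfg$mutation_rate, 0.01)
  expect_equal(cfg$n_host, 2000L)
  expect_equal(cfg$n_parasite, 2000L)
  expect_equal(cfg$generations, 10000L)
  expect_equal(cfg$burn_in, 5000L)
  expect_equal(cfg$replicates, 20L)
  expect_error(sim_config(p_encounter = 1.5), "p_encounter")
  expect_error(sim_config(delta = -0.1), "delta")
  expect_error(sim_config(nu = 1), "nu")
  expect_error(sim_config(burn_in = 20, generations = 10), "burn_in")
  expect_error(sim_config(receptor_mode = "psychic"))
})

test_that("encounters are binomial with uniform parasite pairing", {
  set.seed(41)
  expect_true(all(is.na(assign_encounters(100, 50, 0))))
  e1 <- assign_encounters(100, 50, 1)
  expect_true(all(!is.na(e1)))
  expect_true(all(e1 >= 1 & e1 <= 50))
  counts <- replicate(400, sum(!is.na(assign_encounters(2000, 2000, 0.2))))
  expect_equal(mean(counts), 400, tolerance = 0.02)
})

test_that("fitness evaluation handles no-encounter and repeat-encounter cases", {
  set.seed(42)
  cfg <- small_config(p_encounter = 0, n_host = 10L, n_parasite = 10L)
  hosts <- random_population(10, "host")
  parasites <- random_population(10, "parasite")
  ev <- evaluate_generation(hosts, parasites, cfg)
  # unchallenged hosts pay only the constitutive cost
  C0 <- cfg$kappa * (ev$constitutive[, "y_ES"] + ev$constitutive[, "y_EN"])
  expect_equal(ev$host_fitness, pmax(0, 1 - C0))
  expect_true(all(ev$parasite_fitness == 1))  # neutral parasites
  # one parasite encountered twice: fitness is the mean of the two draws
  cfg1 <- small_config(n_host = 2L, n_parasite = 3L)
  h2 <- random_population(2, "host")
  ev2 <- evaluate_generation(h2, parasites[1:3, ], cfg1,
                             encounters = c(2L, 2L))
  expect_equal(ev2$parasite_fitness[2], mean(ev2$components$W_parasite))
  expect_equal(ev2$parasite_fitness[1], ev2$parasite_fitness[2])  # neutral mean
  # clonal hosts against one parasite share identical components
  mono <- h2[c(1, 1), ]
  ev3 <- evaluate_generation(mono, parasites[1:3, ], cfg1,
                             encounters = c(3L, 3L))
  expect_equal(ev3$components$W_host[1], ev3$components$W_host[2])
  expect_equal(ev3$host_fitness[1], ev3$host_fitness[2])
})

test_that("reproduction keeps sizes fixed and respects the fitness lottery", {
  set.seed(43)
  hosts <- random_population(30, "host")
  # degenerate lottery: one positive-fitness host parents everyone
  w <- c(1, rep(0, 29))
  off <- reproduce_hosts(hosts, w, mutation_rate = 0, L = 10L)
  expect_equal(nrow(off), 30L)
  expect_true(all(apply(off, 1, identical, hosts[1, ])))
  # offspring proteins always come bit-for-bit from a parent
  w2 <- rep(1, 30)
  off2 <- reproduce_hosts(hosts, w2, mutation_rate = 0, L = 10L)
  for (p in 0:3) {
    cols <- p * 30L + 1:30
    for (i in 1:10) {
      matches <- apply(hosts[, cols], 1, identical, off2[i, cols])
      expect_true(any(matches))
    }
  }
  # parasites: clonal offspring in fitness proportion (2:1 within noise)
  parasites <- random_population(300, "parasite")
  parasites[1:150, 1] <- 0L; parasites[151:300, 1] <- 1L
  wp <- c(rep(2, 150), rep(1, 150))
  set.seed(44)
  frac <- mean(replicate(60, {
    off <- reproduce_parasites(parasites, wp, mutation_rate = 0)
    mean(off[, 1] == 0L)
  }))
  expect_equal(frac, 2 / 3, tolerance = 0.02)
  expect_warning(reproduce_parasites(parasites, rep(0, 300)), "uniform")
})

test_that("the simulation engine is deterministic and preserves sizes", {
  cfg <- small_config(generations = 30L)
  set.seed(45); a <- run_simulation(cfg)
  set.seed(45); b <- run_simulation(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$hosts, b$hosts)
  expect_identical(a$parasites, b$parasites)
  expect_equal(nrow(a$hosts), cfg$n_host)
  expect_equal(nrow(a$parasites), cfg$n_parasite)
  expect_equal(nrow(a$summary), cfg$generations + 1L)
  expect_equal(a$summary$generation, 0:30)
  # zero generations: the initial population summary only
  cfg0 <- small_config(generations = 0L, burn_in = 0L)
  set.seed(46); z <- run_simulation(cfg0)
  expect_equal(nrow(z$summary), 1L)
})

test_that("engine generation-0 statistics match the R-level operations", {
  cfg <- small_config(p_encounter = 0, n_host = 25L, n_parasite = 30L,
                      generations = 1L)
  set.seed(47)
  hosts <- random_population(25, "host")
  parasites <- random_population(30, "parasite")
  sim <- run_simulation(cfg, hosts, parasites)
  g0 <- sim$summary[1, ]
  ev <- evaluate_generation(hosts, parasites, cfg,
                            encounters = rep(NA_integer_, 25))
  expect_equal(g0$y0_ES, mean(ev$constitutive[, "y_ES"]), tolerance = 1e-10)
  expect_equal(g0$y0_EN, mean(ev$constitutive[, "y_EN"]), tolerance = 1e-10)
  expect_equal(g0$W_host, mean(ev$host_fitness), tolerance = 1e-10)
  mu <- edge_strengths(hosts)
  for (nm in names(mu)) expect_equal(g0[[nm]], unname(mu[nm]))
  expect_equal(g0$parasite_diversity,
               parasite_pairwise_diversity(parasites))
  expect_true(is.na(g0$induced_EN))  # nobody challenged
})

test_that("without parasites, costly constitutive activity is selected away", {
  cfg <- small_config(p_encounter = 0, kappa = 0.4, n_host = 150L,
                      n_parasite = 20L, generations = 300L)
  set.seed(48)
  sim <- run_simulation(cfg)
  early <- mean(sim$summary$y0_EN[1:20] + sim$summary$y0_ES[1:20])
  late <- mean(tail(sim$summary$y0_EN + sim$summary$y0_ES, 20))
  expect_lt(late, early)
})

test_that("replicate seeds derive deterministically from the master seed", {
  expect_identical(replicate_seeds(7, 5), replicate_seeds(7, 5))
  expect_false(any(replicate_seeds(7, 5) == replicate_seeds(8, 5)))
  cfg <- small_config(generations = 5L)
  r <- run_replicates(cfg, seed = 3, replicates = 2)
  expect_equal(sort(unique(r$summary$replicate)), 1:2)
  expect_equal(nrow(r$summary), 2 * 6)
})
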