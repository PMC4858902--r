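test_that("interaction matrices are pure functions of the genomes", {
  L <- 10L
  all1 <- uniform_host(1L, L)   # every S_I matches every S_O: all mu = 1
  all0 <- uniform_host(0L, L)   # maximal mismatch: all mu = -1
  expect_equal(unname(build_interactions(all1)$mu), rep(1, 6))
  expect_equal(unname(build_interactions(all0)$mu), rep(-1, 6))
  set.seed(21)
  h <- random_genome("host"); p <- random_genome("parasite")
  without <- build_interactions(h)
  with <- build_interactions(h, p, "specific")
  expect_identical(without$mu, with$mu)  # parasite only adds the P->R edge
  expect_true(is.na(without$mu_RP))
  expect_true(with$mu_RP %in% c(0, 1))
})

test_that("derivative matches the model equations at hand-picked states", {
  m <- list(mu = c(mu_ES_R = 0, mu_EN_R = 0, mu_ES_C = 0, mu_EN_C = 0,
                   mu_ES_EN = 0, mu_EN_ES = 0), mu_RP = 0.2)
  # receptor with no inputs: dy_R/dt = 0 at y_R = 0
  d <- activity_derivative(c(0, 0, 0), m, phi = 0.3, parasite_present = FALSE)
  expect_equal(unname(d), c(0, 0, 0))
  # parasite present, mu_RP = 0.2, y_R = 0: dy_R/dt = 0.2
  d <- activity_derivative(c(0, 0, 0), m, phi = 0.3, parasite_present = TRUE)
  expect_equal(d[["y_R"]], 0.2)
  # any node at 1 with only activating inputs: dy/dt = -phi
  m2 <- list(mu = c(mu_ES_R = 1, mu_EN_R = 1, mu_ES_C = 1, mu_EN_C = 1,
                    mu_ES_EN = 1, mu_EN_ES = 1), mu_RP = 1)
  d <- activity_derivative(c(1, 1, 1), m2, phi = 0.3, parasite_present = TRUE)
  expect_equal(unname(d), rep(-0.3, 3))
  # agrees with the independently coded field on random states
  set.seed(22)
  for (i in 1:100) {
    mi <- random_interactions()
    y <- runif(3)
    expect_equal(unname(activity_derivative(y, mi, 0.3, TRUE)),
                 oracle_field(y, mi$mu, mi$mu_RP, TRUE, 0.3))
  }
})

test_that("single-input nodes reach the closed-form equilibrium", {
  # y_R = mu/(phi + mu) for an activating single input with y_P = 1
  m <- list(mu = rep(0, 6), mu_RP = 0.2)
  expect_equal(solve_equilibrium(m, phi = 0.3, parasite_present = TRUE)$y[["y_R"]],
               0.2 / (0.3 + 0.2), tolerance = 1e-7)
  m$mu_RP <- 1
  expect_equal(solve_equilibrium(m, phi = 0.3, parasite_present = TRUE)$y[["y_R"]],
               1 / 1.3, tolerance = 1e-7)
  # effectors fed only by C with mu = +1 each: y = 1/(phi + 1)
  m3 <- list(mu = c(mu_ES_R = 0, mu_EN_R = 0, mu_ES_C = 1, mu_EN_C = 1,
                    mu_ES_EN = 0, mu_EN_ES = 0), mu_RP = 0)
  y <- solve_equilibrium(m3, phi = 0.3)$y
  expect_equal(unname(y[c("y_ES", "y_EN")]), rep(1 / 1.3, 2), tolerance = 1e-7)
  # inhibiting single input decays to zero
  m$mu_RP <- -1
  expect_equal(solve_equilibrium(m, phi = 0.3, parasite_present = TRUE)$y[["y_R"]],
               0, tolerance = 1e-7)
})

test_that("solver equilibria are fixed points and agree with long-time RK4", {
  set.seed(23)
  for (i in 1:150) {
    m <- random_interactions()
    parasite <- i %% 2 == 0
    r <- solve_equilibrium(m, phi = 0.3, parasite_present = parasite)
    expect_true(all(r$y >= 0 & r$y <= 1))
    # residual of the independently coded field at the returned state
    resid <- max(abs(oracle_field(r$y, m$mu, m$mu_RP, parasite, 0.3)))
    expect_lt(resid, 1e-8)
    ref <- oracle_rk4(m$mu, m$mu_RP, parasite, 0.3)
    expect_lt(max(abs(r$y - ref)), 1e-6)
  }
})

test_that("constitutive and induced states follow the infection narrative", {
  set.seed(24)
  h <- random_genome("host")
  y0 <- constitutive_state(h)
  expect_equal(y0[["y_R"]], 0, tolerance = 1e-7)  # no input without P
  # an undetected parasite (specific mismatch) leaves the state unchanged
  p_escape <- row_to_genome(
    c(rep(0L, 10), rep(0L, 10), 1L - h$R$S_I), "parasite")
  expect_identical(induced_state(h, p_escape, "specific"),
                   constitutive_state(h))
  # detection from the constitutive state matches detection from rest
  set.seed(25)
  for (i in 1:50) {
    h <- random_genome("host"); p <- random_genome("parasite")
    m <- build_interactions(h, p, "nonspecific")
    a <- solve_equilibrium(m, parasite_present = TRUE,
                           init = constitutive_state(h))$y
    b <- solve_equilibrium(m, parasite_present = TRUE)$y
    expect_lt(max(abs(a - b)), 1e-7)  # 10 * tol uniqueness probe
  }
  # a receptor that inhibits both effectors cannot induce them
  L <- 10L
  seqs <- function(S_I, S_O) list(S_N = rep(0L, L), S_I = S_I, S_O = S_O)
  ones <- rep(1L, L); zeros <- rep(0L, L)
  h2 <- structure(list(
    R = seqs(ones, ones),        # receptor output all ones
    C = seqs(zeros, ones),       # C activates nothing relevant here
    E_S = seqs(zeros, zeros),    # effector inputs all zeros: mu(E<-R) = -1
    E_N = seqs(zeros, zeros)), class = "host_genome")
  p_match <- row_to_genome(c(zeros, zeros, ones), "parasite")
  y0 <- constitutive_state(h2)
  ys <- induced_state(h2, p_match, "specific")
  expect_lte(ys[["y_ES"]] - y0[["y_ES"]], 1e-9)
  expect_lte(ys[["y_EN"]] - y0[["y_EN"]], 1e-9)
})

test_that("solver agrees with an independent adaptive integrator", {
  skip_if_not_installed("deSolve")
  set.seed(26)
  for (i in 1:25) {
    m <- random_interactions()
    r <- solve_equilibrium(m, phi = 0.3, parasite_present = TRUE)
    sol <- deSolve::ode(
      y = c(0, 0, 0), times = c(0, 400),
      func = function(t, y, parms)
        list(oracle_field(y, m$mu, m$mu_RP, TRUE, 0.3)),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
    expect_lt(max(abs(r$y - sol[2, 2:4])), 1e-6)
  }
})
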