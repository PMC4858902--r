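# Network topology: the receptor R receives input only from the parasite
# protein P (during infection); both effectors E_S and E_N receive input
# from R, from the constitutively active protein C, and from each other.
# C and P are source nodes held at activity 1; R, E_S, E_N are dynamic.

EDGE_NAMES <- c("mu_ES_R", "mu_EN_R", "mu_ES_C", "mu_EN_C",
                "mu_ES_EN", "mu_EN_ES")

#' Assemble the interaction matrix of a host network
#'
#' Applies the Hamming-distance matching rule to the six evolvable host
#' edges (E_S and E_N each receiving from R, C and the other effector)
#' and, when a parasite is supplied, the receptor-parasite specificity
#' rule.
#'
#' @param host a host genome ([random_genome()]).
#' @param parasite optional parasite genome.
#' @param receptor_mode `"specific"` or `"nonspecific"`; only used when
#'   a parasite is supplied.
#' @return list with `mu` (named numeric of the six host-edge
#'   coefficients, each in `[-1, 1]`) and `mu_RP` (receptor-parasite
#'   coefficient, `NA` when no parasite is supplied).
#' @export
build_interactions <- function(host, parasite = NULL,
                               receptor_mode = c("specific", "nonspecific")) {
  stopifnot(inherits(host, "host_genome"))
  mu <- c(
    interaction_coefficient(host$E_S$S_I, host$R$S_O),
    interaction_coefficient(host$E_N$S_I, host$R$S_O),
    interaction_coefficient(host$E_S$S_I, host$C$S_O),
    interaction_coefficient(host$E_N$S_I, host$C$S_O),
    interaction_coefficient(host$E_S$S_I, host$E_N$S_O),
    interaction_coefficient(host$E_N$S_I, host$E_S$S_O)
  )
  names(mu) <- EDGE_NAMES
  mu_RP <- NA_real_
  if (!is.null(parasite))
    mu_RP <- receptor_parasite_coefficient(host$R, parasite, receptor_mode)
  list(mu = mu, mu_RP = mu_RP)
}

#' Time derivative of the network activities
#'
#' Each dynamic protein deactivates spontaneously at rate `phi`; each
#' incoming edge from an active partner j contributes
#' `mu * y_j * (1 - y_i)` when activating (mu > 0) and `mu * y_j * y_i`
#' when inhibiting (mu < 0), which keeps all activities inside `[0, 1]`.
#' The source activities are fixed: `y_C = 1` always, `y_P = 1` while a
#' parasite is present.
#'
#' @param y named numeric `c(y_R, y_ES, y_EN)` of current activities.
#' @param interactions result of [build_interactions()].
#' @param phi spontaneous deactivation rate (> 0).
#' @param parasite_present logical; include the P -> R edge?
#' @return named numeric of `dy/dt` for `y_R`, `y_ES`, `y_EN`.
#' @export
activity_derivative <- function(y, interactions, phi = 0.3,
                                parasite_present = FALSE) {
  stopifnot(length(y) == 3L, phi > 0)
  mu_rp <- if (parasite_present) interactions$mu_RP else 0
  if (parasite_present && is.na(mu_rp))
    stop("parasite_present = TRUE requires mu_RP", call. = FALSE)
  cpp_derivative(as.numeric(y), as.numeric(interactions$mu),
                 as.numeric(mu_rp), parasite_present, phi)
}

#' Steady-state network activities
#'
#' Integrates the activity equations forward (fixed-step fourth-order
#' Runge-Kutta) from `init` until the largest time derivative falls
#' below `tol`, and returns the resulting equilibrium state.
#'
#' @inheritParams activity_derivative
#' @param init initial activities (default all zero).
#' @param tol convergence tolerance on `max |dy/dt|`.
#' @param t_max maximum integration time before giving up.
#' @param step integration step size.
#' @return list with `y` (named activities in `[0, 1]`), `residual`,
#'   `steps` and `converged`.
#' @export
solve_equilibrium <- function(interactions, phi = 0.3,
                              parasite_present = FALSE,
                              init = c(y_R = 0, y_ES = 0, y_EN = 0),
                              tol = 1e-8, t_max = 1000, step = 0.05) {
  stopifnot(tol > 0, phi > 0)
  mu_rp <- if (parasite_present) interactions$mu_RP else 0
  if (parasite_present && (is.null(mu_rp) || is.na(mu_rp)))
    stop("parasite_present = TRUE requires mu_RP", call. = FALSE)
  res <- cpp_solve_equilibrium(as.numeric(interactions$mu),
                               as.numeric(mu_rp), parasite_present,
                               as.numeric(init), phi, step, tol, t_max)
  if (!res$converged)
    warning(sprintf("equilibrium not reached within t_max (residual %.3g)",
                    res$residual), call. = FALSE)
  res
}

#' Constitutive and induced network states of a host
#'
#' `constitutive_state` solves the network without a parasite, starting
#' from all-zero activities (the receptor, having no input, decays to
#' zero). `induced_state` solves the network with the parasite protein
#' held at activity 1, starting from the constitutive equilibrium; the
#' induced component of each effector is the difference between the two
#' states.
#'
#' @param host a host genome.
#' @param phi spontaneous deactivation rate.
#' @param ... passed to [solve_equilibrium()] (`tol`, `t_max`, `step`).
#' @return named numeric activities `c(y_R, y_ES, y_EN)`.
#' @export
constitutive_state <- function(host, phi = 0.3, ...) {
  m <- build_interactions(host)
  solve_equilibrium(m, phi = phi, parasite_present = FALSE, ...)$y
}

#' @rdname constitutive_state
#' @param parasite a parasite genome.
#' @param receptor_mode `"specific"` or `"nonspecific"`.
#' @export
induced_state <- function(host, parasite,
                          receptor_mode = c("specific", "nonspecific"),
                          phi = 0.3, ...) {
  m <- build_interactions(host, parasite, receptor_mode)
  y0 <- constitutive_state(host, phi = phi, ...)
  if (m$mu_RP == 0) return(y0)  # undetected parasite changes nothing
  solve_equilibrium(m, phi = phi, parasite_present = TRUE, init = y0, ...)$y
}
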