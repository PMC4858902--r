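# Efficacy, cost, survival and fitness (host and parasite) for one
# host-parasite evaluation. All pure functions of effector activities
# and the defence parameters.

#' Efficacy and cost of effector deployment
#'
#' Efficacy sums each effector's activity weighted by its
#' parasite-elimination coefficient (`E = xi_S * y_ES + xi_N * y_EN`);
#' cost is the marginal expression cost times total effector activity
#' (`C = kappa * (y_ES + y_EN)`). Applied to the constitutive
#' equilibrium this gives (E0, C0), to the induced equilibrium
#' (Estar, Cstar).
#'
#' @param y_ES,y_EN effector activities in `[0, 1]`.
#' @param xi_S,xi_N effector-parasite efficacy coefficients (see
#'   [effector_parasite_efficacy()]).
#' @param kappa marginal cost of effector expression.
#' @return list with `E` and `C`.
#' @export
efficacy_and_cost <- function(y_ES, y_EN, xi_S, xi_N, kappa) {
  stopifnot(kappa >= 0)
  list(E = xi_S * y_ES + xi_N * y_EN, C = kappa * (y_ES + y_EN))
}

#' Survival of an infected host
#'
#' The infection has two phases: a fraction `delta` of it passes before
#' the induced response is mounted, during which the host is protected
#' only by its constitutive defence; the remainder is spent under the
#' induced defence. In each phase survival is the product of the cost
#' factor `1 - C` and the escape-from-virulence factor
#' `1 - nu * exp(-E)`, and the phase factors combine as a
#' geometric mean weighted by phase duration:
#' `sstar = ((1-C0)(1-nu e^-E0))^delta * ((1-C*)(1-nu e^-E*))^(1-delta)`.
#' Each phase factor is floored at zero before exponentiation so that
#' ruinously costly defence yields zero survival rather than an
#' undefined power.
#'
#' @param E0,C0 constitutive efficacy and cost.
#' @param Estar,Cstar induced efficacy and cost.
#' @param nu maximum virulence in `[0, 1)`; default 0.99, so a host
#'   whose immune system fails entirely loses 99 % of its fitness.
#' @param delta relative induction delay in `[0, 1]`.
#' @return survival probability in `[0, 1]`.
#' @export
survival_infected <- function(E0, C0, Estar, Cstar, nu = 0.99, delta) {
  stopifnot(delta >= 0, delta <= 1, nu >= 0, nu < 1)
  f0 <- pmax(0, (1 - C0) * (1 - nu * exp(-E0)))
  fs <- pmax(0, (1 - Cstar) * (1 - nu * exp(-Estar)))
  f0^delta * fs^(1 - delta)
}

#' Host fitness
#'
#' Pre-infection survival `s0 = 1 - C0` (floored at 0) is paid by every
#' host; a challenged host additionally survives the infection with
#' probability `sstar`, so overall fitness is `s0 * sstar`.
#'
#' @param C0 constitutive cost.
#' @param sstar infected survival ([survival_infected()]); ignored when
#'   `challenged = FALSE`.
#' @param challenged was the host challenged by a parasite?
#' @return fitness in `[0, 1]`.
#' @export
host_fitness <- function(C0, sstar = NULL, challenged = FALSE) {
  s0 <- pmax(0, 1 - C0)
  if (!challenged) return(s0)
  s0 * sstar
}

#' Parasite fitness
#'
#' Proportional to the probability of successful infection: the parasite
#' must evade the constitutive defence for a fraction `delta` of the
#' infection and the induced defence for the rest, giving
#' `W = exp(-(delta * E0 + (1 - delta) * Estar))`.
#'
#' @param E0,Estar constitutive and induced efficacy of the host it
#'   encountered.
#' @param delta relative induction delay.
#' @return fitness in `(0, 1]` for finite non-negative efficacies.
#' @export
parasite_fitness <- function(E0, Estar, delta) {
  stopifnot(delta >= 0, delta <= 1)
  exp(-(delta * E0 + (1 - delta) * Estar))
}
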