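# Per-generation and cross-replicate summaries: effector activity
# decomposition, receptor detection, parasite diversity, evolved edge
# strengths, and consensus-based divergence rates.

#' Mean pairwise genetic distance of a parasite population
#'
#' Mean Hamming distance over all unordered pairs of individuals. By
#' default the distance is computed on the functional domains only
#' (input + output, 2L bits), since the neutral reference sequence adds
#' only noise; `sequences = "all"` includes it. The all-pairs mean is
#' computed exactly in O(N * L) through the per-site allele-frequency
#' identity `sum_sites n1 * n0 / choose(N, 2)`; `sample_pairs` instead
#' estimates it from that many random pairs (a cross-check, and an
#' option for the neutral-inclusive variant on huge populations).
#'
#' @param parasites parasite bit matrix (`3*L` columns).
#' @param sequences `"functional"` (default) or `"all"`.
#' @param sample_pairs `NULL` for the exact all-pairs mean, or a number
#'   of random pairs to sample.
#' @return mean pairwise Hamming distance (0 for a monomorphic
#'   population).
#' @export
parasite_pairwise_diversity <- function(parasites,
                                        sequences = c("functional", "all"),
                                        sample_pairs = NULL) {
  sequences <- match.arg(sequences)
  L <- ncol(parasites) %/% 3L
  cols <- if (sequences == "functional") (L + 1L):(3L * L)
          else seq_len(3L * L)
  n <- nrow(parasites)
  if (n < 2L) return(0)
  if (is.null(sample_pairs))
    return(cpp_mean_pairwise_distance(parasites, cols[1L], length(cols)))
  i <- sample.int(n, sample_pairs, replace = TRUE)
  j <- sample.int(n - 1L, sample_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
  mean(rowSums(parasites[i, cols, drop = FALSE] !=
               parasites[j, cols, drop = FALSE]))
}

#' Decompose effector activity into constitutive and induced components
#'
#' The constitutive component of each effector is its equilibrium
#' activity without a parasite, averaged over all hosts; the induced
#' component is the increase upon detection (`ystar - y0`), averaged
#' over challenged hosts only. With no challenged hosts the induced
#' means are `NA` (missing, not zero).
#'
#' @param constitutive matrix of constitutive equilibria (columns
#'   `y_R`, `y_ES`, `y_EN`), one row per host.
#' @param components per-pair components data frame from
#'   [evaluate_generation()], or `NULL` when no host was challenged.
#' @return list with `constitutive` (mean y0 per effector), `induced`
#'   (mean ystar - y0 per effector over challenged hosts) and
#'   `receptor` (mean induced receptor activity over challenged hosts,
#'   the detection rate signal).
#' @export
activity_decomposition <- function(constitutive, components = NULL) {
  cons <- c(E_S = mean(constitutive[, "y_ES"]),
            E_N = mean(constitutive[, "y_EN"]))
  if (is.null(components) || nrow(components) == 0L) {
    ind <- c(E_S = NA_real_, E_N = NA_real_)
    rec <- NA_real_
  } else {
    ind <- c(E_S = mean(components$ystar_ES - components$y0_ES),
             E_N = mean(components$ystar_EN - components$y0_EN))
    rec <- mean(components$ystar_R)
  }
  list(constitutive = cons, induced = ind, receptor = rec)
}

#' Mean evolved interaction strength per host edge
#'
#' Averages the matching-rule coefficient over all hosts for each of the
#' six evolvable edges (E_S and E_N each receiving from R, C and the
#' other effector).
#'
#' @param hosts host bit matrix (`12*L` columns).
#' @param L sequence length.
#' @return named numeric of length 6 (order `mu_ES_R`, `mu_EN_R`,
#'   `mu_ES_C`, `mu_EN_C`, `mu_ES_EN`, `mu_EN_ES`), each in `[-1, 1]`.
#' @export
edge_strengths <- function(hosts, L = 10L) {
  edge_in <- c("E_S", "E_N", "E_S", "E_N", "E_S", "E_N")
  edge_out <- c("R", "R", "C", "C", "E_N", "E_S")
  mu <- vapply(seq_along(edge_in), function(e) {
    a <- hosts[, seq_cols(edge_in[e], "S_I", L), drop = FALSE]
    b <- hosts[, seq_cols(edge_out[e], "S_O", L), drop = FALSE]
    mean(1 - 2 * rowSums(a != b) / L)
  }, numeric(1L))
  names(mu) <- EDGE_NAMES
  mu
}

#' Population consensus sequence
#'
#' Majority bit per position (ties resolve to 0), the same convention
#' the simulation engine records.
#'
#' @param pop bit matrix.
#' @return integer vector of consensus bits.
#' @export
consensus_bits <- function(pop) {
  as.integer(2 * colSums(pop) > nrow(pop))
}

#' Consensus divergence rates per protein and sequence class
#'
#' For each protein and each sequence class (neutral reference, input
#' domain, output domain), the Hamming distance of the population
#' consensus at each recorded generation from the consensus at a
#' reference generation, divided by the generations elapsed. The
#' neutral reference sequence has no phenotypic effect, so its rate is
#' the neutral benchmark; an excess of the input/output rate over it
#' signals adaptive evolution in the interaction domains.
#'
#' @param consensus bit matrix of consensus sequences, one row per
#'   recorded generation (e.g. `sim$parasite_consensus`).
#' @param generations integer vector of the recorded generations
#'   (`sim$consensus_generations`).
#' @param kind `"host"` or `"parasite"`.
#' @param reference_generation generation to diverge from; defaults to
#'   the first recorded one.
#' @return data frame with columns `generation`, `protein`, `class`
#'   (`S_N`/`S_I`/`S_O`), `hamming` and `rate` (substitutions per
#'   generation; rows at the reference generation have rate 0).
#' @export
divergence_rates <- function(consensus, generations,
                             kind = c("host", "parasite"),
                             reference_generation = NULL) {
  kind <- match.arg(kind)
  proteins <- if (kind == "host") HOST_PROTEINS else "P"
  L <- ncol(consensus) %/% (3L * length(proteins))
  if (is.null(reference_generation)) reference_generation <- generations[1L]
  r <- match(reference_generation, generations)
  if (is.na(r)) stop("reference generation was not recorded", call. = FALSE)
  ref <- consensus[r, ]
  out <- expand.grid(generation = generations, protein = proteins,
                     class = SEQ_CLASSES, stringsAsFactors = FALSE)
  out$hamming <- mapply(function(g, p, s) {
    cols <- seq_cols(p, s, L)
    sum(consensus[match(g, generations), cols] != ref[cols])
  }, out$generation, out$protein, out$class)
  dt <- out$generation - reference_generation
  out$rate <- ifelse(dt > 0, out$hamming / dt, 0)
  out[order(out$generation, out$protein, out$class), ]
}

#' Consensus substitution flux per protein and sequence class
#'
#' Total number of consensus bit changes between successive recorded
#' generations, per generation elapsed. Unlike [divergence_rates()],
#' which measures net distance from a reference consensus and therefore
#' saturates when selection repeatedly sweeps a domain back and forth,
#' the path-length flux keeps counting and is the better measure of the
#' rate of molecular evolution under sustained antagonistic
#' coevolution. Under neutrality both measures agree in expectation
#' across sequence classes.
#'
#' @inheritParams divergence_rates
#' @return data frame with columns `protein`, `class`, `substitutions`
#'   (total consensus changes over the recorded window) and `rate`
#'   (substitutions per generation).
#' @export
divergence_flux <- function(consensus, generations,
                            kind = c("host", "parasite")) {
  kind <- match.arg(kind)
  proteins <- if (kind == "host") HOST_PROTEINS else "P"
  L <- ncol(consensus) %/% (3L * length(proteins))
  span <- max(generations) - min(generations)
  out <- expand.grid(protein = proteins, class = SEQ_CLASSES,
                     stringsAsFactors = FALSE)
  out$substitutions <- mapply(function(p, s) {
    cols <- seq_cols(p, s, L)
    sum(abs(diff(consensus[, cols, drop = FALSE])))
  }, out$protein, out$class)
  out$rate <- if (span > 0) out$substitutions / span else 0
  out
}

#' Adaptive divergence signal
#'
#' Functional-class divergence rate minus the neutral-class rate at the
#' last recorded generation, per protein: positive values indicate the
#' interaction domains accumulate consensus substitutions faster than
#' the neutral benchmark.
#'
#' @param rates output of [divergence_rates()] or [divergence_flux()].
#' @return data frame with columns `protein`, `neutral_rate`,
#'   `functional_rate` (mean of the input- and output-domain rates) and
#'   `adaptive_signal`.
#' @export
adaptive_signal <- function(rates) {
  last <- if ("generation" %in% names(rates))
    rates[rates$generation == max(rates$generation), ]
  else rates
  by_p <- split(last, last$protein)
  out <- do.call(rbind, lapply(by_p, function(d) {
    data.frame(protein = d$protein[1L],
               neutral_rate = d$rate[d$class == "S_N"],
               functional_rate = mean(d$rate[d$class %in% c("S_I", "S_O")]))
  }))
  out$adaptive_signal <- out$functional_rate - out$neutral_rate
  rownames(out) <- NULL
  out
}

#' Aggregate replicate simulations
#'
#' Per-replicate post-burn-in means of every summary column, then mean
#' and standard error across replicates, matching how replicate bands
#' are reported.
#'
#' @param reps result of [run_replicates()], or its `summary` data
#'   frame.
#' @param burn_in generations to discard (defaults to the config's
#'   `burn_in` when `reps` is a `run_replicates()` result).
#' @return data frame with one row per summary statistic: `mean`, `se`
#'   and `n_replicates`.
#' @export
summarize_replicates <- function(reps, burn_in = NULL) {
  if (is.list(reps) && !is.data.frame(reps)) {
    if (is.null(burn_in)) burn_in <- reps$config$burn_in
    tab <- reps$summary
  } else tab <- reps
  if (is.null(burn_in)) stop("burn_in must be supplied", call. = FALSE)
  tab <- tab[tab$generation > burn_in, , drop = FALSE]
  stats <- setdiff(names(tab), c("replicate", "generation"))
  per_rep <- aggregate(tab[stats], by = list(replicate = tab$replicate),
                       FUN = function(x) mean(x, na.rm = TRUE))
  n <- nrow(per_rep)
  data.frame(
    statistic = stats,
    mean = vapply(stats, function(s) mean(per_rep[[s]]), numeric(1L)),
    se = vapply(stats, function(s)
      if (n > 1L) stats::sd(per_rep[[s]]) / sqrt(n) else NA_real_,
      numeric(1L)),
    n_replicates = n, row.names = NULL)
}
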