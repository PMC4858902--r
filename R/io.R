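# Configuration files, tabular output and deterministic test fixtures.

#' Load a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unspecified keys take
#' the model defaults, unknown keys and out-of-range values raise
#' descriptive errors. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML key-value file.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Write / read a per-generation summary table as TSV
#'
#' Deterministic column order, header row, fixed float formatting;
#' a write-then-read round trip reproduces the table within float
#' precision. Tables from [run_replicates()] carry a `replicate` column
#' and rows sorted by (replicate, generation).
#'
#' @param summaries data frame of per-generation summaries
#'   (`sim$summary` or `reps$summary`).
#' @param path output file path.
#' @param digits significant digits for floating-point columns.
#' @export
write_generation_table <- function(summaries, path, digits = 10L) {
  tab <- summaries
  if ("replicate" %in% names(tab))
    tab <- tab[order(tab$replicate, tab$generation), , drop = FALSE]
  num <- vapply(tab, is.double, logical(1L))
  tab[num] <- lapply(tab[num], function(x) signif(x, digits))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_generation_table
#' @export
read_generation_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "NA")
}

#' Deterministic population fixtures
#'
#' Small populations with known properties, for tests and examples:
#' \describe{
#'   \item{`"perfect_match_host"`}{a monomorphic host population whose
#'     input domains all equal the matching output domains, so all six
#'     edge coefficients are 1.}
#'   \item{`"mismatch_host"`}{the complementary case: all six
#'     coefficients are -1.}
#'   \item{`"escaped_parasite"`}{a monomorphic parasite population whose
#'     output domain is the complement of a given receptor input domain,
#'     so the specific receptor coefficient is 0.}
#'   \item{`"two_genotype_parasite"`}{two parasite genotypes at equal
#'     frequency differing at `k` functional sites.}
#'   \item{`"random_host"` / `"random_parasite"`}{seeded random
#'     populations.}
#' }
#'
#' @param kind fixture name.
#' @param n population size.
#' @param L sequence length.
#' @param seed integer seed (fixtures are deterministic given it).
#' @param k number of differing sites for `"two_genotype_parasite"`.
#' @param receptor_S_I receptor input domain to escape from, for
#'   `"escaped_parasite"` (default all ones).
#' @return a population bit matrix.
#' @export
make_fixture <- function(kind = c("perfect_match_host", "mismatch_host",
                                  "escaped_parasite",
                                  "two_genotype_parasite", "random_host",
                                  "random_parasite"),
                         n = 10L, L = 10L, seed = 1L, k = 4L,
                         receptor_S_I = rep(1L, L)) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind %in% c("random_host", "random_parasite"))
    return(random_population(n, sub("random_", "", kind), L))
  if (kind %in% c("perfect_match_host", "mismatch_host")) {
    ones <- rep(1L, L)
    domain_out <- ones
    domain_in <- if (kind == "perfect_match_host") ones else 1L - ones
    protein <- function(S_I, S_O) c(random_bits(L), S_I, S_O)
    row <- c(protein(domain_in, domain_out),  # R
             protein(domain_in, domain_out),  # C
             protein(domain_in, domain_out),  # E_S
             protein(domain_in, domain_out))  # E_N
    return(matrix(rep(row, each = n), nrow = n))
  }
  if (kind == "escaped_parasite") {
    row <- c(random_bits(L), random_bits(L), 1L - as_bits(receptor_S_I))
    return(matrix(rep(row, each = n), nrow = n))
  }
  # two_genotype_parasite: genotypes differ at the first k functional
  # (input-domain) sites, half the population each
  base <- c(random_bits(L), random_bits(L), random_bits(L))
  alt <- base
  flip <- L + seq_len(k)
  alt[flip] <- 1L - alt[flip]
  n1 <- n %/% 2L
  rbind(matrix(rep(base, each = n1), nrow = n1),
        matrix(rep(alt, each = n - n1), nrow = n - n1))
}
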