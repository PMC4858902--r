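#' @useDynLib immunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif aggregate sd
#' @importFrom utils write.table read.table
NULL

# Protein and sequence ordering shared with the compiled engine.
# A host genome carries four proteins, a parasite a single one; every
# protein is encoded by three bitstrings of common length L: a neutral
# reference S_N, an input domain S_I and an output domain S_O.
HOST_PROTEINS <- c("R", "C", "E_S", "E_N")
SEQ_CLASSES <- c("S_N", "S_I", "S_O")

#' Random bitstring
#'
#' Each bit is drawn independently as 0 or 1 with probability 1/2.
#'
#' @param L sequence length (default 10).
#' @return integer vector of 0/1 of length `L`.
#' @export
random_bits <- function(L = 10L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("L must be a positive integer", call. = FALSE)
  sample(0:1, L, replace = TRUE)
}

#' Hamming distance between two bitstrings
#'
#' @param a,b equal-length integer vectors of 0/1 (or character strings of
#'   '0'/'1', which are converted).
#' @return integer count of differing positions, in `[0, L]`.
#' @export
hamming <- function(a, b) {
  a <- as_bits(a); b <- as_bits(b)
  if (length(a) != length(b))
    stop("bitstrings must have equal length", call. = FALSE)
  sum(a != b)
}

as_bits <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  x <- as.integer(x)
  if (any(is.na(x)) || any(x != 0L & x != 1L))
    stop("bits must be 0 or 1", call. = FALSE)
  x
}

#' Interaction coefficient from sequence matching
#'
#' Strength of the directed interaction of an output domain on an input
#' domain: `mu = 1 - 2*H/L`, where H is the Hamming distance between the
#' two domains. Positive (activating) when more than half the bits match,
#' negative (inhibiting) below 50 % match.
#'
#' @param S_I input domain of the downstream protein.
#' @param S_O output domain of the upstream protein.
#' @return numeric in `[-1, 1]`.
#' @export
interaction_coefficient <- function(S_I, S_O) {
  S_I <- as_bits(S_I); S_O <- as_bits(S_O)
  if (length(S_I) != length(S_O))
    stop("bitstrings must have equal length", call. = FALSE)
  1 - 2 * hamming(S_I, S_O) / length(S_I)
}

# All-or-nothing specific coefficient: 1 when the sequence match 1 - H/L
# is at least 60 %, else 0. Integer comparison avoids floating-point
# trouble at the threshold (for L = 10: H <= 4 activates).
specific_coefficient <- function(H, L) {
  as.numeric(5 * (L - H) >= 3 * L)
}

#' Receptor-parasite interaction coefficient
#'
#' In `"nonspecific"` mode the receptor responds to any parasite with the
#' constant low coefficient 0.2. In `"specific"` mode recognition is
#' all-or-nothing: the coefficient is 1 when the sequence match between
#' the receptor input domain and the parasite output domain is at least
#' 60 %, and 0 otherwise.
#'
#' @param receptor a protein (list with `S_N`, `S_I`, `S_O`), e.g.
#'   `host$R`.
#' @param parasite a parasite genome as returned by
#'   [random_genome()] with `kind = "parasite"`.
#' @param mode `"specific"` or `"nonspecific"`.
#' @return numeric coefficient: 0.2, or 0/1.
#' @export
receptor_parasite_coefficient <- function(receptor, parasite,
                                          mode = c("specific", "nonspecific")) {
  mode <- match.arg(mode)
  if (mode == "nonspecific") return(0.2)
  H <- hamming(receptor$S_I, parasite$P$S_O)
  specific_coefficient(H, length(as_bits(receptor$S_I)))
}

#' Effector-parasite efficacy coefficient
#'
#' The non-specific effector E_N eliminates any parasite with constant
#' efficacy 0.2. The specific effector E_S has efficacy 1 against
#' parasites whose input domain matches its output domain at 60 % or
#' better, and 0 otherwise.
#'
#' @param effector a protein (list with `S_N`, `S_I`, `S_O`).
#' @param parasite a parasite genome.
#' @param which `"E_S"` or `"E_N"`.
#' @return numeric efficacy: 0.2, or 0/1.
#' @export
effector_parasite_efficacy <- function(effector, parasite,
                                       which = c("E_S", "E_N")) {
  which <- match.arg(which)
  if (which == "E_N") return(0.2)
  H <- hamming(parasite$P$S_I, effector$S_O)
  specific_coefficient(H, length(as_bits(effector$S_O)))
}

#' Random genome
#'
#' A host genome holds four proteins (receptor R, constitutive protein C,
#' specific effector E_S, non-specific effector E_N); a parasite genome a
#' single protein P. Every protein carries a neutral reference sequence
#' `S_N`, an input domain `S_I` and an output domain `S_O`, all of length
#' `L` and drawn uniformly at random.
#'
#' @param kind `"host"` or `"parasite"`.
#' @param L sequence length (default 10).
#' @return a list of proteins with class `"host_genome"` or
#'   `"parasite_genome"`.
#' @export
random_genome <- function(kind = c("host", "parasite"), L = 10L) {
  kind <- match.arg(kind)
  rp <- function() list(S_N = random_bits(L), S_I = random_bits(L),
                        S_O = random_bits(L))
  if (kind == "host") {
    g <- list(R = rp(), C = rp(), E_S = rp(), E_N = rp())
    class(g) <- "host_genome"
  } else {
    g <- list(P = rp())
    class(g) <- "parasite_genome"
  }
  g
}

n_bits <- function(genome) 3L * length(genome) *
  length(as_bits(genome[[1L]]$S_N))

#' Mutate a genome
#'
#' With probability `rate` the individual receives exactly one point
#' mutation: a single bit, chosen uniformly among all its bitstring
#' positions (host: 12 L; parasite: 3 L), is flipped. Otherwise the
#' genome is returned unchanged. The default rate of 0.01 corresponds to
#' 1 % of individuals mutating per generation.
#'
#' @param genome a host or parasite genome.
#' @param rate per-individual, per-generation mutation probability.
#' @return a genome of the same shape.
#' @export
mutate_genome <- function(genome, rate = 0.01) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (rate == 0 || runif(1L) >= rate) return(genome)
  L <- length(as_bits(genome[[1L]]$S_N))
  pos <- sample.int(n_bits(genome), 1L) - 1L
  p <- pos %/% (3L * L) + 1L
  s <- (pos %% (3L * L)) %/% L + 1L
  k <- pos %% L + 1L
  genome[[p]][[s]][k] <- 1L - genome[[p]][[s]][k]
  genome
}

#' Recombine two host genomes
#'
#' Free recombination between, but never within, proteins: each of the
#' four proteins of the offspring is copied intact (all three sequences
#' together) from one parent or the other with probability 1/2.
#'
#' @param parent_a,parent_b host genomes.
#' @return a host genome.
#' @export
recombine_genomes <- function(parent_a, parent_b) {
  stopifnot(inherits(parent_a, "host_genome"), inherits(parent_b, "host_genome"))
  pick <- runif(4L) < 0.5
  g <- lapply(seq_len(4L), function(p)
    if (pick[p]) parent_a[[p]] else parent_b[[p]])
  names(g) <- HOST_PROTEINS
  class(g) <- "host_genome"
  g
}

# ---- population matrix representation ------------------------------------
# Populations are stored as integer matrices of 0/1 bits, one row per
# individual: host rows have 12*L columns (proteins R, C, E_S, E_N; within
# each protein S_N, S_I, S_O), parasite rows 3*L columns (S_N, S_I, S_O).

#' Column indices of one sequence in a population bit matrix
#'
#' @param protein for hosts one of `"R"`, `"C"`, `"E_S"`, `"E_N"`; for
#'   parasites `"P"`.
#' @param seq one of `"S_N"`, `"S_I"`, `"S_O"`.
#' @param L sequence length.
#' @return integer vector of column indices.
#' @export
seq_cols <- function(protein, seq, L = 10L) {
  s <- match(seq, SEQ_CLASSES) - 1L
  if (identical(protein, "P")) p <- 0L
  else p <- match(protein, HOST_PROTEINS) - 1L
  if (is.na(p) || is.na(s)) stop("unknown protein or sequence", call. = FALSE)
  (p * 3L + s) * L + seq_len(L)
}

#' Random populations as bit matrices
#'
#' @param n number of individuals.
#' @param kind `"host"` or `"parasite"`.
#' @param L sequence length.
#' @return integer matrix with `n` rows and `12*L` (host) or `3*L`
#'   (parasite) columns of 0/1 bits.
#' @export
random_population <- function(n, kind = c("host", "parasite"), L = 10L) {
  kind <- match.arg(kind)
  b <- if (kind == "host") 12L * L else 3L * L
  matrix(sample(0:1, n * b, replace = TRUE), nrow = n, ncol = b)
}

#' Convert between genome lists and bit-matrix rows
#'
#' @param genome a host or parasite genome.
#' @return integer vector (the matrix row).
#' @export
genome_to_row <- function(genome) {
  unlist(lapply(genome, function(p) c(as_bits(p$S_N), as_bits(p$S_I),
                                      as_bits(p$S_O))), use.names = FALSE)
}

#' @rdname genome_to_row
#' @param row integer vector of bits.
#' @param kind `"host"` or `"parasite"`.
#' @export
row_to_genome <- function(row, kind = c("host", "parasite")) {
  kind <- match.arg(kind)
  np <- if (kind == "host") 4L else 1L
  L <- length(row) %/% (3L * np)
  stopifnot(length(row) == 3L * np * L)
  g <- lapply(seq_len(np) - 1L, function(p) {
    list(S_N = as.integer(row[p * 3L * L + seq_len(L)]),
         S_I = as.integer(row[p * 3L * L + L + seq_len(L)]),
         S_O = as.integer(row[p * 3L * L + 2L * L + seq_len(L)]))
  })
  names(g) <- if (kind == "host") HOST_PROTEINS else "P"
  class(g) <- paste0(kind, "_genome")
  g
}

#' Write / read genome populations as plain text
#'
#' One line per sequence of '0'/'1' characters, three lines per protein
#' (S_N, S_I, S_O), proteins in fixed order, individuals concatenated.
#' A header line `# kind n L` makes the file self-describing.
#'
#' @param pop population bit matrix (see [random_population()]).
#' @param kind `"host"` or `"parasite"`.
#' @param path file path.
#' @export
write_genomes <- function(pop, kind = c("host", "parasite"), path) {
  kind <- match.arg(kind)
  np <- if (kind == "host") 4L else 1L
  L <- ncol(pop) %/% (3L * np)
  lines <- c(sprintf("# %s %d %d", kind, nrow(pop), L),
             unlist(lapply(seq_len(nrow(pop)), function(i)
               vapply(seq_len(3L * np), function(s)
                 paste(pop[i, (s - 1L) * L + seq_len(L)], collapse = ""),
                 character(1L)))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genomes
#' @return `read_genomes` returns a list with `pop` (bit matrix), `kind`
#'   and `L`.
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#\\s*", "", lines[1L]), "\\s+")[[1L]]
  kind <- hdr[1L]; n <- as.integer(hdr[2L]); L <- as.integer(hdr[3L])
  np <- if (kind == "host") 4L else 1L
  body <- lines[-1L]
  stopifnot(length(body) == n * 3L * np)
  pop <- matrix(0L, nrow = n, ncol = 3L * np * L)
  for (i in seq_len(n)) {
    for (s in seq_len(3L * np)) {
      pop[i, (s - 1L) * L + seq_len(L)] <-
        as_bits(body[(i - 1L) * 3L * np + s])
    }
  }
  list(pop = pop, kind = kind, L = L)
}
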