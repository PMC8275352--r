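#' Configuration for the synthetic bipartite-motif benchmark
#'
#' Describes an in-silico enrichment experiment: random background
#' oligomers plus an enriched set in which two motif cores, separated by a
#' stochastically drawn linker, are implanted. Defaults emulate a 40-nt
#' random oligomer library with 2000 sequences per set, cores `AAA` and
#' `CCC`, and a negative-binomial linker `NB(r = 4, p = 0.4)` whose mode is
#' 4 nt (in the 3-5 nt range). `core_a` / `core_b` may be vectors of
#' variants, sampled uniformly per sequence, to emulate degenerate motifs.
#'
#' @param n_enriched,n_background Set sizes (default 2000 each).
#' @param length Sequence length in nt (default 40).
#' @param core_a,core_b Character vector(s) of core variants over ACGU.
#' @param linker List with `family` (`"nbinom"` for the negative binomial
#'   matching the binding model, or `"binom"`), and parameters `r`
#'   (size) and `p` (probability).
#' @param composition Background nucleotide probabilities, named `A,C,G,U`
#'   (default uniform).
#' @param seed Integer seed.
#' @return An object of class `bmf_synthetic_config`.
#' @export
synthetic_config <- function(n_enriched = 2000, n_background = 2000,
                             length = 40,
                             core_a = "AAA", core_b = "CCC",
                             linker = list(family = "nbinom", r = 4, p = 0.4),
                             composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, U = 0.25),
                             seed = 1L) {
  stopifnot(n_enriched >= 1, n_background >= 1, length >= 1,
            is.character(core_a), is.character(core_b),
            all(nchar(core_a) > 0), all(nchar(core_b) > 0))
  core_a <- normalize_sequence(core_a)
  core_b <- normalize_sequence(core_b)
  if (!all(strsplit(paste0(c(core_a, core_b), collapse = ""), "")[[1]] %in%
           BMF_ALPHABET)) {
    stop("cores must be sequences over A, C, G, U")
  }
  linker$family <- match.arg(linker$family, c("nbinom", "binom"))
  stopifnot(linker$r > 0, linker$p > 0, linker$p < 1)
  composition <- check_composition(composition)
  if (max(nchar(core_a)) + max(nchar(core_b)) > length) {
    stop("cores do not fit in the sequence length")
  }
  structure(list(n_enriched = as.integer(n_enriched),
                 n_background = as.integer(n_background),
                 length = as.integer(length),
                 core_a = core_a, core_b = core_b, linker = linker,
                 composition = composition, seed = as.integer(seed)),
            class = "bmf_synthetic_config")
}

check_composition <- function(composition) {
  if (is.null(names(composition))) names(composition) <- BMF_ALPHABET
  composition <- composition[BMF_ALPHABET]
  if (anyNA(composition) || any(composition < 0) || sum(composition) <= 0) {
    stop("composition must be non-negative probabilities for A, C, G, U")
  }
  composition / sum(composition)
}

#' Sample random background sequences
#'
#' `n` i.i.d. sequences of length `L`, positions drawn i.i.d. from the
#' given nucleotide composition.
#'
#' @param n Number of sequences.
#' @param L Sequence length.
#' @param composition Named nucleotide probabilities (default uniform).
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return Character vector of `n` sequences.
#' @export
sample_background <- function(n, L, composition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, U = 0.25),
                              seed = NULL) {
  stopifnot(n >= 1, L >= 1)
  composition <- check_composition(composition)
  draw <- function() {
    letters <- sample(BMF_ALPHABET, n * L, replace = TRUE, prob = composition)
    apply(matrix(letters, nrow = n, ncol = L), 1L, paste0, collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

draw_gap <- function(linker) {
  switch(linker$family,
         nbinom = rnbinom(1L, size = linker$r, prob = linker$p),
         binom = rbinom(1L, size = linker$r, prob = linker$p))
}

#' Implant a bipartite motif into sequences
#'
#' For each sequence: draw a core-A variant, a core-B variant and a linker
#' gap `d` from the linker law; choose a start uniformly among positions
#' where `core_a + d + core_b` fits; overwrite the existing letters (so
#' lengths are unchanged) with core A, `d` untouched background letters and
#' core B. Core A is always upstream of core B. Gaps that cannot fit are
#' re-drawn (at most `max_retries` times, then the call fails).
#'
#' @param sequences Character vector of host sequences.
#' @param core_a,core_b Character vector(s) of core variants.
#' @param linker Linker law, as in [synthetic_config()].
#' @param seed Optional integer seed.
#' @param max_retries Redraw attempts per sequence for oversized gaps.
#' @return Character vector with implanted motifs; same lengths as input.
#' @export
implant_motifs <- function(sequences, core_a, core_b,
                           linker = list(family = "nbinom", r = 4, p = 0.4),
                           seed = NULL, max_retries = 100L) {
  sequences <- normalize_sequence(sequences)
  core_a <- normalize_sequence(core_a)
  core_b <- normalize_sequence(core_b)
  draw <- function() {
    vapply(sequences, function(s) {
      L <- nchar(s)
      a <- core_a[[sample.int(length(core_a), 1L)]]
      b <- core_b[[sample.int(length(core_b), 1L)]]
      la <- nchar(a); lb <- nchar(b)
      if (la + lb > L) stop("cores do not fit in a sequence of length ", L)
      d <- draw_gap(linker)
      tries <- 0L
      while (la + d + lb > L) {
        tries <- tries + 1L
        if (tries > max_retries) {
          stop(sprintf(paste0("could not draw a linker gap fitting a ",
                              "length-%d sequence after %d attempts"),
                       L, max_retries))
        }
        d <- draw_gap(linker)
      }
      block <- la + d + lb
      start <- sample.int(L - block + 1L, 1L)
      substr(s, start, start + la - 1L) <- a
      substr(s, start + la + d, start + block - 1L) <- b
      s
    }, character(1L), USE.NAMES = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic enrichment benchmark
#'
#' Background set: random sequences. Enriched set: an independent fresh
#' background sample with the bipartite motif implanted in every sequence.
#' The two sets use disjoint RNG streams derived from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A [bmf_dataset()].
#' @export
make_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "bmf_synthetic_config"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 3L))
  background <- sample_background(config$n_background, config$length,
                                  config$composition, seed = seeds[1L])
  host <- sample_background(config$n_enriched, config$length,
                            config$composition, seed = seeds[2L])
  enriched <- implant_motifs(host, config$core_a, config$core_b,
                             config$linker, seed = seeds[3L])
  bmf_dataset(enriched = enriched, background = background)
}
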