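#' Normalize nucleotide sequences to the RNA alphabet
#'
#' Case-folds to upper case and maps DNA thymine to uracil (`T` -> `U`).
#' Characters outside `{A,C,G,U}` (e.g. `N`) are kept as-is; downstream,
#' any k-mer window containing such a character contributes statistical
#' weight zero to the partition sum.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length over the RNA alphabet.
#' @export
#' @examples
#' normalize_sequence(c("acgt", "ANGU"))
normalize_sequence <- function(x) {
  stopifnot(is.character(x))
  chartr("T", "U", toupper(x))
}

# Single source of truth for the lexicographic nucleotide order A<C<G<U.
BMF_ALPHABET <- c("A", "C", "G", "U")

#' All k-mers in lexicographic order
#'
#' Lexicographic order with `A < C < G < U`, i.e. base-4 encoding with
#' `A=0, C=1, G=2, U=3`. This order indexes every energy vector and is
#' stable across the model file format.
#'
#' @param k Core length (positive integer).
#' @return Character vector of length `4^k`.
#' @export
kmer_strings <- function(k) {
  stopifnot(k >= 1)
  # expand.grid varies its first factor fastest; the last character of a
  # lexicographically ordered k-mer is the fastest-varying one.
  grid <- expand.grid(rep(list(BMF_ALPHABET), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

#' Encode a sequence as k-mer window indices
#'
#' Returns, for each window start `s = 1..L-k+1`, the 0-based lexicographic
#' index of the k-mer starting there (base-4, `A=0, C=1, G=2, U=3`).
#' The empty vector is returned when `L < k`.
#'
#' @param seq A single sequence (character scalar); normalized internally
#'   via [normalize_sequence()].
#' @param k Core length.
#' @param ambiguous `"error"` rejects any character outside `{A,C,G,U}`
#'   (naming position and character); `"mask"` encodes windows covering such
#'   characters as `-1`, the convention used by the partition-function DP
#'   (those windows get statistical weight 0).
#' @return Integer vector of 0-based k-mer indices (or `-1` for masked
#'   windows), one per window start.
#' @export
#' @examples
#' encode_sequence("ACGU", 2) # AC, CG, GU -> 1, 6, 11
encode_sequence <- function(seq, k, ambiguous = c("error", "mask")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1)
  seq <- normalize_sequence(seq)
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  digits <- match(chars, BMF_ALPHABET) - 1L # NA for ambiguous characters
  if (ambiguous == "error" && anyNA(digits)) {
    bad <- which(is.na(digits))[1L]
    stop(sprintf("invalid character '%s' at position %d (alphabet ACGU)",
                 chars[bad], bad))
  }
  if (L < k) return(integer(0))
  n <- L - k + 1L
  idx <- rep(0, n)
  masked <- rep(FALSE, n)
  for (j in seq_len(k)) {
    d <- digits[j:(j + n - 1L)]
    masked <- masked | is.na(d)
    idx <- idx * 4 + ifelse(is.na(d), 0, d)
  }
  idx[masked] <- -1L
  as.integer(idx)
}

# Encode a vector of sequences for the C++ batch DP (ambiguous masked).
encode_batch <- function(seqs, k) {
  lapply(seqs, encode_sequence, k = k, ambiguous = "mask")
}
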