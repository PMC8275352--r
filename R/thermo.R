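#' Effective concentration of domain B at linker distance d
#'
#' `cB(d) = cAB + S * NB(d; r, p)` with `cAB = 1` fixed and `NB` the
#' negative binomial pmf (gamma-generalized to non-integer `r`). `d` is the
#' number of nucleotides strictly between the two core binding sites.
#'
#' @param d Non-negative integer distance(s).
#' @param spacer [spacer_params()].
#' @return Numeric vector of concentrations, all `>= 1`.
#' @export
#' @examples
#' sp <- spacer_from_natural(r = 1, p = 0.2, S = 10000)
#' effective_concentration(0, sp) # 1 + 10000 * 0.2^1 = 2001
effective_concentration <- function(d, spacer) {
  stopifnot(inherits(spacer, "spacer_params"), all(d >= 0), all(d == floor(d)))
  S <- spacer_s(spacer)
  if (S == 0) return(rep(1, length(d)))
  1 + S * dnbinom(d, size = spacer_r(spacer), prob = spacer_p(spacer))
}

#' Partition sum over all binding configurations (dynamic programming)
#'
#' Computes, for one sequence, the sum of statistical weights of all
#' configurations of zero, one or more proteins bound to the RNA. The DP
#' state `ZA(i)` accumulates configurations whose last placement is domain A
#' ending at position `i`; `ZB(i)` accumulates configurations with nothing
#' bound at `i` or domain B bound with right edge at or upstream of `i`.
#' The unbound configuration has weight 1, so `Z >= 1` always.
#'
#' Arithmetic is in linear space; per-position statistical weights are
#' deterministically capped at `1e250` and the `overflow` flag is set when
#' the cap is hit (results are then saturated lower bounds).
#' Windows containing ambiguous characters (anything outside `ACGU` after
#' T->U normalization) contribute statistical weight 0.
#'
#' @param seq A single sequence (character scalar).
#' @param model A [bmf_model()].
#' @return An object of class `bmf_dp`: list with `Z` (partition sum),
#'   `ZA`, `ZB` (length-L statistical-weight vectors) and `overflow`.
#' @export
forward_partition <- function(seq, model) {
  stopifnot(inherits(model, "bmf_model"))
  seq <- normalize_sequence(seq)
  L <- nchar(seq)
  win <- encode_sequence(seq, model$k, ambiguous = "mask")
  res <- cpp_dp_single(win, L, model$k,
                       model$core_a$energies, model$core_b$energies,
                       model$spacer$rho, model$spacer$pi, model$spacer$log_s,
                       gradient = FALSE)
  structure(list(Z = res$Z, ZA = res$ZA, ZB = res$ZB,
                 overflow = res$overflow),
            class = "bmf_dp")
}

#' @export
print.bmf_dp <- function(x, ...) {
  cat(sprintf("<bmf_dp> Z = %.6g, p(bound) = %.6g%s\n", x$Z, 1 - 1 / x$Z,
              if (x$overflow) " [weight cap hit]" else ""))
  invisible(x)
}

#' Probability that a sequence is bound by at least one protein
#'
#' `p(bound | x) = 1 - 1/Z(x)`: one minus the normalized weight of the
#' unbound configuration. Vectorized over sequences.
#'
#' @param seq Character vector of sequences.
#' @param model A [bmf_model()].
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
binding_probability <- function(seq, model) {
  stopifnot(inherits(model, "bmf_model"))
  seq <- normalize_sequence(seq)
  enc <- encode_batch(seq, model$k)
  res <- cpp_dp_batch(enc, nchar(seq), model$k,
                      model$core_a$energies, model$core_b$energies,
                      model$spacer$rho, model$spacer$pi, model$spacer$log_s,
                      gradient = FALSE)
  1 - 1 / res$Z
}

#' Partition sum by exhaustive configuration enumeration (oracle)
#'
#' Brute-force sum over every binding configuration, used as an independent
#' check of [forward_partition()]. A configuration is an ordered list of
#' non-overlapping k-length placements, each labelled A or B. Scanning left
#' to right: an A placement weighs `cAB * exp(-EA)`; a B placement whose
#' immediately preceding placement is an A is that A's partner and weighs
#' `cB(d) * exp(-EB)` with `d` the number of nucleotides strictly between
#' them; a B preceded by nothing or by a B weighs `cAB * exp(-EB)`. The
#' empty configuration has weight 1. Only intended for short sequences.
#'
#' @param seq A single sequence, length at most `max_len`.
#' @param model A [bmf_model()].
#' @param max_len Enumeration limit (default 16); longer input is refused.
#' @return The partition sum (numeric scalar `>= 1`).
#' @export
enumerate_partition <- function(seq, model, max_len = 16L) {
  stopifnot(inherits(model, "bmf_model"))
  seq <- normalize_sequence(seq)
  L <- nchar(seq)
  if (L > max_len) {
    stop(sprintf("sequence length %d exceeds enumeration limit %d", L, max_len))
  }
  k <- model$k
  if (L < k) return(1)
  win <- encode_sequence(seq, k, ambiguous = "mask")
  wA <- ifelse(win >= 0, exp(-model$core_a$energies[win + 1L]), 0)
  wB <- ifelse(win >= 0, exp(-model$core_b$energies[win + 1L]), 0)
  cB <- effective_concentration(0:max(L - 2 * k, 0), model$spacer)
  n_start <- L - k + 1L
  # recursive enumeration: sum over all completions with next placement
  # starting at or after `s`, given the label and end of the last placement
  rec <- function(s, last_label, last_end) {
    total <- 1 # stop here: no further placements
    if (s > n_start) return(total)
    for (t in s:n_start) {
      # place A at t (free; weight cAB = 1 times Boltzmann factor)
      if (wA[t] > 0) {
        total <- total + wA[t] * rec(t + k, "A", t + k - 1L)
      }
      # place B at t: paired iff the immediately preceding placement is an A
      if (wB[t] > 0) {
        w <- if (identical(last_label, "A")) {
          cB[t - last_end] * wB[t] # d = t - last_end - 1 gap positions
        } else {
          wB[t]
        }
        total <- total + w * rec(t + k, "B", t + k - 1L)
      }
    }
    total
  }
  rec(1L, NULL, 0L)
}
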