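#' Per-domain k-mer binding-energy table
#'
#' Holds one binding energy (in units of kBT; kBT = 1 throughout) for every
#' one of the `4^k` k-mers, indexed in lexicographic order `A < C < G < U`
#' (see [kmer_strings()]). Lower energy means stronger binding.
#'
#' @param energies Numeric vector of length `4^k`, all finite.
#' @param k Core length.
#' @return An object of class `energy_table`.
#' @export
energy_table <- function(energies, k) {
  stopifnot(k >= 1, is.numeric(energies))
  if (length(energies) != 4^k) {
    stop(sprintf("energies must have length 4^k = %d, got %d",
                 4^k, length(energies)))
  }
  if (!all(is.finite(energies))) stop("all energies must be finite")
  structure(list(k = as.integer(k), energies = as.numeric(energies)),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("<energy_table> k = %d (%d k-mers), energy range [%.3f, %.3f] kBT\n",
              x$k, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Spacer (linker) parameters of the effective-concentration model
#'
#' The effective concentration of domain B at distance `d` nucleotides
#' downstream of a bound domain A is
#' `cB(d) = cAB + S * NB(d; r, p)`, with the free-protein concentration
#' `cAB` fixed to 1 and `NB` the negative binomial pmf
#' `choose(d+r-1, d) p^r (1-p)^d` (gamma-generalized for non-integer `r`).
#' Parameters are stored unconstrained: `exp(rho) = r`,
#' `p = 1/(1 + exp(-pi))`, `S = exp(log_s)` (so `log_s = -Inf` encodes
#' `S = 0`, switching cooperativity off).
#'
#' @param rho Unconstrained log of the NB size parameter `r`.
#' @param pi Unconstrained logit of the NB probability `p`.
#' @param log_s Log of the concentration scale `S >= 0`.
#' @return An object of class `spacer_params`.
#' @seealso [spacer_from_natural()] to construct from `(r, p, S)` directly.
#' @export
spacer_params <- function(rho, pi, log_s) {
  stopifnot(is.finite(rho), is.finite(pi), is.numeric(log_s),
            length(log_s) == 1L, !is.na(log_s), log_s < Inf)
  structure(list(rho = as.numeric(rho), pi = as.numeric(pi),
                 log_s = as.numeric(log_s)),
            class = "spacer_params")
}

#' @rdname spacer_params
#' @param r NB size parameter, positive.
#' @param p NB probability, strictly in `(0, 1)`.
#' @param S Concentration scale, `S >= 0`.
#' @export
spacer_from_natural <- function(r, p, S) {
  stopifnot(r > 0, p > 0, p < 1, S >= 0)
  spacer_params(rho = log(r), pi = qlogis(p), log_s = log(S))
}

#' @rdname spacer_params
#' @param spacer A `spacer_params` object.
#' @export
spacer_r <- function(spacer) exp(spacer$rho)

#' @rdname spacer_params
#' @export
spacer_p <- function(spacer) plogis(spacer$pi)

#' @rdname spacer_params
#' @export
spacer_s <- function(spacer) exp(spacer$log_s)

#' @export
print.spacer_params <- function(x, ...) {
  cat(sprintf("<spacer_params> r = %.4g, p = %.4g, S = %.4g (cAB = 1)\n",
              spacer_r(x), spacer_p(x), spacer_s(x)))
  invisible(x)
}

#' Bipartite motif model
#'
#' The full parameter set of the two-domain thermodynamic binding model:
#' one [energy_table()] per domain core (A binds upstream, B downstream)
#' and the [spacer_params()] governing the effective concentration of B as
#' a function of the linker distance.
#'
#' @param core_a,core_b [energy_table()]s of equal core length.
#' @param spacer [spacer_params()].
#' @return An object of class `bmf_model` with fields `core_a`, `core_b`,
#'   `spacer` and `k`.
#' @export
bmf_model <- function(core_a, core_b, spacer) {
  stopifnot(inherits(core_a, "energy_table"), inherits(core_b, "energy_table"),
            inherits(spacer, "spacer_params"))
  if (core_a$k != core_b$k) stop("both cores must have the same core length k")
  structure(list(core_a = core_a, core_b = core_b, spacer = spacer,
                 k = core_a$k),
            class = "bmf_model")
}

#' @export
print.bmf_model <- function(x, ...) {
  km <- kmer_strings(x$k)
  cat(sprintf("<bmf_model> k = %d\n", x$k))
  cat(sprintf("  core A: best k-mer %s (%.3f kBT)\n",
              km[which.min(x$core_a$energies)], min(x$core_a$energies)))
  cat(sprintf("  core B: best k-mer %s (%.3f kBT)\n",
              km[which.min(x$core_b$energies)], min(x$core_b$energies)))
  cat(sprintf("  spacer: r = %.4g, p = %.4g, S = %.4g\n",
              spacer_r(x$spacer), spacer_p(x$spacer), spacer_s(x$spacer)))
  invisible(x)
}

# --- flat parameter vector used by the optimizer and the gradient code ---
# layout: [EA(1..M), EB(1..M), rho, pi, log_s], M = 4^k

param_names <- function(k) {
  km <- kmer_strings(k)
  c(paste0("EA_", km), paste0("EB_", km), "rho", "pi", "log_s")
}

model_to_params <- function(model) {
  p <- c(model$core_a$energies, model$core_b$energies,
         model$spacer$rho, model$spacer$pi, model$spacer$log_s)
  names(p) <- param_names(model$k)
  p
}

params_to_model <- function(params, k) {
  M <- 4^k
  stopifnot(length(params) == 2 * M + 3)
  bmf_model(energy_table(params[seq_len(M)], k),
            energy_table(params[M + seq_len(M)], k),
            spacer_params(params[2 * M + 1], params[2 * M + 2],
                          params[2 * M + 3]))
}
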