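# Shared fixture builders; all randomness is seeded by the callers.

ALPH <- c("A", "C", "G", "U")

random_seq <- function(L) paste0(sample(ALPH, L, replace = TRUE),
                                 collapse = "")

# A random model whose energies are low enough (shift below the 12 kBT
# initialization) that several binding configurations carry visible weight.
random_model <- function(k, shift = 10, seed = NULL) {
  m <- initialize_model(k, seed = seed)
  m$core_a$energies <- m$core_a$energies - shift
  m$core_b$energies <- m$core_b$energies - shift
  m
}

# Straight-line transcription of the enrichment likelihood, evaluated term
# by term on tiny sequences with the brute-force enumeration oracle:
#   p(x | bound) = p_bg(x) (1 - 1/Z(x)) / sum_x' p_bg(x') (1 - 1/Z(x'))
#   LL           = sum_{x in X+} ln p(x | bound)
# Completely independent of the package's DP/likelihood code path.
transcribed_loglik <- function(enriched, background, model) {
  tab <- table(background)
  pbg <- as.numeric(tab) / length(background)
  names(pbg) <- names(tab)
  pbound <- function(x) 1 - 1 / enumerate_partition(x, model)
  denom <- sum(vapply(names(pbg), function(x) {
    pbg[[x]] * pbound(x)
  }, numeric(1)))
  sum(vapply(enriched, function(x) {
    log(pbg[[x]] * pbound(x) / denom)
  }, numeric(1)))
}

# Central finite differences of the log-likelihood w.r.t. the flat
# parameter vector.
fd_gradient <- function(dataset, model, h = 1e-5) {
  par <- bmf:::model_to_params(model)
  k <- model$k
  vapply(seq_along(par), function(i) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (log_likelihood(dataset, bmf:::params_to_model(pp, k)) -
       log_likelihood(dataset, bmf:::params_to_model(pm, k))) / (2 * h)
  }, numeric(1))
}

top1_kmer <- function(table) kmer_strings(table$k)[which.min(table$energies)]
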