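#' Boltzmann k-mer probabilities of one core
#'
#' `p(m) = exp(-E(m)) / sum_m' exp(-E(m'))`, computed stably by subtracting
#' the minimum energy before exponentiating.
#'
#' @param table An [energy_table()].
#' @return Named numeric vector over the `4^k` k-mers, summing to 1.
#' @export
boltzmann_probs <- function(table) {
  stopifnot(inherits(table, "energy_table"))
  w <- exp(-(table$energies - min(table$energies)))
  stats::setNames(w / sum(w), kmer_strings(table$k))
}

#' Top k-mers of a core, renormalized
#'
#' The `n` highest-probability k-mers (ties broken lexicographically), with
#' probabilities renormalized to sum to 1 over the selected `n` -- the
#' representation used to render motif logos.
#'
#' @param table An [energy_table()].
#' @param n How many k-mers (default 5).
#' @return Data frame with columns `kmer` and `prob` (summing to 1).
#' @export
top_kmers <- function(table, n = 5) {
  stopifnot(inherits(table, "energy_table"))
  if (n < 1 || n > 4^table$k) {
    stop(sprintf("n must be between 1 and 4^k = %d", 4^table$k))
  }
  p <- boltzmann_probs(table)
  ord <- order(-p, names(p))[seq_len(n)]
  data.frame(kmer = names(p)[ord], prob = unname(p[ord] / sum(p[ord])),
             stringsAsFactors = FALSE)
}

#' Spacer-length distribution of a model
#'
#' The pmf of the linker length `d` between the two cores is the normalized
#' negative-binomial component of the effective-concentration model (the
#' constant `cAB` term is free-protein concentration, not a spacer length,
#' and is excluded). `P(d > 0) = 1 - NB(0; r, p) = 1 - p^r`. By default
#' `d_max` is chosen so the reported tail mass is below `1e-6` (and at
#' least 100).
#'
#' @param spacer A [spacer_params()].
#' @param d_max Largest distance to tabulate; `NULL` for the default policy.
#' @return List with `d` (0..d_max), `pmf`, `p_gt0` and `tail_mass`
#'   (`1 - sum(pmf)`).
#' @export
spacer_distribution <- function(spacer, d_max = NULL) {
  stopifnot(inherits(spacer, "spacer_params"))
  r <- spacer_r(spacer)
  p <- spacer_p(spacer)
  if (is.null(d_max)) {
    d_max <- max(100L, qnbinom(1e-7, size = r, prob = p, lower.tail = FALSE))
  }
  stopifnot(d_max >= 0)
  d <- 0:d_max
  pmf <- dnbinom(d, size = r, prob = p)
  list(d = d, pmf = pmf, p_gt0 = 1 - p^r, tail_mass = max(0, 1 - sum(pmf)))
}

#' Classify a model as adjacent-core or bipartite
#'
#' A model is called bipartite when the probability of a spacer length
#' above zero, `P(d > 0) = 1 - p^r`, exceeds `threshold`; otherwise the two
#' cores are effectively adjacent (a single longer motif).
#'
#' @param model A [bmf_model()].
#' @param threshold Decision threshold on `P(d > 0)` (default 0.5).
#' @return `"bipartite"` or `"adjacent"`.
#' @export
classify_bipartite <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "bmf_model"))
  p_gt0 <- spacer_distribution(model$spacer, d_max = 0L)$p_gt0
  if (p_gt0 > threshold) "bipartite" else "adjacent"
}

#' Similarity of the two core motifs
#'
#' Pearson correlation between the Boltzmann k-mer probability vectors of
#' the two cores. Returns `NA` when either vector is constant (zero
#' variance, e.g. a uniform core), where the correlation is undefined.
#'
#' @param model A [bmf_model()].
#' @return Correlation in `[-1, 1]`, or `NA_real_`.
#' @export
core_similarity <- function(model) {
  stopifnot(inherits(model, "bmf_model"))
  pa <- boltzmann_probs(model$core_a)
  pb <- boltzmann_probs(model$core_b)
  if (stats::var(pa) == 0 || stats::var(pb) == 0) return(NA_real_)
  stats::cor(pa, pb)
}

# 4 x k positional nucleotide marginals of a core's Boltzmann distribution
positional_marginals <- function(table) {
  p <- boltzmann_probs(table)
  k <- table$k
  idx <- 0:(4^k - 1)
  m <- matrix(0, nrow = 4, ncol = k, dimnames = list(BMF_ALPHABET, NULL))
  for (pos in seq_len(k)) {
    digit <- (idx %/% 4^(k - pos)) %% 4
    for (n in 0:3) m[n + 1, pos] <- sum(p[digit == n])
  }
  m
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Motif sequence entropy (complexity)
#'
#' For each core, the Boltzmann k-mer probabilities are marginalized to a
#' nucleotide distribution at each of the `k` positions; the score is the
#' mean Shannon entropy (bits) over all `2k` positions. Near 2 for complex
#' (close-to-uniform) motifs, near 0 for degenerate/repetitive ones.
#'
#' @param model A [bmf_model()].
#' @return Entropy in bits per position, in `[0, 2]`.
#' @export
motif_entropy <- function(model) {
  stopifnot(inherits(model, "bmf_model"))
  ma <- positional_marginals(model$core_a)
  mb <- positional_marginals(model$core_b)
  mean(c(apply(ma, 2, shannon_bits), apply(mb, 2, shannon_bits)))
}

# The 16 repeat units: 4 mononucleotide + 12 ordered distinct dinucleotide.
repeat_units <- function() {
  mono <- BMF_ALPHABET
  di <- outer(BMF_ALPHABET, BMF_ALPHABET, paste0)
  di <- di[as.vector(outer(BMF_ALPHABET, BMF_ALPHABET, "!="))]
  c(mono, di)
}

#' Sequence repetitiveness of a model
#'
#' For each of the 16 repeat units `u` (4 mononucleotide, 12 dinucleotide),
#' `q_core(u)` is the Boltzmann probability mass on k-mers that are
#' substrings of the infinite repetition of `u`. The score is
#' `max_u sqrt(q_a(u) * q_b(u))`: high when both cores concentrate on
#' mono- or di-nucleotide repeats.
#'
#' @param model A [bmf_model()].
#' @return Repetitiveness in `[0, 1]`.
#' @export
repetitiveness <- function(model) {
  stopifnot(inherits(model, "bmf_model"))
  k <- model$k
  kmers <- kmer_strings(k)
  pa <- boltzmann_probs(model$core_a)
  pb <- boltzmann_probs(model$core_b)
  best <- 0
  for (u in repeat_units()) {
    rep_str <- strrep(u, k + 1L)
    mask <- vapply(kmers, function(m) grepl(m, rep_str, fixed = TRUE),
                   logical(1L))
    best <- max(best, sqrt(sum(pa[mask]) * sum(pb[mask])))
  }
  best
}

#' Entropy/repetitiveness distribution of random models
#'
#' Draws `n_samples` models via [initialize_model()] (with distinct
#' sub-seeds derived from `seed`) and records their [motif_entropy()] and
#' [repetitiveness()] -- the null distribution against which trained
#' models are compared.
#'
#' @param k Core length.
#' @param n_samples Number of random models.
#' @param seed Integer seed.
#' @return Data frame with columns `entropy` and `repetitiveness`.
#' @export
random_model_baseline <- function(k = 3, n_samples = 100, seed = 1L) {
  stopifnot(n_samples >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_samples))
  vals <- vapply(seeds, function(s) {
    m <- initialize_model(k, seed = s)
    c(motif_entropy(m), repetitiveness(m))
  }, numeric(2L))
  data.frame(entropy = vals[1L, ], repetitiveness = vals[2L, ])
}

#' Per-model motif summary
#'
#' Collects the post-hoc statistics of a trained model: full Boltzmann
#' probability vectors, top-5 k-mers per core (renormalized), spacer pmf
#' with `P(d > 0)` and tail mass, core similarity, entropy and
#' repetitiveness, plus the bipartite/adjacent call.
#'
#' @param model A [bmf_model()].
#' @param n_top How many top k-mers per core (default 5).
#' @param d_max Spacer tabulation limit (`NULL` = default policy, see
#'   [spacer_distribution()]).
#' @return An object of class `bmf_motif_summary`.
#' @export
motif_summary <- function(model, n_top = 5, d_max = NULL) {
  stopifnot(inherits(model, "bmf_model"))
  sp <- spacer_distribution(model$spacer, d_max = d_max)
  structure(list(k = model$k,
                 probs_a = boltzmann_probs(model$core_a),
                 probs_b = boltzmann_probs(model$core_b),
                 top_a = top_kmers(model$core_a, n_top),
                 top_b = top_kmers(model$core_b, n_top),
                 spacer = sp,
                 classification = classify_bipartite(model),
                 core_similarity = core_similarity(model),
                 entropy = motif_entropy(model),
                 repetitiveness = repetitiveness(model)),
            class = "bmf_motif_summary")
}

#' @export
print.bmf_motif_summary <- function(x, ...) {
  bar <- function(p) strrep("#", round(40 * p))
  cat(sprintf("Bipartite motif summary (k = %d)\n", x$k))
  cat(sprintf("  classification: %s (P(d>0) = %.3f)\n",
              x$classification, x$spacer$p_gt0))
  cat(sprintf("  core similarity %.3f | entropy %.3f bits | repetitiveness %.3f\n",
              x$core_similarity, x$entropy, x$repetitiveness))
  cat("  core A top k-mers:\n")
  for (i in seq_len(nrow(x$top_a))) {
    cat(sprintf("    %s %6.3f %s\n", x$top_a$kmer[i], x$top_a$prob[i],
                bar(x$top_a$prob[i])))
  }
  cat("  core B top k-mers:\n")
  for (i in seq_len(nrow(x$top_b))) {
    cat(sprintf("    %s %6.3f %s\n", x$top_b$kmer[i], x$top_b$prob[i],
                bar(x$top_b$prob[i])))
  }
  mode_d <- x$spacer$d[which.max(x$spacer$pmf)]
  cat(sprintf("  spacer: mode %d nt, P(d>0) = %.3f, tail mass %.2g\n",
              mode_d, x$spacer$p_gt0, x$spacer$tail_mass))
  invisible(x)
}

#' @description Plot method: three panels (top k-mers of each core as
#'   Boltzmann-probability bars, and the spacer pmf truncated at the last
#'   1% of mass).
#' @param x A `bmf_motif_summary`.
#' @param ... Ignored.
#' @rdname motif_summary
#' @export
plot.bmf_motif_summary <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(x$top_a$prob, names.arg = x$top_a$kmer, las = 2,
                    main = "core A", ylab = "probability")
  graphics::barplot(x$top_b$prob, names.arg = x$top_b$kmer, las = 2,
                    main = "core B", ylab = "probability")
  show <- which(cumsum(x$spacer$pmf) <= 0.99)
  show <- seq_len(max(5L, length(show) + 1L))
  graphics::plot(x$spacer$d[show], x$spacer$pmf[show], type = "h", lwd = 3,
                 xlab = "spacer length d (nt)", ylab = "probability",
                 main = sprintf("P(d>0) = %.2f", x$spacer$p_gt0))
  invisible(x)
}

#' Write a motif summary as tab-separated text
#'
#' Long-format TSV with one row per statistic (k-mer probabilities, spacer
#' pmf and scalar summaries), suitable for downstream tooling.
#'
#' @param summary A [motif_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motif_summary <- function(summary, path) {
  stopifnot(inherits(summary, "bmf_motif_summary"))
  rows <- rbind(
    data.frame(section = "core_a", key = names(summary$probs_a),
               value = unname(summary$probs_a)),
    data.frame(section = "core_b", key = names(summary$probs_b),
               value = unname(summary$probs_b)),
    data.frame(section = "spacer", key = as.character(summary$spacer$d),
               value = summary$spacer$pmf),
    data.frame(section = "summary",
               key = c("p_spacer_gt0", "tail_mass", "core_similarity",
                       "entropy", "repetitiveness"),
               value = c(summary$spacer$p_gt0, summary$spacer$tail_mass,
                         summary$core_similarity, summary$entropy,
                         summary$repetitiveness)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
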