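#' Enriched/background sequence dataset
#'
#' Container for the two sequence sets of an enrichment (SELEX-type)
#' experiment: the enriched (selected) set and the input/background library.
#' Background weights are the empirical fractions of each distinct
#' background sequence; duplicated reads share one entry with
#' proportionally larger weight (equivalently, each read carries weight
#' `1/M` -- both give identical likelihoods).
#'
#' @param enriched Character vector of enriched sequences (non-empty).
#' @param background Character vector of background sequences (non-empty).
#' @return An object of class `bmf_dataset` with fields `enriched`,
#'   `background` (reads, normalized), `background_unique` and
#'   `background_weights` (empirical fractions summing to 1).
#' @export
bmf_dataset <- function(enriched, background) {
  if (length(enriched) == 0) stop("enriched set must be non-empty")
  if (length(background) == 0) stop("background set must be non-empty")
  enriched <- normalize_sequence(enriched)
  background <- normalize_sequence(background)
  w <- background_weights(background)
  structure(list(enriched = enriched, background = background,
                 background_unique = names(w),
                 background_weights = unname(w)),
            class = "bmf_dataset")
}

#' @export
print.bmf_dataset <- function(x, ...) {
  cat(sprintf("<bmf_dataset> %d enriched, %d background (%d distinct)\n",
              length(x$enriched), length(x$background),
              length(x$background_unique)))
  invisible(x)
}

#' Empirical background sequence weights
#'
#' The fraction of each distinct sequence in the input library:
#' multiplicity divided by the total read count. Weights are positive and
#' sum to 1, and are invariant under replicating the whole library.
#'
#' @param background Character vector of background reads (non-empty).
#' @return Named numeric vector over distinct sequences, summing to 1.
#' @export
#' @examples
#' background_weights(c("AAA", "AAA", "CCC")) # AAA 2/3, CCC 1/3
background_weights <- function(background) {
  if (length(background) == 0) stop("background set must be non-empty")
  tab <- table(background)
  w <- as.numeric(tab) / length(background)
  names(w) <- names(tab)
  w
}

# Core likelihood/gradient assembly shared by log_likelihood,
# model_gradient and the SGD loop, on pre-encoded sequences.
# `wbg` are weights over the background entries summing to 1.
ll_core <- function(enc_pos, len_pos, enc_bg, len_bg, wbg, model, gradient) {
  k <- model$k
  n_pos <- length(enc_pos)
  rp <- cpp_dp_batch(enc_pos, len_pos, k,
                     model$core_a$energies, model$core_b$energies,
                     model$spacer$rho, model$spacer$pi, model$spacer$log_s,
                     gradient = gradient)
  rb <- cpp_dp_batch(enc_bg, len_bg, k,
                     model$core_a$energies, model$core_b$energies,
                     model$spacer$rho, model$spacer$pi, model$spacer$log_s,
                     gradient = gradient)
  Zp <- rp$Z
  Zb <- rb$Z
  if (any(Zp == 1)) {
    bad <- which(Zp == 1)[1L]
    warning(sprintf(paste0("enriched sequence %d has zero binding ",
                           "weight (Z = 1); log-likelihood is -Inf"), bad))
  }
  denom <- sum(wbg * (1 - 1 / Zb))
  ll <- sum(log(1 - 1 / Zp)) - n_pos * log(denom)
  out <- list(ll = ll)
  if (gradient) {
    gpos <- rp$grad %*% (1 / (Zp * (Zp - 1)))
    gbg <- rb$grad %*% (wbg / Zb^2)
    out$grad <- as.numeric(gpos - n_pos * gbg / denom)
    names(out$grad) <- param_names(k)
  }
  out
}

ll_and_grad <- function(pos, bg, wbg, model, gradient) {
  ll_core(encode_batch(pos, model$k), nchar(pos),
          encode_batch(bg, model$k), nchar(bg), wbg, model, gradient)
}

#' Log-likelihood of a model on an enrichment dataset
#'
#' For enriched sequences `x` and background fractions `p_bg`:
#' `LL = sum_x [ln p_bg(x)] + sum_x ln(1 - 1/Z(x))
#'       - N+ * ln sum_x' p_bg(x') (1 - 1/Z(x'))`.
#' The `ln p_bg(x)` term is constant in the model parameters and excluded
#' by default (`include_constant = FALSE`): enriched sequences need not
#' occur in the background library, where their empirical fraction would be
#' zero. With `include_constant = TRUE` the constant is added using the
#' empirical background fractions (`-Inf` for unseen sequences).
#'
#' @param dataset A [bmf_dataset()].
#' @param model A [bmf_model()].
#' @param include_constant Include the parameter-free `ln p_bg(x)` term?
#' @return Log-likelihood (numeric scalar; `-Inf`, with a warning naming
#'   the sequence, if an enriched sequence has `Z = 1` exactly).
#' @export
log_likelihood <- function(dataset, model, include_constant = FALSE) {
  stopifnot(inherits(dataset, "bmf_dataset"), inherits(model, "bmf_model"))
  res <- ll_and_grad(dataset$enriched, dataset$background_unique,
                     dataset$background_weights, model, gradient = FALSE)
  ll <- res$ll
  if (include_constant) {
    pbg <- dataset$background_weights[match(dataset$enriched,
                                            dataset$background_unique)]
    pbg[is.na(pbg)] <- 0
    ll <- ll + sum(log(pbg))
  }
  ll
}

#' Posterior probability of each background sequence being the bound one
#'
#' `p(x | bound) = p_bg(x) (1 - 1/Z(x)) / sum_x' p_bg(x') (1 - 1/Z(x'))`
#' over the distinct background sequences; sums to 1 by construction.
#'
#' @inheritParams log_likelihood
#' @return Named numeric vector over distinct background sequences.
#' @export
bound_posterior <- function(dataset, model) {
  stopifnot(inherits(dataset, "bmf_dataset"), inherits(model, "bmf_model"))
  pb <- binding_probability(dataset$background_unique, model)
  num <- dataset$background_weights * pb
  stats::setNames(num / sum(num), dataset$background_unique)
}

#' Analytic gradient of the log-likelihood
#'
#' Partial derivatives of [log_likelihood()] (constant term excluded) with
#' respect to every parameter: both energy tables and the unconstrained
#' spacer parameters `(rho, pi, log_s)`. Computed by propagating derivative
#' recursions alongside the partition-function DP, not by numerical
#' differentiation; deterministic for a fixed dataset.
#'
#' @inheritParams log_likelihood
#' @return Named numeric vector of length `2*4^k + 3`, in the order
#'   `EA_<kmer>..., EB_<kmer>..., rho, pi, log_s`.
#' @export
model_gradient <- function(dataset, model) {
  stopifnot(inherits(dataset, "bmf_dataset"), inherits(model, "bmf_model"))
  ll_and_grad(dataset$enriched, dataset$background_unique,
              dataset$background_weights, model, gradient = TRUE)$grad
}

#' Random model initialization
#'
#' All `2 * 4^k` binding energies are drawn i.i.d. Normal(mean 12, sd 1)
#' kBT -- in the range of experimentally observed binding energies, and
#' small enough Boltzmann factors to keep the linear-space DP far from
#' overflow at the start. The concentration scale is set to `S = 10^4`;
#' the NB size parameter is drawn from Uniform(1, 5) and the NB
#' probability from Uniform(0, 0.5).
#'
#' @param k Core length (default 3).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A [bmf_model()].
#' @export
initialize_model <- function(k = 3, seed = NULL) {
  draw <- function() {
    M <- 4^k
    eA <- rnorm(M, mean = 12, sd = 1)
    eB <- rnorm(M, mean = 12, sd = 1)
    r <- runif(1, 1, 5)
    p <- runif(1, 0, 0.5)
    bmf_model(energy_table(eA, k), energy_table(eB, k),
              spacer_from_natural(r = r, p = p, S = 1e4))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Training configuration
#'
#' ADAM hyperparameters and stopping rules for [bmf_train()]. Defaults:
#' learning rate 0.01, beta1 0.9, beta2 0.999, epsilon 1e-8, minibatch 512,
#' at most 1000 iterations, and convergence when the relative variation of
#' all four tracked statistics over the last 5 iterations falls below 0.03.
#'
#' @param learning_rate,beta1,beta2,epsilon ADAM hyperparameters.
#' @param minibatch_size Sequences per minibatch (enriched and background
#'   each); datasets smaller than this are used in full every iteration.
#' @param max_iterations Unconditional iteration cap.
#' @param variation_threshold,variation_window Convergence rule: stop when
#'   `(max - min) / |last|` over the last `variation_window` recorded values
#'   is below `variation_threshold` for the best-bound k-mer energy of each
#'   core and for `r` and `p`.
#' @param record_every Record the tracked statistics (and test convergence)
#'   every this many iterations. With the default ADAM step size a single
#'   iteration moves any statistic far less than the variation threshold,
#'   so the variation is measured across spaced-out snapshots.
#' @param rng_seed Integer seed controlling initialization and minibatch
#'   sampling.
#' @return An object of class `bmf_train_config`.
#' @export
train_config <- function(learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, minibatch_size = 512,
                         max_iterations = 1000, variation_threshold = 0.03,
                         variation_window = 5, record_every = 10,
                         rng_seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, minibatch_size >= 1, max_iterations >= 1,
            variation_threshold > 0, variation_window >= 2, record_every >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, minibatch_size = as.integer(minibatch_size),
                 max_iterations = as.integer(max_iterations),
                 variation_threshold = variation_threshold,
                 variation_window = as.integer(variation_window),
                 record_every = as.integer(record_every),
                 rng_seed = as.integer(rng_seed)),
            class = "bmf_train_config")
}

#' One ADAM update step (gradient ascent)
#'
#' Standard ADAM with bias correction, applied in the ascent direction
#' (`params + lr * m_hat / (sqrt(v_hat) + epsilon)`), since training
#' maximizes the log-likelihood.
#'
#' @param params Numeric parameter vector.
#' @param gradient Gradient of the objective being maximized (same shape).
#' @param state ADAM state as returned by [adam_init()] or a previous call.
#' @param config A [train_config()].
#' @return List with updated `params` and `state`.
#' @export
adam_update <- function(params, gradient, state, config) {
  stopifnot(length(params) == length(gradient),
            length(state$m) == length(params))
  t <- state$t + 1L
  m <- config$beta1 * state$m + (1 - config$beta1) * gradient
  v <- config$beta2 * state$v + (1 - config$beta2) * gradient^2
  m_hat <- m / (1 - config$beta1^t)
  v_hat <- v / (1 - config$beta2^t)
  params <- params + config$learning_rate * m_hat / (sqrt(v_hat) +
                                                     config$epsilon)
  list(params = params, state = list(m = m, v = v, t = t))
}

#' @rdname adam_update
#' @param n_params Number of parameters.
#' @export
adam_init <- function(n_params) {
  list(m = numeric(n_params), v = numeric(n_params), t = 0L)
}

#' Convergence test on the training trace
#'
#' For each tracked statistic (best-bound k-mer energy of each core, `r`,
#' `p`), the variation over the last `variation_window` recorded values is
#' `v = (max - min) / |last|`; training has converged when every `v` is
#' below `variation_threshold`. With fewer than `variation_window` recorded
#' iterations the answer is `FALSE`.
#'
#' @param trace A `bmf_trace` (or anything with a `stats` matrix whose rows
#'   are iterations).
#' @param config A [train_config()].
#' @return Logical scalar.
#' @export
has_converged <- function(trace, config) {
  stats <- trace$stats
  w <- config$variation_window
  if (is.null(stats) || nrow(stats) < w) return(FALSE)
  recent <- stats[nrow(stats) - w + seq_len(w), , drop = FALSE]
  last <- recent[w, ]
  spread <- apply(recent, 2, max) - apply(recent, 2, min)
  v <- ifelse(spread == 0, 0, spread / abs(last))
  all(v < config$variation_threshold)
}

# Epoch-wise minibatch sampler: without replacement within an epoch,
# reshuffled (from the current RNG stream) at each epoch boundary.
make_sampler <- function(n, batch) {
  batch <- min(batch, n)
  perm <- sample.int(n)
  ptr <- 0L
  function() {
    if (ptr + batch > n) {
      perm <<- sample.int(n)
      ptr <<- 0L
    }
    out <- perm[ptr + seq_len(batch)]
    ptr <<- ptr + batch
    out
  }
}

#' Train a bipartite motif model by stochastic gradient ascent
#'
#' Maximum-likelihood estimation of all model parameters with ADAM and
#' analytic gradients. Each iteration draws a minibatch of enriched
#' sequences and an independent, equally sized minibatch of background
#' sequences (the likelihood normalizer is computed over the background
#' minibatch with uniform weights -- a stochastic approximation of the
#' full-background normalizer, which keeps the per-iteration cost
#' proportional to the batch size). Minibatches are drawn without
#' replacement within an epoch and reshuffled between epochs. Training
#' stops when [has_converged()] fires or at `max_iterations`. Fully
#' reproducible from `config$rng_seed`.
#'
#' @param dataset A [bmf_dataset()].
#' @param k Core length (default 3).
#' @param config A [train_config()].
#' @param init Optional starting [bmf_model()]; by default drawn with
#'   [initialize_model()] from the training RNG stream.
#' @return List with elements `model` (the trained [bmf_model()]) and
#'   `trace` (class `bmf_trace`: per-iteration minibatch log-likelihood,
#'   tracked statistics, iteration count and termination reason).
#' @export
bmf_train <- function(dataset, k = 3, config = train_config(), init = NULL) {
  stopifnot(inherits(dataset, "bmf_dataset"),
            inherits(config, "bmf_train_config"))
  with_seed(config$rng_seed, {
    model <- init %||% initialize_model(k)
    stopifnot(model$k == k)
    params <- model_to_params(model)
    M <- 4^k
    state <- adam_init(length(params))
    n_pos <- length(dataset$enriched)
    n_bg <- length(dataset$background)
    next_pos <- make_sampler(n_pos, config$minibatch_size)
    next_bg <- make_sampler(n_bg, config$minibatch_size)
    enc_pos <- encode_batch(dataset$enriched, k)
    len_pos <- nchar(dataset$enriched)
    enc_bg <- encode_batch(dataset$background, k)
    len_bg <- nchar(dataset$background)

    loglik <- numeric(config$max_iterations)
    n_rec <- config$max_iterations %/% config$record_every
    stats <- matrix(NA_real_, nrow = n_rec, ncol = 4,
                    dimnames = list(NULL, c("ea_best", "eb_best", "r", "p")))
    recorded_at <- integer(n_rec)
    rec <- 0L
    termination <- "max_iterations"
    iterations <- 0L
    for (it in seq_len(config$max_iterations)) {
      ip <- next_pos()
      ib <- next_bg()
      cur <- params_to_model(params, k)
      res <- ll_core(enc_pos[ip], len_pos[ip], enc_bg[ib], len_bg[ib],
                     rep(1 / length(ib), length(ib)), cur, gradient = TRUE)
      upd <- adam_update(params, res$grad, state, config)
      params <- upd$params
      state <- upd$state
      loglik[it] <- res$ll
      iterations <- it
      if (it %% config$record_every == 0L) {
        rec <- rec + 1L
        stats[rec, ] <- c(min(params[seq_len(M)]),
                          min(params[M + seq_len(M)]),
                          exp(params[2 * M + 1]),
                          plogis(params[2 * M + 2]))
        recorded_at[rec] <- it
        if (has_converged(list(stats = stats[seq_len(rec), , drop = FALSE]),
                          config)) {
          termination <- "converged"
          break
        }
      }
    }
    loglik <- loglik[seq_len(iterations)]
    stats <- stats[seq_len(rec), , drop = FALSE]
    trace <- structure(list(loglik = loglik, stats = stats,
                            recorded_at = recorded_at[seq_len(rec)],
                            iterations = iterations,
                            termination = termination,
                            seed = config$rng_seed),
                       class = "bmf_trace")
    list(model = params_to_model(params, k), trace = trace)
  })
}

#' @export
print.bmf_trace <- function(x, ...) {
  cat(sprintf("<bmf_trace> %d iterations (%s), final minibatch LL %.4f\n",
              x$iterations, x$termination, tail(x$loglik, 1L)))
  invisible(x)
}
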