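test_that("background weights are empirical fractions", {
  w <- background_weights(c("AAA", "AAA", "CCC"))
  expect_equal(w[["AAA"]], 2 / 3)
  expect_equal(w[["CCC"]], 1 / 3)
  expect_equal(sum(w), 1)
  distinct <- c("ACG", "GGC", "UUA", "CAU")
  expect_equal(unname(background_weights(distinct)), rep(1 / 4, 4))
  # replication invariance
  expect_equal(background_weights(rep(distinct, 3)),
               background_weights(distinct))
  expect_error(background_weights(character(0)), "non-empty")
})

test_that("log-likelihood matches a term-by-term transcription", {
  set.seed(11)
  bg <- replicate(6, random_seq(8))
  enriched <- sample(bg, 4, replace = TRUE)
  ds <- bmf_dataset(enriched, bg)
  for (i in 1:3) {
    m <- random_model(2, shift = runif(1, 7, 10))
    expect_equal(log_likelihood(ds, m, include_constant = TRUE),
                 transcribed_loglik(enriched, bg, m), tolerance = 1e-9)
  }
})

test_that("likelihood closed forms: equal Z and single shared sequence", {
  # all background sequences same length + flat energy tables => equal Z,
  # so the binding factors cancel and LL reduces to the ln p_bg constants
  k <- 2
  m <- bmf_model(energy_table(rep(8, 16), k), energy_table(rep(8, 16), k),
                 spacer_from_natural(2, 0.3, 100))
  bg <- c("ACGUAC", "GGCAUU", "UUACGG", "CAGUCA") # distinct, uniform 1/4
  ds <- bmf_dataset(bg[c(1, 3)], bg)
  expect_equal(log_likelihood(ds, m), 0, tolerance = 1e-12)
  expect_equal(log_likelihood(ds, m, include_constant = TRUE),
               -2 * log(4), tolerance = 1e-12)
  ds1 <- bmf_dataset("ACGUAC", "ACGUAC")
  expect_equal(log_likelihood(ds1, m, include_constant = TRUE), 0,
               tolerance = 1e-12)
})

test_that("an enriched sequence with zero binding weight is reported", {
  m <- random_model(3, seed = 2)
  ds <- bmf_dataset(c("ACGUACGU", "NNNN"), c("ACGUACGU", "GGCAUCGA"))
  expect_warning(ll <- log_likelihood(ds, m), "sequence 2")
  expect_identical(ll, -Inf)
})

test_that("duplicating the background library leaves the likelihood fixed", {
  set.seed(19)
  bg <- replicate(5, random_seq(12))
  ds1 <- bmf_dataset(replicate(3, random_seq(12)), bg)
  ds2 <- bmf_dataset(ds1$enriched, rep(bg, 2))
  m <- random_model(2, seed = 4)
  expect_equal(log_likelihood(ds1, m), log_likelihood(ds2, m),
               tolerance = 1e-12)
})

test_that("the bound-sequence posterior normalizes over the background", {
  set.seed(23)
  for (i in 1:5) {
    ds <- bmf_dataset(replicate(4, random_seq(15)),
                      replicate(8, random_seq(15)))
    post <- bound_posterior(ds, random_model(3, shift = runif(1, 6, 10)))
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(post >= 0))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(41)
  for (i in 1:4) {
    ds <- bmf_dataset(replicate(sample(2:5, 1), random_seq(sample(6:20, 1))),
                      replicate(sample(3:6, 1), random_seq(sample(6:20, 1))))
    m <- random_model(2, shift = runif(1, 7, 10))
    g <- model_gradient(ds, m)
    fd <- fd_gradient(ds, m)
    scale <- pmax(abs(fd), 1e-6)
    expect_lt(max(abs(g - fd) / scale), 1e-4)
  }
})

test_that("gradient structure: unused k-mers and S = 0 give exact zeros", {
  ds <- bmf_dataset(c("AAAAAA", "AAACAA"), c("AAAAAA", "AAAGAA"))
  m <- random_model(2, seed = 6)
  g <- model_gradient(ds, m)
  expect_identical(unname(g["EA_UU"]), 0) # UU occurs nowhere
  expect_identical(unname(g["EB_GC"]), 0)
  m$spacer <- spacer_params(m$spacer$rho, m$spacer$pi, -Inf)
  g0 <- model_gradient(ds, m)
  expect_identical(unname(g0["rho"]), 0)
  expect_identical(unname(g0["pi"]), 0)
})

test_that("initialization follows the documented distributions", {
  m <- initialize_model(3, seed = 99)
  expect_equal(spacer_s(m$spacer), 1e4, tolerance = 1e-12)
  expect_gte(spacer_r(m$spacer), 1)
  expect_lte(spacer_r(m$spacer), 5)
  expect_gt(spacer_p(m$spacer), 0)
  expect_lt(spacer_p(m$spacer), 0.5)
  e <- c(m$core_a$energies, m$core_b$energies)
  expect_lt(abs(mean(e) - 12), 5 / sqrt(length(e)))
  m2 <- initialize_model(3, seed = 99)
  expect_identical(m, m2)
  expect_false(identical(initialize_model(3, seed = 100), m))
})

test_that("ADAM takes learning-rate-sized bias-corrected first steps", {
  cfg <- train_config()
  st <- adam_init(3)
  par <- c(1, 2, 3)
  up0 <- adam_update(par, c(0, 0, 0), st, cfg)
  expect_identical(up0$params, par)
  g <- c(0.5, -2, 1e-3)
  up1 <- adam_update(par, g, st, cfg)
  step <- up1$params - par
  expect_equal(unname(step), cfg$learning_rate * sign(g), tolerance = 1e-3)
  expect_identical(up1$state$t, 1L)
  # defaults are the stated hyperparameters
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  expect_equal(cfg$epsilon, 1e-8)
  expect_equal(cfg$minibatch_size, 512L)
  expect_equal(cfg$max_iterations, 1000L)
})

test_that("variation-based convergence follows the printed rule", {
  cfg <- train_config()
  flat <- matrix(2, nrow = 5, ncol = 4)
  expect_true(has_converged(list(stats = flat), cfg))
  one_moving <- flat
  one_moving[, 2] <- c(1, 1, 1, 1, 2) # v = (2-1)/2 = 0.5
  expect_false(has_converged(list(stats = one_moving), cfg))
  expect_false(has_converged(list(stats = flat[1:4, , drop = FALSE]), cfg))
})

test_that("training is reproducible and ascends the likelihood", {
  set.seed(55)
  enriched <- paste0(substr(replicate(40, random_seq(14)), 1, 5), "AAA",
                     substr(replicate(40, random_seq(14)), 1, 6))
  bg <- replicate(40, random_seq(14))
  ds <- bmf_dataset(enriched, bg)
  cfg <- train_config(max_iterations = 60, rng_seed = 3L)
  fit1 <- bmf_train(ds, k = 2, config = cfg)
  fit2 <- bmf_train(ds, k = 2, config = cfg)
  expect_identical(fit1$trace$stats, fit2$trace$stats)
  expect_identical(fit1$model, fit2$model)
  # full-batch here (dataset < minibatch): smoothed LL must increase
  ll <- fit1$trace$loglik
  expect_gt(mean(tail(ll, 5)), mean(head(ll, 5)))
})
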