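test_that("choice log-likelihood has the right limits and composition", {
  trials <- random_trials(30, seed = 2)
  ll0 <- choice_loglikelihood(trials, "reward", c(alpha = 0.5, beta = 0))
  expect_equal(ll0, rep(log(0.5), 30))
  # engineered belief path: after learning good -> 0.65 and bad -> 0.35
  # (alpha = 1), the third trial's good choice has softmax prob ~0.927
  tr <- data.frame(chosen_arm = c("good", "bad", "good"),
                   reward = c(65, 35, 50))
  ll <- choice_loglikelihood(tr, "reward", c(alpha = 1, beta = 8.48))
  expect_equal(ll[3], log(1 / (1 + exp(-8.48 * 0.30))))
  expect_equal(round(exp(ll[3]), 3), 0.927)
})

test_that("WAIC matches a brute-force computation and its invariances", {
  # identical draws: no penalty
  ll_same <- matrix(log(0.5), nrow = 4, ncol = 10)
  w <- waic(ll_same)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * 10 * log(0.5))
  # hand-computed 3-draw x 2-trial case
  ll <- matrix(log(c(0.5, 0.6, 0.7, 0.2, 0.3, 0.4)), nrow = 3)
  lppd_brute <- log(mean(c(0.5, 0.6, 0.7))) + log(mean(c(0.2, 0.3, 0.4)))
  p_brute <- var(log(c(0.5, 0.6, 0.7))) + var(log(c(0.2, 0.3, 0.4)))
  w2 <- waic(ll)
  expect_equal(w2$lppd, lppd_brute)
  expect_equal(w2$p_waic, p_brute)
  expect_equal(w2$waic, -2 * (lppd_brute - p_brute))
  # invariant to reordering of draws
  expect_equal(waic(ll[c(3, 1, 2), ]), w2)
  expect_error(waic(ll[1, , drop = FALSE]), "2 draws")
})

test_that("prior-only sampling reproduces the prior moments", {
  trials <- random_trials(20, seed = 5)
  post <- sample_posterior(trials, "ssat_t", n_draws = 4000, n_warmup = 1000,
                           seed = 9, prior_only = TRUE)
  m <- colMeans(post$draws)
  # threshold ~ U(0,1); alpha ~ Beta(1.1, 1.1) (mean 0.5)
  expect_lt(abs(m[["threshold"]] - 0.5), 0.06)
  expect_lt(abs(sd(post$draws[, "threshold"]) - sqrt(1 / 12)), 0.03)
  expect_lt(abs(m[["alpha"]] - 0.5), 0.06)
  # beta ~ Half-Normal(10): mean 10 * sqrt(2/pi)
  expect_lt(abs(m[["beta"]] - 10 * sqrt(2 / pi)), 1.2)
})

test_that("posterior sampling recovers a strong learner's parameters", {
  d <- build_design("exp1", seed = 10)
  s <- simulate_agent(d, "reward", c(alpha = 0.6, beta = 9), seed = 11)
  post <- sample_posterior(s, "reward", n_draws = 1500, n_warmup = 800,
                           seed = 1)
  expect_lt(abs(colMeans(post$draws)[["alpha"]] - 0.6), 0.15)
  expect_true(all(post$rhat < 1.1))
  expect_true(all(post$draws[, "alpha"] > 0 & post$draws[, "alpha"] < 1))
  # two seeds agree within Monte-Carlo error
  post2 <- sample_posterior(s, "reward", n_draws = 1500, n_warmup = 800,
                            seed = 2)
  d_mean <- abs(colMeans(post$draws) - colMeans(post2$draws))
  mc <- 3 * sqrt(post$mcse^2 + post2$mcse^2) + 0.02
  expect_true(all(d_mean < mc))
})

test_that("confidence regression R2 behaves at its extremes", {
  d <- build_design("exp1", seed = 12)
  p <- c(alpha = 0.5, beta = 6, gamma = 0.3, threshold = 0.4)
  s <- simulate_agent(d, "ssat_t", p, seed = 13)
  # reports an exact affine function of the model predictions -> R2 = 1
  dv <- predict(structure(list(model = "ssat_t", trials = s$trials,
                               estimates = data.frame(mean = p,
                                                      row.names = names(p))),
                          class = "bandit_fit"))
  s$trials$confidence <- 2 + 3 * dv
  expect_equal(suppressWarnings(confidence_fit_r2(s$trials, "ssat_t", p)), 1)
  # constant predictions -> R2 = 0 (alpha = 0 freezes the beliefs)
  s2 <- simulate_agent(d, "reward", c(alpha = 0.5, beta = 5), seed = 14)
  expect_equal(confidence_fit_r2(s2$trials, "reward",
                                 c(alpha = 0, beta = 5)), 0)
  expect_error(confidence_fit_r2(s$trials[1:5, ], "ssat_t", p),
               "fewer than 3")
})

test_that("the generating model predicts its own confidence best", {
  d <- build_design("exp1", seed = 15)
  p_ssat <- c(alpha = 0.58, beta = 5.34, gamma = 0.31, threshold = 0.35)
  p_rew <- c(alpha = 0.58, beta = 5.34, threshold = 0.35)
  diffs <- sapply(1:20, function(i) {
    s <- simulate_agent(d, "ssat_t", p_ssat, noise_sd = 0, seed = 400 + i)
    confidence_fit_r2(s, "ssat_t", p_ssat) -
      confidence_fit_r2(s, "reward_t", p_rew)
  })
  expect_gte(mean(diffs), 0)
})

test_that("fit_bandit returns a complete, coherent fit object", {
  d <- build_design("exp1", seed = 16)
  s <- simulate_agent(d, "reward_t",
                      c(alpha = 0.56, beta = 8.48, threshold = 0.33),
                      seed = 17)
  f <- fit_bandit(s, "reward_t", n_draws = 800, n_warmup = 500, seed = 3)
  expect_s3_class(f, "bandit_fit")
  expect_equal(f$waic, -2 * (f$lppd - f$p_waic))
  expect_gte(f$p_waic, 0)
  expect_gte(f$confidence_r2, 0)
  expect_lte(f$confidence_r2, 1)
  expect_named(coef(f), c("alpha", "beta", "threshold"))
  expect_equal(attr(logLik(f), "nobs"), 240)
  expect_output(print(f), "WAIC")
  expect_output(print(summary(f)), "Posterior")
  pr <- predict(f, type = "choice_prob")
  expect_length(pr, 240)
  expect_true(all(pr >= 0 & pr <= 1))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]$trials), 240)
  expect_length(residuals(f), sum(window_ok <- s$trials$phase == "stable" &
    s$trials$trial_in_block >= 10 & s$trials$trial_in_block <= 25))
})

test_that("an irrelevant extra parameter never beats the true model by more
           than its penalty", {
  d <- build_design("exp1", seed = 18)
  w_simple <- w_extra <- numeric(5)
  for (i in 1:5) {
    s <- simulate_agent(d, "reward", c(alpha = 0.6, beta = 7),
                        seed = 500 + i)
    w_simple[i] <- fit_bandit(s, "reward", n_draws = 800, n_warmup = 500,
                              seed = i)$waic
    w_extra[i] <- fit_bandit(s, "reward_t", n_draws = 800, n_warmup = 500,
                             seed = i)$waic
  }
  expect_lte(sum(w_simple), sum(w_extra) + 10)
})

test_that("compare_models assembles tables, tallies and parameter
           correlations", {
  d <- build_design("exp1", seed = 19)
  fits <- list()
  for (i in 1:4) {
    s <- simulate_agent(d, "reward_t",
                        c(alpha = runif(1, .4, .7), beta = runif(1, 5, 10),
                          threshold = runif(1, .2, .5)), seed = 600 + i,
                        subject_id = paste0("s", i))
    for (m in c("reward_t", "ssat_t")) {
      fits[[paste(m, i)]] <- fit_bandit(s, m, n_draws = 600,
                                        n_warmup = 400, seed = i)
    }
  }
  cmp <- compare_models(fits)
  expect_s3_class(cmp, "bandit_comparison")
  expect_equal(sort(cmp$table$model), sort(c("reward_t", "ssat_t")))
  expect_equal(sum(cmp$best_counts$n_best_waic), 4)
  expect_true(is.na(cmp$waic_tests[[cmp$best_waic]]))
  expect_true(all(cmp$param_r2$r2 >= 0 & cmp$param_r2$r2 <= 1))
  expect_output(print(cmp), "Model comparison")
  # paired difference of a model with itself is degenerate -> caught
  expect_error(compare_models(fits[1:3]), "all subjects")
})
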