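test_that("belief updates follow the delta rules", {
  bel <- belief_state()
  # mean update: 0.5 + 0.5 * (0.7 - 0.5) = 0.6
  b2 <- update_beliefs(bel, "good", 0.7, c(alpha = 0.5, beta = 5), "reward")
  expect_equal(b2$Q[["good"]], 0.6)
  expect_equal(b2$Q[["bad"]], 0.5)       # unchosen untouched without drift
  expect_equal(b2$V[["good"]], 0.04)     # reward family does not track V

  # variance fixed point: (R - Q)^2 == V leaves V unchanged
  p <- c(alpha = 0, beta = 5, gamma = 0.3, threshold = 0.4)
  bel3 <- belief_state(Q = c(good = 0.5, bad = 0.5),
                       V = c(good = 0.04, bad = 0.04))
  b3 <- update_beliefs(bel3, "good", 0.7, p, "ssat")
  expect_equal(b3$V[["good"]], 0.04)

  # drift of the unchosen option toward the threshold
  p4 <- c(alpha = 0.5, beta = 5, threshold = 0.35)
  bel4 <- belief_state(Q = c(good = 0.5, bad = 0.7))
  b4 <- update_beliefs(bel4, "good", 0.5, p4, "reward_t")
  expect_equal(b4$Q[["bad"]], 0.7 + 0.5 * (0.35 - 0.7))
})

test_that("repeated rewards drive Q to R geometrically; drift pulls to T", {
  p <- c(alpha = 0.3, beta = 5, threshold = 0.35)
  bel <- belief_state()
  for (t in 1:40) bel <- update_beliefs(bel, "good", 0.8, p, "reward_t")
  expect_equal(bel$Q[["good"]], 0.8 - (0.8 - 0.5) * 0.7^40, tolerance = 1e-12)
  expect_equal(bel$Q[["bad"]], 0.35, tolerance = 1e-5)
})

test_that("certainty equivalent matches the mean-variance form and the exact
           Gaussian expected exponential utility ordering", {
  expect_equal(certainty_equivalent(0.65, 0.0625, 1), 0.61875)
  expect_equal(certainty_equivalent(0.4, 0.1, 1e-12), 0.4, tolerance = 1e-9)
  # exact expected utility of exp-utility under Normal(Q, V):
  # E[-exp(-lambda X)] = -exp(-lambda Q + lambda^2 V / 2)
  grid <- expand.grid(Q = seq(0.2, 0.9, length.out = 6),
                      V = c(0.0025, 0.01, 0.04, 0.0625))
  for (lam in c(0.5, 1, 2)) {
    ce <- certainty_equivalent(grid$Q, grid$V, lam)
    eu_exact <- -exp(-lam * grid$Q + lam^2 * grid$V / 2)
    eu_numeric <- mapply(function(q, v) {
      integrate(function(x) -exp(-lam * x) * dnorm(x, q, sqrt(v)),
                q - 12 * sqrt(v), q + 12 * sqrt(v))$value
    }, grid$Q, grid$V)
    expect_equal(eu_numeric, eu_exact, tolerance = 1e-7)
    expect_equal(order(ce), order(eu_exact))
  }
})

test_that("satisficing probability equals the Gaussian upper tail mass", {
  set.seed(4)
  grid <- data.frame(Q = runif(100, 0.1, 0.9),
                     V = runif(100, 0.001, 0.09),
                     Tt = runif(100, 0.1, 0.9))
  sp <- satisficing_probability(grid$Q, grid$V, grid$Tt)
  brute <- mapply(function(q, v, tt) {
    integrate(function(x) dnorm(x, q, sqrt(v)), tt, Inf)$value
  }, grid$Q, grid$V, grid$Tt)
  expect_lt(max(abs(sp - brute)), 1e-6)
  expect_equal(satisficing_probability(0.4, 0.01, 0.4), 0.5)
  expect_error(satisficing_probability(0.4, 0, 0.4), "positive")
})

test_that("variance moves the satisficing probability asymmetrically but the
           certainty equivalent symmetrically", {
  v <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  below <- satisficing_probability(0.3, v, 0.5)  # Q < T: V helps
  above <- satisficing_probability(0.7, v, 0.5)  # Q > T: V hurts
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) < 0))
  expect_true(all(diff(certainty_equivalent(0.3, v, 1)) < 0))
  expect_true(all(diff(certainty_equivalent(0.7, v, 1)) < 0))
})

test_that("power utility is identity at rho 0, concave, and log-like near 1", {
  r <- seq(0.05, 1, by = 0.05)
  expect_equal(power_utility(r, 0), r)
  for (rho in c(0.2, 0.5, 0.8)) {
    a <- 0.2; b <- 0.9
    expect_gte(power_utility((a + b) / 2, rho),
               (power_utility(a, rho) + power_utility(b, rho)) / 2)
  }
  expect_equal(cor(power_utility(r, 0.999), log(r), method = "spearman"), 1)
  expect_error(power_utility(r, 1))
  expect_error(power_utility(-0.1, 0.5))
})

test_that("decision variables dispatch per family", {
  bel <- belief_state(Q = c(good = 0.65, bad = 0.35),
                      V = c(good = 0.04, bad = 0.04))
  expect_equal(decision_variables(bel, c(alpha = .5, beta = 5), "reward"),
               c(good = 0.65, bad = 0.35))
  # equal variances cancel in the utility difference
  dv_u <- decision_variables(bel, c(alpha = .5, beta = 1, gamma = .3,
                                    lambda = 2), "utility")
  expect_equal(dv_u[["good"]] - dv_u[["bad"]], 0.30)
  # both arms at Q = T give satisficing probability 0.5
  belT <- belief_state(Q = c(good = 0.4, bad = 0.4))
  dv_s <- decision_variables(belT, c(alpha = .5, beta = 5, gamma = .3,
                                     threshold = 0.4), "ssat")
  expect_equal(unname(dv_s), c(0.5, 0.5))
  expect_error(decision_variables(bel, c(alpha = .5, beta = 5), "foo"))
})

test_that("softmax choice probability is logistic in the DV difference", {
  expect_equal(choice_probability(0.4, 0.4, 5), 0.5)
  expect_equal(choice_probability(0.9, 0.1, 0), 0.5)
  expect_equal(choice_probability(0.65, 0.35, 8.48),
               1 / (1 + exp(-8.48 * 0.30)))
  expect_equal(round(choice_probability(0.65, 0.35, 8.48), 3), 0.927)
  # translation invariance
  expect_equal(choice_probability(0.65, 0.35, 3),
               choice_probability(0.25, -0.05, 3))
  # extreme differences stay finite
  expect_equal(choice_probability(1e4, -1e4, 10), 1)
  expect_error(choice_probability(1, 0, -1))
})

test_that("predicted confidence is the chosen option's decision variable", {
  bel <- belief_state(Q = c(good = 0.65, bad = 0.35))
  expect_equal(predicted_confidence(bel, c(alpha = .5, beta = 5), "reward",
                                    "good"), 0.65)
  p <- c(alpha = .5, beta = 5, gamma = .3, threshold = 0.52)
  belT <- belief_state(Q = c(good = 0.52, bad = 0.3))
  expect_equal(predicted_confidence(belT, p, "ssat_t", "good"), 0.5)
})

test_that("the compiled replay agrees with the stepwise R implementation", {
  trials <- random_trials(80, seed = 3)
  for (m in names(example_params)) {
    ref <- ref_replay(trials, m, example_params[[m]])
    ll <- choice_loglikelihood(trials, m, example_params[[m]])
    expect_equal(ll, ref$loglik, tolerance = 1e-10, info = m)
  }
})

test_that("parameter validation enforces bounds and completeness", {
  expect_error(validate_params(c(alpha = .5), "reward"), "beta")
  expect_error(validate_params(c(alpha = 1.2, beta = 5), "reward"),
               "outside")
  expect_error(model_spec("nope"), "unknown model")
  expect_equal(nrow(bandit_models()), 8)
})
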