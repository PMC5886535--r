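# Independent replay of a choice/reward sequence through the exported
# single-step R functions; used to cross-check the compiled engine.
ref_replay <- function(trials, model, params) {
  bel <- belief_state()
  n <- nrow(trials)
  ll <- dv_chosen <- numeric(n)
  for (t in seq_len(n)) {
    dv <- decision_variables(bel, params, model)
    beta <- unlist(params)[["beta"]]
    p_good <- choice_probability(dv[["good"]], dv[["bad"]], beta)
    ch <- trials$chosen_arm[t]
    ll[t] <- log(if (ch == "good") p_good else 1 - p_good)
    dv_chosen[t] <- dv[[ch]]
    bel <- update_beliefs(bel, ch, trials$reward[t] / 100, params, model)
  }
  list(loglik = ll, dv_chosen = dv_chosen)
}

# Random trial table (recorded data, not simulated behaviour).
random_trials <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chosen_arm = sample(c("good", "bad"), n, replace = TRUE),
    reward = sample(1:100, n, replace = TRUE)
  )
}

# Example parameter sets, one per model variant.
example_params <- list(
  reward    = c(alpha = 0.6, beta = 7),
  reward_t  = c(alpha = 0.56, beta = 8.48, threshold = 0.33),
  utility   = c(alpha = 0.55, beta = 0.7, gamma = 0.36, lambda = 0.91),
  utility_t = c(alpha = 0.49, beta = 0.86, gamma = 0.39, lambda = 0.66,
                threshold = 0.41),
  ssat      = c(alpha = 0.64, beta = 5.65, gamma = 0.32, threshold = 0.52),
  ssat_t    = c(alpha = 0.58, beta = 5.34, gamma = 0.31, threshold = 0.35),
  power     = c(alpha = 0.6, beta = 7, rho = 0.3),
  power_t   = c(alpha = 0.6, beta = 7, rho = 0.3, threshold = 0.35)
)
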