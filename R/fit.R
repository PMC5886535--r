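# Per-subject Bayesian fitting: choice likelihood, weakly informative
# priors, adaptive random-walk Metropolis on transformed parameters, WAIC,
# and confidence-regression goodness of fit.

# ---- data coercion ---------------------------------------------------------

as_trials <- function(data) {
  if (inherits(data, "bandit_subject")) data <- data$trials
  if (!is.data.frame(data) ||
      !all(c("chosen_arm", "reward") %in% names(data))) {
    stop("data must be a bandit_subject or a data frame with columns ",
         "'chosen_arm' and 'reward'")
  }
  if (!all(data$chosen_arm %in% c("good", "bad"))) {
    stop("chosen_arm must be 'good' or 'bad'")
  }
  data
}

replay <- function(trials, model, params) {
  spec <- model_spec(model)
  pv <- par_vector(params, model)
  bandit_replay_cpp(as.integer(trials$chosen_arm == "good"),
                    normalize_reward(trials$reward),
                    spec$family_code, spec$drift, pv, .Q0, .V0)
}

#' Per-trial choice log-likelihood
#'
#' Replays the recorded choices and rewards through the model's belief
#' dynamics and returns each trial's log softmax probability of the
#' recorded choice. Confidence reports contribute nothing to the choice
#' likelihood.
#'
#' @param data A `bandit_subject` or data frame with `chosen_arm`
#'   (`"good"`/`"bad"`) and `reward` (points, 1--100), trials in order.
#' @param model Model key (see [bandit_models()]).
#' @param params Named parameters for `model`.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
choice_loglikelihood <- function(data, model, params) {
  trials <- as_trials(data)
  ll <- replay(trials, model, params)$loglik
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood at trial ", which(!is.finite(ll))[1])
  }
  ll
}

# ---- priors and transforms -------------------------------------------------

# alpha, gamma ~ Beta(1.1, 1.1); beta ~ Half-Normal(10);
# lambda ~ Half-Normal(2); threshold ~ Uniform(0,1); rho ~ Uniform(0, 0.99).
.PRIOR_LOG <- list(
  alpha = function(x) dbeta(x, 1.1, 1.1, log = TRUE),
  gamma = function(x) dbeta(x, 1.1, 1.1, log = TRUE),
  beta = function(x) dnorm(x, 0, 10, log = TRUE) + log(2),
  lambda = function(x) dnorm(x, 0, 2, log = TRUE) + log(2),
  threshold = function(x) 0,
  rho = function(x) -log(0.99)
)

.TRANSFORM <- list(
  logit  = c("alpha", "gamma", "threshold"),
  log    = c("beta", "lambda"),
  logit99 = "rho"
)

to_unconstrained <- function(params) {
  u <- params
  for (p in names(params)) {
    u[[p]] <- if (p %in% .TRANSFORM$logit) qlogis(params[[p]])
    else if (p %in% .TRANSFORM$log) log(params[[p]])
    else qlogis(params[[p]] / 0.99)
  }
  u
}

to_natural <- function(u) {
  x <- u
  for (p in names(u)) {
    x[[p]] <- if (p %in% .TRANSFORM$logit) plogis(u[[p]])
    else if (p %in% .TRANSFORM$log) exp(u[[p]])
    else 0.99 * plogis(u[[p]])
  }
  x
}

# log prior density of the natural values plus log |d natural / d u|
log_prior_jacobian <- function(u) {
  x <- to_natural(u)
  lp <- 0
  for (p in names(u)) {
    lp <- lp + .PRIOR_LOG[[p]](x[[p]])
    lp <- lp + if (p %in% .TRANSFORM$log) u[[p]]
    else {
      q <- plogis(u[[p]])
      log(q) + log1p(-q) + if (p == "rho") log(0.99) else 0
    }
  }
  lp
}

# ---- sampler ---------------------------------------------------------------

# Adaptive random-walk Metropolis: global scale tuned toward 0.3 acceptance
# by Robbins-Monro during warmup, proposal covariance re-estimated from the
# warmup history; the kernel is frozen for the sampling phase.
adaptive_metropolis <- function(lpost, init_u, n_warmup, n_iter) {
  d <- length(init_u)
  u <- init_u
  cur <- lpost(u)
  log_s <- log(2.38 / sqrt(d))
  L <- diag(d)
  hist_u <- matrix(NA_real_, n_warmup, d)
  draws_u <- matrix(NA_real_, n_iter, d)
  accepted <- 0L
  total <- n_warmup + n_iter
  for (i in seq_len(total)) {
    prop <- u + exp(log_s) * as.numeric(L %*% rnorm(d))
    names(prop) <- names(u)
    cand <- lpost(prop)
    a <- min(1, exp(cand$lp - cur$lp))
    if (is.finite(a) && runif(1) < a) {
      u <- prop; cur <- cand
      if (i > n_warmup) accepted <- accepted + 1L
    }
    if (i <= n_warmup) {
      hist_u[i, ] <- u
      log_s <- log_s + min(0.1, i^(-0.6)) * (a - 0.3)
      if (i >= 100 && i %% 50 == 0) {
        S <- stats::cov(hist_u[max(1, i - 500):i, , drop = FALSE])
        L <- tryCatch(t(chol(S + diag(1e-6, d))), error = function(e) L)
      }
    } else {
      draws_u[i - n_warmup, ] <- u
    }
  }
  list(draws_u = draws_u, accept_rate = accepted / n_iter,
       final_lpost = cur$lp)
}

ess_acf <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  r <- acf(x, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
  pos <- which(r < 0.05)
  k <- if (length(pos)) pos[1] - 1 else length(r)
  max(1, n / (1 + 2 * sum(r[seq_len(k)])))
}

split_rhat <- function(x) {
  n <- length(x) %/% 2
  h <- list(x[1:n], x[(n + 1):(2 * n)])
  w <- mean(vapply(h, var, 0))
  if (w == 0) return(1)
  m <- vapply(h, mean, 0)
  b <- n * var(m)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sample the per-subject posterior of a model
#'
#' Adaptive random-walk Metropolis over the model's free parameters
#' (logit/log transformed), targeting likelihood x prior. Emits the
#' per-trial log-likelihood at every kept draw (needed for WAIC) and basic
#' convergence diagnostics (acceptance rate, split R-hat, effective sample
#' sizes).
#'
#' @inheritParams choice_loglikelihood
#' @param n_draws Kept posterior draws.
#' @param n_warmup Warmup (adaptation) iterations, discarded.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed.
#' @param prior_only If `TRUE` the likelihood is dropped and the draws
#'   target the prior (useful for checking the sampler).
#' @param init Optional named initial parameter values (natural scale).
#' @return List with `draws` (n_draws x n_params matrix, natural scale),
#'   `loglik` (n_draws x n_trials matrix), `accept_rate`, `ess`, `rhat`,
#'   `mcse`, `model`.
#' @export
sample_posterior <- function(data, model, n_draws = 2000, n_warmup = 1000,
                             thin = 1, seed = NULL, prior_only = FALSE,
                             init = NULL) {
  trials <- as_trials(data)
  spec <- model_spec(model)
  choice <- as.integer(trials$chosen_arm == "good")
  reward <- normalize_reward(trials$reward)
  n_trials <- length(choice)
  pv_template <- c(alpha = 0, beta = 0, gamma = 0, lambda = 0,
                   threshold = 0.5, rho = 0)
  lpost <- function(u) {
    x <- unlist(to_natural(u))
    lp <- log_prior_jacobian(u)
    if (prior_only) return(list(lp = lp, ll = numeric(n_trials)))
    pv <- pv_template
    pv[names(x)] <- x
    ll <- bandit_replay_cpp(choice, reward, spec$family_code, spec$drift,
                            unname(pv), .Q0, .V0)$loglik
    list(lp = lp + sum(ll), ll = ll)
  }
  defaults <- c(alpha = 0.5, beta = 5, gamma = 0.3, lambda = 0.8,
                threshold = 0.4, rho = 0.3)
  start <- defaults[spec$params]
  if (!is.null(init)) start[names(init)] <- unlist(init)[names(init)]
  with_seed(seed, {
    u0 <- unlist(to_unconstrained(as.list(start)))
    run <- adaptive_metropolis(function(u) lpost(as.list(u)),
                               u0, n_warmup, n_draws * thin)
    keep <- seq(thin, n_draws * thin, by = thin)
    du <- run$draws_u[keep, , drop = FALSE]
    draws <- du
    for (j in seq_along(spec$params)) {
      draws[, j] <- unlist(to_natural(setNames(list(du[, j]),
                                               spec$params[j])))
    }
    colnames(draws) <- spec$params
    ll <- matrix(NA_real_, nrow(draws), n_trials)
    for (i in seq_len(nrow(draws))) {
      ll[i, ] <- lpost(as.list(setNames(du[i, ], spec$params)))$ll
    }
    ess <- apply(draws, 2, ess_acf)
    list(draws = draws, loglik = ll, accept_rate = run$accept_rate,
         ess = ess, rhat = apply(draws, 2, split_rhat),
         mcse = apply(draws, 2, sd) / sqrt(ess), model = model)
  })
}

# ---- WAIC ------------------------------------------------------------------

#' Watanabe-Akaike information criterion from per-trial draws
#'
#' `lppd = sum_t log mean_d exp(ll[d, t])`, `p_waic = sum_t var_d(ll[d, t])`
#' (the variance form of the penalty), `waic = -2 (lppd - p_waic)`;
#' lower is better.
#'
#' @param loglik_draws Matrix of per-trial log-likelihoods, draws in rows.
#' @return List with `lppd`, `p_waic`, `waic`.
#' @export
waic <- function(loglik_draws) {
  if (is.null(dim(loglik_draws)) || nrow(loglik_draws) < 2) {
    stop("need a matrix with at least 2 draws")
  }
  lppd <- sum(apply(loglik_draws, 2, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  p_waic <- sum(apply(loglik_draws, 2, var))
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

# ---- confidence goodness of fit -------------------------------------------

#' Confidence-regression goodness of fit
#'
#' Replays the model over the recorded choices and rewards, takes the
#' chosen option's decision variable as the model's confidence prediction,
#' restricts to within-block stable trials 10--25, and regresses the
#' reported 1--6 confidence on the predictions by ordinary least squares.
#'
#' @inheritParams choice_loglikelihood
#' @param params Point parameters (e.g. posterior means).
#' @param window Within-block stable-trial window (inclusive).
#' @param return_lm If `TRUE`, return the `lm` fit instead of just R^2.
#' @return The coefficient of determination in `[0, 1]` (0 when the
#'   predictions are constant), or the `lm` object.
#' @export
confidence_fit_r2 <- function(data, model, params, window = c(10, 25),
                              return_lm = FALSE) {
  trials <- as_trials(data)
  if (!"confidence" %in% names(trials)) stop("data has no confidence column")
  dv <- replay(trials, model, params)$dv_chosen
  sel <- window_rows(trials, window) & !is.na(trials$confidence)
  if (sum(sel) < 3) stop("fewer than 3 usable trials in the window")
  d <- data.frame(confidence = trials$confidence[sel], dv = dv[sel])
  if (var(d$dv) < 1e-12) {
    if (return_lm) return(lm(confidence ~ 1, data = d))
    return(0)
  }
  fit <- lm(confidence ~ dv, data = d)
  if (return_lm) return(fit)
  summary(fit)$r.squared
}

# ---- main fitting surface --------------------------------------------------

#' Fit a bandit model to one subject
#'
#' The package's central fitting function: samples the per-subject
#' posterior of the chosen model over the recorded choices and rewards,
#' computes WAIC from the per-trial log-likelihood draws, and scores the
#' model's confidence predictions (R^2 of reports on predictions over
#' stable trials 10--25) at the posterior-mean parameters.
#'
#' @inheritParams sample_posterior
#' @param window Stable-trial window for the confidence regression.
#' @return An object of class `bandit_fit` with components `model`,
#'   `subject_id`, `draws`, `loglik`, `estimates` (posterior mean/sd),
#'   `lppd`, `p_waic`, `waic`, `confidence_r2`, `diagnostics`, `trials`,
#'   `design`. Supports `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `simulate`, `residuals` and `plot`.
#' @examples
#' \donttest{
#' d <- build_design("exp1", seed = 2)
#' s <- simulate_agent(d, "reward_t",
#'   params = c(alpha = 0.56, beta = 8.5, threshold = 0.33), seed = 2)
#' f <- fit_bandit(s, "reward_t", n_draws = 500, n_warmup = 400, seed = 1)
#' f
#' }
#' @export
fit_bandit <- function(data, model = "ssat_t", n_draws = 2000,
                       n_warmup = 1000, thin = 1, seed = NULL,
                       window = c(10, 25), init = NULL) {
  trials <- as_trials(data)
  post <- sample_posterior(data, model, n_draws = n_draws,
                           n_warmup = n_warmup, thin = thin, seed = seed,
                           init = init)
  ic <- waic(post$loglik)
  est <- data.frame(mean = colMeans(post$draws),
                    sd = apply(post$draws, 2, sd),
                    q2.5 = apply(post$draws, 2, quantile, 0.025),
                    q97.5 = apply(post$draws, 2, quantile, 0.975),
                    ess = post$ess, rhat = post$rhat)
  r2 <- if ("confidence" %in% names(trials) &&
            "trial_in_block" %in% names(trials) &&
            !all(is.na(trials$confidence))) {
    tryCatch(confidence_fit_r2(trials, model,
                               setNames(est$mean, rownames(est)),
                               window = window),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(
    model = model,
    subject_id = if (inherits(data, "bandit_subject")) data$subject_id
                 else NA_character_,
    draws = post$draws, loglik = post$loglik, estimates = est,
    lppd = ic$lppd, p_waic = ic$p_waic, waic = ic$waic,
    confidence_r2 = r2,
    diagnostics = list(accept_rate = post$accept_rate, ess = post$ess,
                       rhat = post$rhat, mcse = post$mcse),
    trials = trials,
    design = if (inherits(data, "bandit_subject")) data$design,
    window = window
  ), class = "bandit_fit")
}

#' @export
print.bandit_fit <- function(x, digits = 3, ...) {
  cat("Bandit model fit: ", x$model,
      if (!is.na(x$subject_id)) paste0("  (subject ", x$subject_id, ")"),
      "\n", sep = "")
  cat("  trials: ", nrow(x$trials),
      "   WAIC: ", round(x$waic, 1),
      "   confidence R^2: ",
      if (is.na(x$confidence_r2)) "NA" else round(x$confidence_r2, digits),
      "\n", sep = "")
  cat("  posterior means:\n")
  print(round(setNames(x$estimates$mean, rownames(x$estimates)), digits))
  invisible(x)
}

#' @export
summary.bandit_fit <- function(object, ...) {
  structure(list(model = object$model, subject_id = object$subject_id,
                 estimates = object$estimates, lppd = object$lppd,
                 p_waic = object$p_waic, waic = object$waic,
                 confidence_r2 = object$confidence_r2,
                 accept_rate = object$diagnostics$accept_rate,
                 n_trials = nrow(object$trials),
                 n_draws = nrow(object$draws)),
            class = "summary.bandit_fit")
}

#' @export
print.summary.bandit_fit <- function(x, digits = 3, ...) {
  cat("Model:", x$model, "  subject:", x$subject_id, "\n")
  cat(sprintf("Trials: %d   draws: %d   acceptance: %.2f\n",
              x$n_trials, x$n_draws, x$accept_rate))
  cat(sprintf("lppd: %.2f   p_waic: %.2f   WAIC: %.2f\n",
              x$lppd, x$p_waic, x$waic))
  cat("Confidence R^2:",
      if (is.na(x$confidence_r2)) "NA" else round(x$confidence_r2, digits),
      "\n\nPosterior:\n")
  print(round(x$estimates, digits))
  invisible(x)
}

#' @export
coef.bandit_fit <- function(object, ...) {
  setNames(object$estimates$mean, rownames(object$estimates))
}

#' @export
logLik.bandit_fit <- function(object, ...) {
  structure(object$lppd, df = object$p_waic, nobs = nrow(object$trials),
            class = "logLik")
}

#' Model predictions for a fitted subject
#'
#' @param object A [fit_bandit()] object.
#' @param newdata Optional replacement trial table (defaults to the fitted
#'   trials).
#' @param type `"confidence"` (chosen option's decision variable),
#'   `"dv"` (both arms) or `"choice_prob"` (softmax P(good)).
#' @param ... Unused.
#' @return Numeric vector, or two-column matrix for `type = "dv"`.
#' @export
predict.bandit_fit <- function(object, newdata = NULL,
                               type = c("confidence", "dv", "choice_prob"),
                               ...) {
  type <- match.arg(type)
  trials <- as_trials(if (is.null(newdata)) object$trials else newdata)
  rep <- replay(trials, object$model, coef(object))
  switch(type,
         confidence = rep$dv_chosen,
         dv = cbind(good = rep$dv_good, bad = rep$dv_bad),
         choice_prob = rep$p_good)
}

#' @export
residuals.bandit_fit <- function(object, ...) {
  fit <- confidence_fit_r2(object$trials, object$model, coef(object),
                           window = object$window, return_lm = TRUE)
  residuals(fit)
}

#' Simulate new datasets from a fitted model
#'
#' Simulates agents at the posterior-mean parameters on the fitted design
#' (or a supplied one).
#'
#' @param object A [fit_bandit()] object.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param design A [build_design()] object; defaults to the design stored
#'   with the fitted subject.
#' @param ... Passed to [simulate_agent()].
#' @return List of `bandit_subject` objects.
#' @export
simulate.bandit_fit <- function(object, nsim = 1, seed = NULL,
                                design = NULL, ...) {
  design <- design %||% object$design
  if (is.null(design)) stop("no design stored with the fit; supply one")
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    simulate_agent(design, object$model, coef(object),
                   subject_id = sprintf("postsim%02d", i), ...)
  }))
}

#' @export
plot.bandit_fit <- function(x, ...) {
  p <- colnames(x$draws)
  old <- graphics::par(mfrow = c(1, length(p)))
  on.exit(graphics::par(old))
  for (j in seq_along(p)) {
    graphics::hist(x$draws[, j], breaks = 30, main = p[j], xlab = p[j],
                   col = "grey80", border = "white", ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
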