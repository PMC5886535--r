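# Behavioural statistics and optimality analyses: condition summaries,
# choice stability, correlation screens with analytic critical values,
# reward-maximization parameter search, and steady-state value differences.

#' Condition-wise choice and confidence summaries
#'
#' Per experimental condition: good-choice frequency, and mean confidence
#' split by chosen arm, computed over within-block stable trials 10--25,
#' averaged first within and then across subjects. Cells with no
#' observations for a subject (e.g. a subject who never chose the bad
#' option in a condition) are flagged missing, not zero.
#'
#' @param cohort List of `bandit_subject` objects sharing one design.
#' @param window Within-block stable-trial window (inclusive).
#' @return Data frame with one row per condition: `condition`,
#'   `n_subjects`, `p_good` (+ sd), `conf_good` (+ sd), `conf_bad` (+ sd).
#' @export
condition_summaries <- function(cohort, window = c(10, 25)) {
  if (inherits(cohort, "bandit_subject")) cohort <- list(cohort)
  per_subject <- lapply(cohort, function(s) {
    tr <- s$trials[window_rows(s$trials, window), ]
    if (!nrow(tr)) stop("no stable-window trials in subject ", s$subject_id)
    do.call(rbind, lapply(split(tr, tr$condition), function(d) {
      good <- d$chosen_arm == "good"
      data.frame(
        condition = d$condition[1],
        p_good = mean(good),
        conf_good = if (any(good)) mean(d$confidence[good]) else NA_real_,
        conf_bad = if (any(!good)) mean(d$confidence[!good]) else NA_real_
      )
    }))
  })
  all <- do.call(rbind, per_subject)
  out <- do.call(rbind, lapply(split(all, all$condition), function(d) {
    data.frame(
      condition = d$condition[1], n_subjects = nrow(d),
      p_good = mean(d$p_good), p_good_sd = sd(d$p_good),
      conf_good = mean(d$conf_good, na.rm = TRUE),
      conf_good_sd = sd(d$conf_good, na.rm = TRUE),
      conf_bad = mean(d$conf_bad, na.rm = TRUE),
      conf_bad_sd = sd(d$conf_bad, na.rm = TRUE)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Sliding-window choice stability
#'
#' For each 5-trial window, stability is 5 minus the number of
#' consecutive-trial choice switches inside the window (4 pairs per
#' window): 5 when the same option was chosen on all five trials, 1 when
#' the choice alternated on every trial.
#'
#' @param choices Vector of choices (any type; compared with `!=`).
#' @param width Window width (default 5).
#' @return Integer vector of stability values, one per window, named by the
#'   window's final trial index.
#' @export
choice_stability <- function(choices, width = 5) {
  n <- length(choices)
  width <- as.integer(width)
  if (n < width) stop("need at least ", width, " trials")
  sw <- as.integer(choices[-1] != choices[-n])
  stab <- vapply(width:n, function(t) {
    width - sum(sw[(t - width + 1):(t - 1)])
  }, 0L)
  names(stab) <- width:n
  stab
}

#' Per-trial stability series for a subject
#'
#' Applies [choice_stability()] within each block's stable segment
#' (windows never span block boundaries or transitions), aligning each
#' window's value to its final trial.
#'
#' @param subject A `bandit_subject`.
#' @param width Window width.
#' @return Data frame `trial`, `stability` (NA where no full window ends).
#' @export
stability_series <- function(subject, width = 5) {
  tr <- subject$trials
  out <- data.frame(trial = tr$trial, stability = NA_integer_)
  stable <- tr[tr$phase == "stable", ]
  for (b in split(stable, stable$block)) {
    if (nrow(b) < width) next
    st <- choice_stability(b$chosen_arm, width)
    out$stability[match(b$trial[width:nrow(b)], out$trial)] <- st
  }
  out
}

#' Critical value of the Pearson correlation
#'
#' Two-sided critical |r| at level `alpha` for `n` pairs, from the t
#' distribution with `n - 2` degrees of freedom:
#' `r* = t* / sqrt(n - 2 + t*^2)`.
#'
#' @param n Number of pairs (>= 3).
#' @param alpha Significance level.
#' @return The critical correlation.
#' @examples
#' critical_r(240) # ~0.13
#' critical_r(160) # ~0.16
#' @export
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tstar <- qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}

#' Pearson correlation with its analytic significance threshold
#'
#' Drops incomplete pairs, computes Pearson's r, and compares |r| with
#' [critical_r()] at the requested level.
#'
#' @param x,y Equal-length numeric series (NAs dropped pairwise).
#' @param alpha Significance level.
#' @return List with `r`, `n`, `critical_r`, `significant`.
#' @export
correlate_with_threshold <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance series")
  r <- cor(x, y)
  rc <- critical_r(length(x), alpha)
  list(r = r, n = length(x), critical_r = rc, significant = abs(r) >= rc)
}

#' Stability-confidence correlation for one subject
#'
#' Correlates the per-trial stability series with the confidence reports,
#' with the analytic significance threshold.
#'
#' @inheritParams stability_series
#' @param alpha Significance level.
#' @return As [correlate_with_threshold()].
#' @export
stability_confidence_correlation <- function(subject, width = 5,
                                             alpha = 0.05) {
  st <- stability_series(subject, width)
  correlate_with_threshold(st$stability, subject$trials$confidence, alpha)
}

# Mean total points over seeded simulations of `model` on `design`.
mean_sim_reward <- function(model, params, design, sims_seeds) {
  mean(vapply(sims_seeds, function(s) {
    sum(simulate_agent(design, model, params, noise_sd = 0,
                       seed = s)$trials$reward)
  }, 0))
}

#' Simulate the omniscient benchmark
#'
#' An agent that knows the true trial-wise arm means (including during
#' transitions) and always picks the higher-mean arm; rewards are sampled
#' from the true distributions.
#'
#' @param design A [build_design()] object.
#' @param n_reps Repetitions.
#' @param seed Integer seed.
#' @return Numeric vector of total points per repetition.
#' @export
simulate_omniscient <- function(design, n_reps = 100, seed = NULL) {
  tw <- trialwise_parameters(design)
  pick_good <- tw$mu_good >= tw$mu_bad
  mu <- ifelse(pick_good, tw$mu_good, tw$mu_bad)
  s2 <- ifelse(pick_good, tw$var_good, tw$var_bad)
  with_seed(seed, vapply(seq_len(n_reps), function(i) {
    sum(sample_reward(mu, s2, n = nrow(tw)))
  }, 0))
}

#' Reward-maximizing parameters for a model family
#'
#' Derivative-free (Nelder-Mead) search over a model's free parameters
#' maximizing the mean total points over seeded simulations of the design
#' (common random numbers across evaluations), with multiple seeded
#' restarts. The best parameters are then evaluated over `n_reps` fresh
#' simulations and compared with the omniscient benchmark.
#'
#' @param model Model key.
#' @param design A [build_design()] object.
#' @param n_reps Fresh evaluation repetitions.
#' @param restarts Seeded Nelder-Mead restarts.
#' @param n_sims Simulations per objective evaluation.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param seed Integer seed.
#' @return Object of class `bandit_optim`: `model`, `par` (best
#'   parameters), `mean_reward`, `rewards` (per repetition),
#'   `omniscient_mean`, `omniscient_rewards`, `objective_value`.
#' @export
optimize_for_reward <- function(model, design, n_reps = 100, restarts = 10,
                                n_sims = 20, maxit = 150, seed = NULL) {
  stopifnot(n_reps >= 1)
  spec <- model_spec(model)
  with_seed(seed, {
    obj_seeds <- sample.int(1e6, n_sims)
    objective <- function(u) {
      params <- unlist(to_natural(as.list(setNames(u, spec$params))))
      -mean_sim_reward(model, params, design, obj_seeds)
    }
    best <- NULL
    for (r in seq_len(restarts)) {
      start <- draw_params(model, cohort_spec(1)$param_means,
                           cohort_spec(1)$param_sds)
      u0 <- unlist(to_unconstrained(as.list(start)))
      opt <- optim(u0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    par <- unlist(to_natural(as.list(setNames(best$par, spec$params))))
    eval_seeds <- sample.int(1e6, n_reps)
    rewards <- vapply(eval_seeds, function(s) {
      sum(simulate_agent(design, model, par, noise_sd = 0,
                         seed = s)$trials$reward)
    }, 0)
    omn <- simulate_omniscient(design, n_reps,
                               seed = sample.int(1e6, 1))
    structure(list(model = model, par = par,
                   mean_reward = mean(rewards), rewards = rewards,
                   omniscient_mean = mean(omn), omniscient_rewards = omn,
                   objective_value = -best$value),
              class = "bandit_optim")
  })
}

#' @export
print.bandit_optim <- function(x, ...) {
  cat("Reward-maximizing parameters for '", x$model, "':\n", sep = "")
  print(round(x$par, 3))
  cat(sprintf("mean accrued points: %.0f (omniscient benchmark: %.0f)\n",
              x$mean_reward, x$omniscient_mean))
  invisible(x)
}

#' Steady-state decision-variable differences
#'
#' Sets the beliefs to each condition's true normalized arm means and
#' variances (the post-learning steady state) and reports the good-minus-
#' bad decision-variable difference for each acceptability threshold in a
#' grid. Threshold-free families give a constant difference.
#'
#' @param model Model key.
#' @param params Named parameters for `model` (its `threshold` is replaced
#'   by each grid value in turn; for threshold-free families the grid is
#'   ignored).
#' @param design A [build_design()] object.
#' @param thresholds Acceptability-threshold grid in (0, 1).
#' @return Data frame `condition`, `threshold`, `dv_good`, `dv_bad`,
#'   `dv_diff`.
#' @export
steady_state_value_difference <- function(model, params, design,
                                          thresholds = seq(0.25, 0.75,
                                                           by = 0.05)) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  spec <- model_spec(model)
  conds <- unique(do.call(rbind, lapply(design$blocks, function(b) {
    data.frame(condition = b$condition,
               mu_g = b$good$mean / 100, v_g = b$good$variance / 1e4,
               mu_b = b$bad$mean / 100, v_b = b$bad$variance / 1e4)
  })))
  uses_threshold <- "threshold" %in% spec$params
  grid <- if (uses_threshold) thresholds else NA_real_
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    bel <- belief_state(Q = c(good = conds$mu_g[i], bad = conds$mu_b[i]),
                        V = c(good = conds$v_g[i], bad = conds$v_b[i]))
    for (th in grid) {
      p <- as.list(params)
      if (uses_threshold) p$threshold <- th
      dv <- decision_variables(bel, p, model)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = conds$condition[i], threshold = th,
        dv_good = dv[["good"]], dv_bad = dv[["bad"]],
        dv_diff = dv[["good"]] - dv[["bad"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
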