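# Synthetic cohorts: agents governed by a known model and parameters,
# 1-6 confidence reports, and the exclusion pathologies (chance performers,
# single-level confidence reporters).

#' Map a decision variable to a 1--6 confidence report
#'
#' Linear map of the chosen option's decision variable across `dv_range`
#' onto the 1--6 scale, plus Gaussian noise (sd in report units), rounded
#' and clipped. With `noise_sd = 0` the map is deterministic and monotone.
#' This is a reporting convention of the generator only; model fitting never
#' uses it (confidence is scored by regressing reports on model
#' predictions).
#'
#' @param dv_chosen Decision variable(s) of the chosen option.
#' @param dv_range Length-2 numeric `(lo, hi)` with `lo < hi`.
#' @param noise_sd Gaussian report noise sd on the 1--6 scale.
#' @return Integer report(s) in `{1, ..., 6}`.
#' @export
confidence_report <- function(dv_chosen, dv_range = c(0, 1), noise_sd = 0) {
  if (length(dv_range) != 2L || dv_range[1] >= dv_range[2]) {
    stop("dv_range must be (lo, hi) with lo < hi")
  }
  raw <- 1 + 5 * (dv_chosen - dv_range[1]) / (dv_range[2] - dv_range[1])
  if (noise_sd > 0) raw <- raw + rnorm(length(raw), 0, noise_sd)
  as.integer(pmin(6, pmax(1, round(raw))))
}

#' Simulate one agent on a design
#'
#' Plays the full trial sequence: computes the model's decision variables
#' from the current beliefs, samples the choice through the softmax, draws
#' the reward from the trial's true arm distribution, reports confidence
#' via [confidence_report()], and updates beliefs. Fully reproducible from
#' `seed`.
#'
#' @param design A [build_design()] object.
#' @param model Model key (see [bandit_models()]).
#' @param params Named parameters for `model`.
#' @param noise_sd Confidence report noise sd (1--6 scale units).
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param subject_id Identifier stored with the dataset.
#' @param confidence_constant If not `NULL`, every report is forced to this
#'   level (injects the single-level pathology).
#' @param dv_range Decision-variable range mapped onto the report scale.
#' @return An object of class `bandit_subject`: list with `subject_id`,
#'   `model`, `params`, `design`, and `trials` (data frame with `trial`,
#'   `block`, `condition`, `phase`, `trial_in_block`, `chosen_arm`,
#'   `confidence`, `reward`, `rt`).
#' @examples
#' d <- build_design("exp1", seed = 1)
#' s <- simulate_agent(d, "ssat_t",
#'   params = c(alpha = 0.5, beta = 6, gamma = 0.3, threshold = 0.4),
#'   seed = 1)
#' head(s$trials)
#' @export
simulate_agent <- function(design, model, params, noise_sd = 0.5,
                           seed = NULL, subject_id = "sim01",
                           confidence_constant = NULL,
                           dv_range = c(0, 1)) {
  stopifnot(inherits(design, "bandit_design"))
  spec <- model_spec(model)
  pv <- par_vector(params, model)
  tw <- trialwise_parameters(design)
  conf_const <- if (is.null(confidence_constant)) 0L
                else as.integer(confidence_constant)
  if (conf_const < 0L || conf_const > 6L) stop("confidence_constant in 1..6")
  sim <- with_seed(seed, bandit_simulate_cpp(
    tw$mu_good, tw$var_good, tw$mu_bad, tw$var_bad,
    spec$family_code, spec$drift, pv, noise_sd, .Q0, .V0,
    dv_range[1], dv_range[2], conf_const
  ))
  trials <- data.frame(
    trial = tw$trial, block = tw$block, condition = tw$condition,
    phase = tw$phase, trial_in_block = tw$trial_in_block,
    chosen_arm = ifelse(sim$choice == 1L, "good", "bad"),
    confidence = sim$confidence, reward = sim$reward, rt = NA_real_
  )
  structure(list(subject_id = subject_id, model = model,
                 params = validate_params(params, model),
                 design = design, trials = trials),
            class = "bandit_subject")
}

#' @export
print.bandit_subject <- function(x, ...) {
  cat("Simulated bandit subject '", x$subject_id, "' (",
      if (is.null(x$model)) "model unknown" else x$model, "), ",
      nrow(x$trials), " trials, good-choice rate ",
      round(mean(x$trials$chosen_arm == "good"), 3), "\n", sep = "")
  invisible(x)
}

#' Specify a synthetic cohort
#'
#' Ground-truth models, parameter sampling and pathology injection for
#' [generate_cohort()]. Default parameter distributions are centred on the
#' magnitudes typical of fitted subjects in this task (learning rates just
#' above 0.5, inverse temperatures around 6, thresholds around 0.4 on the
#' normalized scale), truncated to their bounds.
#'
#' @param n_subjects Number of non-pathological subjects.
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @param models Model key(s); recycled over subjects (a half/half vector
#'   gives a mixture cohort).
#' @param noise_sd Confidence report noise sd.
#' @param n_chance Extra subjects simulated with `beta = 0` (chance
#'   performers).
#' @param n_constant_conf Extra subjects whose confidence is forced to one
#'   level.
#' @param param_means,param_sds Named numerics overriding the sampling
#'   means / sds for any of `alpha`, `beta`, `gamma`, `lambda`,
#'   `threshold`, `rho`.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, experiment_id = "exp1",
                        models = "ssat_t", noise_sd = 0.5,
                        n_chance = 0, n_constant_conf = 0,
                        param_means = NULL, param_sds = NULL,
                        seed = NULL) {
  stopifnot(n_subjects >= 1, n_chance >= 0, n_constant_conf >= 0)
  means <- c(alpha = 0.55, beta = 6, gamma = 0.33, lambda = 0.8,
             threshold = 0.38, rho = 0.3)
  sds <- c(alpha = 0.15, beta = 2, gamma = 0.15, lambda = 0.4,
           threshold = 0.1, rho = 0.15)
  if (!is.null(param_means)) means[names(param_means)] <- param_means
  if (!is.null(param_sds)) sds[names(param_sds)] <- param_sds
  structure(list(n_subjects = n_subjects, experiment_id = experiment_id,
                 models = models, noise_sd = noise_sd,
                 n_chance = n_chance, n_constant_conf = n_constant_conf,
                 param_means = means, param_sds = sds, seed = seed),
            class = "cohort_spec")
}

# Truncated-normal parameter draw within the model's bounds.
draw_params <- function(spec_model, means, sds) {
  lower <- c(alpha = 0.05, beta = 0.5, gamma = 0.05, lambda = 0.05,
             threshold = 0.05, rho = 0)
  upper <- c(alpha = 0.95, beta = 20, gamma = 0.95, lambda = 5,
             threshold = 0.95, rho = 0.95)
  vapply(model_spec(spec_model)$params, function(p) {
    repeat {
      v <- rnorm(1, means[[p]], sds[[p]])
      if (v >= lower[[p]] && v <= upper[[p]]) return(v)
    }
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Simulates `n_subjects` agents with parameters drawn from the cohort
#' spec, plus the requested pathological subjects: chance performers
#' (`beta = 0`) and single-level confidence reporters (reports forced to
#' level 4). Ground truth (model and parameters) is stored with every
#' subject. A pure function of the spec, including its seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of `bandit_subject` objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    design <- build_design(spec$experiment_id,
                           seed = sample.int(.Machine$integer.max, 1))
    models <- rep_len(spec$models, spec$n_subjects)
    n_total <- spec$n_subjects + spec$n_chance + spec$n_constant_conf
    ids <- sprintf("sub%03d", seq_len(n_total))
    out <- vector("list", n_total)
    for (i in seq_len(spec$n_subjects)) {
      pars <- draw_params(models[i], spec$param_means, spec$param_sds)
      out[[i]] <- simulate_agent(design, models[i], pars,
                                 noise_sd = spec$noise_sd,
                                 subject_id = ids[i])
    }
    j <- spec$n_subjects
    base_model <- models[1]
    for (k in seq_len(spec$n_chance)) {
      pars <- draw_params(base_model, spec$param_means, spec$param_sds)
      pars[["beta"]] <- 0
      s <- simulate_agent(design, base_model, pars,
                          noise_sd = spec$noise_sd,
                          subject_id = ids[j + k])
      s$pathology <- "chance"
      out[[j + k]] <- s
    }
    j <- j + spec$n_chance
    for (k in seq_len(spec$n_constant_conf)) {
      pars <- draw_params(base_model, spec$param_means, spec$param_sds)
      s <- simulate_agent(design, base_model, pars,
                          noise_sd = spec$noise_sd,
                          subject_id = ids[j + k],
                          confidence_constant = 4L)
      s$pathology <- "constant_confidence"
      out[[j + k]] <- s
    }
    out
  })
}

# Stable-window rows (within-block trials 10-25 of the stable segment).
window_rows <- function(trials, window = c(10, 25)) {
  trials$phase == "stable" &
    !is.na(trials$trial_in_block) &
    trials$trial_in_block >= window[1] & trials$trial_in_block <= window[2]
}

#' Participant exclusion filters
#'
#' Excludes subjects whose good-choice proportion over within-block trials
#' 10--25 is not significantly above chance (one-sided exact binomial test
#' against 0.5), and subjects who used exactly one confidence level across
#' all trials.
#'
#' @param cohort List of `bandit_subject` objects.
#' @param alpha Test level for the chance-performance filter.
#' @param window Within-block stable-trial window used for the
#'   chance-performance test.
#' @return List with `kept` (subjects) and `excluded` (data frame of
#'   `subject_id`, `reason`).
#' @export
apply_exclusion_filters <- function(cohort, alpha = 0.05,
                                    window = c(10, 25)) {
  stopifnot(length(cohort) >= 1)
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    tr <- s$trials
    if (length(unique(tr$confidence)) == 1L) {
      ids <- c(ids, s$subject_id); reasons <- c(reasons, "single_confidence_level")
      next
    }
    w <- tr[window_rows(tr, window), ]
    n_good <- sum(w$chosen_arm == "good")
    p <- binom.test(n_good, nrow(w), p = 0.5,
                    alternative = "greater")$p.value
    if (p >= alpha) {
      ids <- c(ids, s$subject_id); reasons <- c(reasons, "chance_performance")
      next
    }
    keep[i] <- TRUE
  }
  list(kept = cohort[keep],
       excluded = data.frame(subject_id = ids, reason = reasons))
}

#' Write / read trial tables as CSV
#'
#' One row per trial with columns `subject_id`, `trial`, `block`,
#' `condition`, `phase`, `trial_in_block`, `chosen_arm`, `confidence`,
#' `reward`, `rt`. Ground truth (model, parameters) can be written to a
#' sidecar JSON. Reading reconstructs a list of `bandit_subject` objects;
#' round trips are exact.
#'
#' @param cohort A `bandit_subject` or list of them.
#' @param path CSV path.
#' @param truth_path Optional JSON path for the ground-truth sidecar.
#' @return `write_trials`: `path` invisibly. `read_trials`: list of
#'   `bandit_subject` objects.
#' @export
write_trials <- function(cohort, path, truth_path = NULL) {
  if (inherits(cohort, "bandit_subject")) cohort <- list(cohort)
  tabs <- lapply(cohort, function(s) {
    cbind(subject_id = s$subject_id, s$trials)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- lapply(cohort, function(s) {
      list(subject_id = s$subject_id, model = s$model,
           params = as.list(s$params),
           pathology = if (is.null(s$pathology)) NULL else s$pathology)
    })
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, truth_path = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  truth <- if (!is.null(truth_path)) {
    tl <- jsonlite::read_json(truth_path, simplifyVector = FALSE)
    setNames(tl, vapply(tl, `[[`, "", "subject_id"))
  }
  lapply(split(tab, tab$subject_id)[unique(tab$subject_id)], function(d) {
    d <- d[order(d$trial), ]
    tr <- d[, setdiff(names(d), "subject_id")]
    rownames(tr) <- NULL
    tr$condition <- ifelse(tr$condition == "" | is.na(tr$condition),
                           NA_character_, tr$condition)
    tr$rt <- as.numeric(tr$rt)
    s <- list(subject_id = d$subject_id[1], model = NULL, params = NULL,
              design = NULL, trials = tr)
    if (!is.null(truth) && d$subject_id[1] %in% names(truth)) {
      t1 <- truth[[d$subject_id[1]]]
      s$model <- t1$model
      s$params <- unlist(t1$params)
      if (!is.null(t1$pathology)) s$pathology <- t1$pathology
    }
    structure(s, class = "bandit_subject")
  })
}
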