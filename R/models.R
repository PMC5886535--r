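# Model families and their primitive operations.
#
# Four families, each with an optional drift of the unchosen option toward
# the acceptability threshold ("-T" variants):
#   reward  : tracks each arm's mean reward Q by a delta rule and chooses
#             on Q itself.
#   utility : additionally tracks reward variance V and chooses on the
#             mean-variance certainty equivalent Q - lambda * V / 2
#             (exponential utility on Gaussian payoffs).
#   ssat    : tracks Q and V and chooses on the satisficing probability
#             P(payoff > T) under the Normal(Q, V) belief.
#   power   : like reward but learns from power-utility-transformed payoffs
#             U(R) = R^(1 - rho) / (1 - rho).
#
# All quantities live on the normalized reward scale (points / 100).

.FAMILY_CODES <- c(reward = 1L, utility = 2L, ssat = 3L, power = 4L)

.MODEL_PARAMS <- list(
  reward    = c("alpha", "beta"),
  reward_t  = c("alpha", "beta", "threshold"),
  utility   = c("alpha", "beta", "gamma", "lambda"),
  utility_t = c("alpha", "beta", "gamma", "lambda", "threshold"),
  ssat      = c("alpha", "beta", "gamma", "threshold"),
  ssat_t    = c("alpha", "beta", "gamma", "threshold"),
  power     = c("alpha", "beta", "rho"),
  power_t   = c("alpha", "beta", "rho", "threshold")
)

#' Registry of implemented model variants
#'
#' Eight model variants: the four families crossed with the optional drift
#' of the unchosen option toward the acceptability threshold. Keys follow
#' the `family` / `family_t` convention (`"ssat_t"` is the stochastic
#' satisficing model with drift).
#'
#' @return A data frame with columns `model`, `family`, `drift` and a
#'   comma-separated list of the free parameters each variant uses.
#' @examples
#' bandit_models()
#' @export
bandit_models <- function() {
  keys <- names(.MODEL_PARAMS)
  data.frame(
    model = keys,
    family = sub("_t$", "", keys),
    drift = grepl("_t$", keys),
    parameters = vapply(.MODEL_PARAMS, paste, "", collapse = ", "),
    row.names = NULL
  )
}

#' Resolve a model key into its family, drift flag and parameter set
#'
#' @param model One of the keys listed by [bandit_models()].
#' @return A list with `model`, `family`, `family_code`, `drift` and
#'   `params` (character vector of free-parameter names).
#' @export
model_spec <- function(model) {
  if (length(model) != 1L || !model %in% names(.MODEL_PARAMS)) {
    stop("unknown model '", paste(model, collapse = ","),
         "'; see bandit_models()", call. = FALSE)
  }
  family <- sub("_t$", "", model)
  list(model = model, family = family,
       family_code = .FAMILY_CODES[[family]],
       drift = grepl("_t$", model),
       params = .MODEL_PARAMS[[model]])
}

.PARAM_LOWER <- c(alpha = 0, beta = 0, gamma = 0, lambda = 0,
                  threshold = 0, rho = 0)
.PARAM_UPPER <- c(alpha = 1, beta = Inf, gamma = 1, lambda = Inf,
                  threshold = 1, rho = 0.99)

#' Validate a parameter set for a model variant
#'
#' Checks that every free parameter of `model` is present, finite and
#' within its bounds (`alpha`, `gamma`, `threshold` in (0,1); `beta`,
#' `lambda` non-negative; `rho` in `[0, 0.99]`).
#'
#' @param params Named list or numeric vector of parameter values.
#' @param model Model key (see [bandit_models()]).
#' @return The parameters as a named numeric vector (invisibly usable).
#' @export
validate_params <- function(params, model) {
  spec <- model_spec(model)
  params <- unlist(params)
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop("model '", model, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (p in spec$params) {
    v <- params[[p]]
    if (!is.finite(v) || v < .PARAM_LOWER[[p]] || v > .PARAM_UPPER[[p]]) {
      stop("parameter '", p, "' = ", v, " outside [",
           .PARAM_LOWER[[p]], ", ", .PARAM_UPPER[[p]], "]", call. = FALSE)
    }
  }
  params[spec$params]
}

# Full length-6 parameter vector in the order the compiled core expects.
# Unused slots get inert placeholders.
par_vector <- function(params, model) {
  params <- validate_params(params, model)
  full <- c(alpha = 0, beta = 0, gamma = 0, lambda = 0,
            threshold = 0.5, rho = 0)
  full[names(params)] <- params
  unname(full)
}

#' Initial belief state
#'
#' Tracked mean and variance per arm on the normalized reward scale.
#' Defaults: mean at the scale midpoint, sd 0.2.
#'
#' @param Q Named numeric `c(good=, bad=)`, tracked mean reward per arm.
#' @param V Named numeric `c(good=, bad=)`, tracked reward variance per arm.
#' @return A list with elements `Q` and `V`.
#' @export
belief_state <- function(Q = c(good = 0.5, bad = 0.5),
                         V = c(good = 0.04, bad = 0.04)) {
  stopifnot(all(c("good", "bad") %in% names(Q)),
            all(c("good", "bad") %in% names(V)),
            all(is.finite(Q)), all(V > 0))
  list(Q = Q[c("good", "bad")], V = V[c("good", "bad")])
}

#' Power utility transform
#'
#' `U(R) = R^(1 - rho) / (1 - rho)` with risk-aversion exponent
#' `rho` in `[0, 1)`; `rho = 0` is the identity and the ordering
#' approaches `log(R)` as `rho` approaches 1.
#'
#' @param reward Positive reward (normalized scale).
#' @param rho Risk-aversion exponent in `[0, 1)`.
#' @return Transformed reward.
#' @export
power_utility <- function(reward, rho) {
  if (any(rho >= 1) || any(rho < 0)) stop("rho must lie in [0, 1)")
  if (any(reward <= 0)) stop("reward must be positive")
  reward^(1 - rho) / (1 - rho)
}

#' Mean-variance certainty equivalent
#'
#' Expected exponential utility of a Gaussian payoff `Normal(Q, V)`
#' is ordered by `Q - lambda * V / 2`; this is the value the utility
#' family maximizes.
#'
#' @param Q Tracked mean reward.
#' @param V Tracked reward variance (>= 0).
#' @param lambda Risk-aversion coefficient (> 0; the limit `lambda -> 0`
#'   recovers the risk-neutral mean).
#' @return `Q - lambda * V / 2`.
#' @export
certainty_equivalent <- function(Q, V, lambda) {
  if (any(V < 0)) stop("V must be non-negative")
  Q - lambda * V / 2
}

#' Satisficing probability
#'
#' Probability that a payoff drawn from the `Normal(Q, V)` belief exceeds
#' the acceptability threshold `T`: the Gaussian upper-tail probability
#' `1 - Phi((T - Q)/sqrt(V))`. Strictly increasing in `Q`, decreasing in
#' `T`; increasing in `V` iff `Q < T` (the asymmetric variance effect).
#'
#' @param Q Tracked mean reward.
#' @param V Tracked reward variance (> 0).
#' @param threshold Acceptability threshold on the normalized scale.
#' @return Probability in (0, 1).
#' @export
satisficing_probability <- function(Q, V, threshold) {
  if (any(V <= 0)) stop("V must be positive")
  pnorm((Q - threshold) / sqrt(V))
}

#' One belief-update step
#'
#' Delta-rule update of the chosen arm's tracked mean (on the
#' utility-transformed payoff for the power family), variance tracking for
#' the families that use it (utility, ssat), and, for drift variants, decay
#' of the unchosen arm's mean toward the acceptability threshold.
#'
#' @param belief A [belief_state()].
#' @param chosen_arm `"good"` or `"bad"`.
#' @param reward Obtained reward on the normalized scale.
#' @param params Named parameters for `model` (see [validate_params()]).
#' @param model Model key.
#' @return The updated belief state.
#' @export
update_beliefs <- function(belief, chosen_arm, reward, params, model) {
  spec <- model_spec(model)
  params <- validate_params(params, model)
  stopifnot(chosen_arm %in% c("good", "bad"))
  if (!is.finite(reward) || reward < 0 || reward > 1) {
    stop("reward must lie on the normalized [0, 1] scale")
  }
  a <- chosen_arm
  b <- setdiff(c("good", "bad"), a)
  x <- if (spec$family == "power") power_utility(reward, params[["rho"]])
       else reward
  q_old <- belief$Q[[a]]
  belief$Q[[a]] <- q_old + params[["alpha"]] * (x - q_old)
  if (spec$family %in% c("utility", "ssat")) {
    v_new <- belief$V[[a]] +
      params[["gamma"]] * ((reward - q_old)^2 - belief$V[[a]])
    belief$V[[a]] <- max(v_new, 1e-6)
  }
  if (spec$drift) {
    target <- if (spec$family == "power")
      power_utility(params[["threshold"]], params[["rho"]])
    else params[["threshold"]]
    belief$Q[[b]] <- belief$Q[[b]] +
      params[["alpha"]] * (target - belief$Q[[b]])
  }
  belief
}

#' Decision variables of both arms
#'
#' The family-specific quantity the softmax compares: tracked mean
#' (reward/power), certainty equivalent (utility) or satisficing
#' probability (ssat).
#'
#' @inheritParams update_beliefs
#' @return Named numeric `c(good=, bad=)`.
#' @export
decision_variables <- function(belief, params, model) {
  spec <- model_spec(model)
  params <- validate_params(params, model)
  switch(spec$family,
    reward = ,
    power = belief$Q,
    utility = certainty_equivalent(belief$Q, belief$V, params[["lambda"]]),
    ssat = satisficing_probability(belief$Q, belief$V,
                                   params[["threshold"]])
  )
}

#' Softmax choice probability
#'
#' Probability of choosing arm a given the two decision variables and the
#' inverse temperature `beta`; computed from the difference, so it is
#' translation invariant and overflow safe.
#'
#' @param dv_a,dv_b Decision variables of the two arms.
#' @param beta Inverse temperature (>= 0; `beta = 0` is indifference).
#' @return `P(choose a)` in (0, 1).
#' @export
choice_probability <- function(dv_a, dv_b, beta) {
  if (any(beta < 0)) stop("beta must be non-negative")
  plogis(beta * (dv_a - dv_b))
}

#' Model-predicted confidence
#'
#' The chosen arm's decision variable: the satisficing probability for the
#' ssat family, the certainty equivalent for the utility family, and the
#' tracked mean for the reward and power families. Confidence reports are
#' modelled as proportional to this quantity.
#'
#' @inheritParams update_beliefs
#' @return The chosen arm's decision variable.
#' @export
predicted_confidence <- function(belief, params, model, chosen_arm) {
  stopifnot(chosen_arm %in% c("good", "bad"))
  decision_variables(belief, params, model)[[chosen_arm]]
}
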