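# Reward environments of the two block-design experiments.
#
# Experiment 1 (240 trials): six stable blocks, good/bad arm means fixed at
# 65/35 points, arm variances high (625) or low (100) in a 2x2 design (four
# conditions plus two seeded-random repeats), 10-trial linear transitions.
# Experiment 2 (160 trials): four blocks, bad arm fixed at mean 35 /
# variance 100, good arm mean in {57, 72} x variance in {25, 400}.
#
# Condition labels: exp1 "v<G>-v<B>" where the first letter is the *good*
# option's variance level and the second the bad option's; exp2 "m<G>-v<G>"
# for the good option's mean and variance levels.

.EXP1_CONDITIONS <- data.frame(
  condition = c("vL-vL", "vL-vH", "vH-vL", "vH-vH"),
  good_mean = 65, good_var = c(100, 100, 625, 625),
  bad_mean = 35, bad_var = c(100, 625, 100, 625)
)

.EXP2_CONDITIONS <- data.frame(
  condition = c("mL-vL", "mL-vH", "mH-vL", "mH-vH"),
  good_mean = c(57, 57, 72, 72), good_var = c(25, 400, 25, 400),
  bad_mean = 35, bad_var = 100
)

# Draw stable-block lengths uniformly from {27,...,35} and adjust the final
# block so the stable trials sum exactly to `target`; redraw until the
# adjusted final length stays in [25, 35].
draw_block_lengths <- function(n_blocks, target) {
  for (i in 1:1000) {
    len <- sample(27:35, n_blocks, replace = TRUE)
    len[n_blocks] <- target - sum(len[-n_blocks])
    if (len[n_blocks] >= 25 && len[n_blocks] <= 35) return(len)
  }
  stop("could not draw feasible block lengths for ", target,
       " stable trials") # nocov
}

#' Build an experiment design
#'
#' Constructs the block sequence, Gaussian arm parameters and transition
#' structure of one of the two experiments. Block order (and, for
#' experiment 1, which two of the four conditions repeat) is seeded-random;
#' stable block lengths are drawn uniformly from 27--35 trials with the
#' final block adjusted so stable plus transition trials total exactly 240
#' (exp1) or 160 (exp2).
#'
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @param seed Integer seed; the same seed always yields the same design.
#' @param transition_length Trials per between-block linear transition
#'   (default 10; 0 gives step changes).
#' @return An object of class `bandit_design`: list with `experiment_id`,
#'   `blocks` (each with `condition`, `good`/`bad` arm mean and variance,
#'   `n_stable_trials`, `repeat_of_earlier`), `transition_length`,
#'   `total_trials`, `seed`.
#' @examples
#' d <- build_design("exp1", seed = 1)
#' d
#' @export
build_design <- function(experiment_id = c("exp1", "exp2"), seed = NULL,
                         transition_length = 10) {
  experiment_id <- match.arg(experiment_id)
  stopifnot(transition_length >= 0)
  with_seed(seed, {
    if (experiment_id == "exp1") {
      cond <- .EXP1_CONDITIONS
      total <- 240L
      idx <- c(1:4, sample(1:4, 2))       # four conditions + two repeats
    } else {
      cond <- .EXP2_CONDITIONS
      total <- 160L
      idx <- 1:4
    }
    idx <- sample(idx)                     # block order
    n_blocks <- length(idx)
    n_trans <- (n_blocks - 1L) * transition_length
    stable_target <- total - n_trans
    if (stable_target < 25L * n_blocks) {
      stop("stable block lengths infeasible for total_trials = ", total)
    }
    lengths <- draw_block_lengths(n_blocks, stable_target)
    seen <- integer(0)
    blocks <- lapply(seq_len(n_blocks), function(i) {
      k <- idx[i]
      rep_flag <- k %in% seen
      seen <<- c(seen, k)
      list(condition = cond$condition[k],
           good = list(mean = cond$good_mean[k], variance = cond$good_var[k]),
           bad = list(mean = cond$bad_mean[k], variance = cond$bad_var[k]),
           n_stable_trials = lengths[i],
           repeat_of_earlier = rep_flag)
    })
    structure(list(experiment_id = experiment_id, blocks = blocks,
                   transition_length = as.integer(transition_length),
                   total_trials = total, seed = seed),
              class = "bandit_design")
  })
}

#' @export
print.bandit_design <- function(x, ...) {
  cat("Two-armed bandit design (", x$experiment_id, "): ",
      x$total_trials, " trials, ", length(x$blocks), " stable blocks, ",
      x$transition_length, "-trial transitions\n", sep = "")
  for (b in x$blocks) {
    cat(sprintf("  %-6s good N(%g, %g)  bad N(%g, %g)  %d stable trials%s\n",
                b$condition, b$good$mean, b$good$variance,
                b$bad$mean, b$bad$variance, b$n_stable_trials,
                if (isTRUE(b$repeat_of_earlier)) "  [repeat]" else ""))
  }
  invisible(x)
}

#' Trial-wise true arm parameters
#'
#' Expands a design into one row per trial. Within stable blocks the arm
#' parameters are constant; within a transition each parameter moves
#' linearly from the old to the new block value (trial j of an L-trial
#' transition sits at fraction j / (L + 1) of the way).
#'
#' @param design A [build_design()] object.
#' @return Data frame with columns `trial`, `block`, `condition`, `phase`
#'   (`"stable"` or `"transition"`), `trial_in_block` (position within the
#'   stable segment; NA in transitions), `mu_good`, `var_good`, `mu_bad`,
#'   `var_bad` (points scale).
#' @export
trialwise_parameters <- function(design) {
  stopifnot(inherits(design, "bandit_design"))
  rows <- list()
  tl <- design$transition_length
  nb <- length(design$blocks)
  for (i in seq_len(nb)) {
    b <- design$blocks[[i]]
    n <- b$n_stable_trials
    rows[[length(rows) + 1L]] <- data.frame(
      block = i, condition = b$condition, phase = "stable",
      trial_in_block = seq_len(n),
      mu_good = b$good$mean, var_good = b$good$variance,
      mu_bad = b$bad$mean, var_bad = b$bad$variance
    )
    if (i < nb && tl > 0) {
      nxt <- design$blocks[[i + 1L]]
      f <- seq_len(tl) / (tl + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        block = i, condition = NA_character_, phase = "transition",
        trial_in_block = NA_integer_,
        mu_good = b$good$mean + f * (nxt$good$mean - b$good$mean),
        var_good = b$good$variance + f * (nxt$good$variance - b$good$variance),
        mu_bad = b$bad$mean + f * (nxt$bad$mean - b$bad$mean),
        var_bad = b$bad$variance + f * (nxt$bad$variance - b$bad$variance)
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  stopifnot(nrow(out) == design$total_trials)
  out
}

#' Sample clipped integer rewards
#'
#' Gaussian draws rounded to integer points and clipped to the task's
#' 1--100 point range.
#'
#' @param mu Mean (points).
#' @param sigma2 Variance (> 0, squared points).
#' @param n Number of draws.
#' @return Integer vector of rewards in `[1, 100]`.
#' @export
sample_reward <- function(mu, sigma2, n = 1) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  as.integer(pmin(100, pmax(1, round(rnorm(n, mu, sqrt(sigma2))))))
}

#' Normalize / denormalize reward points
#'
#' Modelling runs on the `points / 100` scale, on which fitted
#' acceptability thresholds are directly comparable to point values
#' (35 points -> 0.35).
#'
#' @param points Integer points in `[1, 100]`.
#' @return `normalize_reward`: values in `[0.01, 1]`.
#' @export
normalize_reward <- function(points) {
  if (any(points < 1 | points > 100)) stop("points must lie in [1, 100]")
  points / 100
}

#' @rdname normalize_reward
#' @param x Normalized rewards in `[0.01, 1]`.
#' @return `denormalize_reward`: points in `[1, 100]`.
#' @export
denormalize_reward <- function(x) {
  if (any(x < 0.01 | x > 1)) stop("x must lie in [0.01, 1]")
  x * 100
}

#' Read and write designs as JSON
#'
#' @param design A [build_design()] object.
#' @param path File path.
#' @return `read_design` returns the `bandit_design`; `write_design`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bandit_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$transition_length <- as.integer(x$transition_length)
  x$total_trials <- as.integer(x$total_trials)
  x$blocks <- lapply(x$blocks, function(b) {
    b$n_stable_trials <- as.integer(b$n_stable_trials)
    b
  })
  structure(x, class = "bandit_design")
}
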