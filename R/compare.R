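# Cross-model comparison of per-subject fits: WAIC and confidence-R^2
# tables, paired tests, best-model tallies, and cross-model parameter
# correlations.

#' Compare fitted models across subjects
#'
#' Takes per-subject fits of several models and assembles the comparison
#' statistics: per-model WAIC sums and mean +/- sd, confidence-R^2 mean +/-
#' sd, paired two-sided t-tests of each model against the WAIC-best (and
#' R^2-best) model, per-subject best-model tallies, and squared
#' correlations of matched parameters (learning rate, threshold) between
#' model pairs.
#'
#' @param fits List of [fit_bandit()] objects covering every subject x
#'   model combination (all subjects must be fitted under all models).
#' @return An object of class `bandit_comparison` with components `table`
#'   (per-model summary), `waic_tests` and `r2_tests` (paired t-test
#'   p-values against the respective best model), `best_counts`
#'   (per-subject tallies by WAIC and by R^2), `param_r2` (cross-model
#'   squared parameter correlations), `waic` and `r2` (subject x model
#'   matrices).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  subj <- vapply(fits, function(f) f$subject_id, "")
  mod <- vapply(fits, function(f) f$model, "")
  models <- unique(mod)
  subjects <- unique(subj)
  key <- paste(subj, mod)
  if (anyDuplicated(key)) stop("duplicate subject x model fits")
  full <- outer(subjects, models, function(s, m) paste(s, m))
  if (!all(full %in% key)) stop("all subjects must be fitted under all models")
  idx <- function(s, m) which(subj == s & mod == m)
  waic_m <- outer(subjects, models,
                  Vectorize(function(s, m) fits[[idx(s, m)]]$waic))
  r2_m <- outer(subjects, models,
                Vectorize(function(s, m) fits[[idx(s, m)]]$confidence_r2))
  dimnames(waic_m) <- dimnames(r2_m) <- list(subjects, models)

  tab <- data.frame(
    model = models,
    sum_waic = colSums(waic_m),
    mean_waic = colMeans(waic_m),
    sd_waic = apply(waic_m, 2, sd),
    mean_r2 = colMeans(r2_m, na.rm = TRUE),
    sd_r2 = apply(r2_m, 2, sd, na.rm = TRUE),
    row.names = NULL
  )
  best_waic <- models[which.min(tab$sum_waic)]
  best_r2 <- models[which.max(tab$mean_r2)]

  paired_p <- function(mat, ref, better_low) {
    vapply(models, function(m) {
      if (m == ref) return(NA_real_)
      d <- mat[, m] - mat[, ref]
      if (length(d) < 2 || sd(d, na.rm = TRUE) == 0) return(NA_real_)
      t.test(d)$p.value
    }, numeric(1))
  }
  waic_tests <- paired_p(waic_m, best_waic)
  r2_tests <- paired_p(r2_m, best_r2)

  best_counts <- data.frame(
    model = models,
    n_best_waic = vapply(models, function(m)
      sum(apply(waic_m, 1, function(r) models[which.min(r)] == m)), 0L),
    n_best_r2 = vapply(models, function(m)
      sum(apply(r2_m, 1, function(r) models[which.max(r)] == m)), 0L),
    row.names = NULL
  )

  # cross-model squared correlations of shared parameters across subjects
  shared <- c("alpha", "threshold")
  pairs <- if (length(models) >= 2) utils::combn(models, 2) else NULL
  param_r2 <- NULL
  if (!is.null(pairs) && length(subjects) >= 3) {
    rows <- list()
    get_par <- function(s, m, p) {
      e <- fits[[idx(s, m)]]$estimates
      if (p %in% rownames(e)) e[p, "mean"] else NA_real_
    }
    for (k in seq_len(ncol(pairs))) {
      m1 <- pairs[1, k]; m2 <- pairs[2, k]
      for (p in shared) {
        x <- vapply(subjects, get_par, 0, m = m1, p = p)
        y <- vapply(subjects, get_par, 0, m = m2, p = p)
        if (all(is.finite(x)) && all(is.finite(y)) &&
            sd(x) > 0 && sd(y) > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            model1 = m1, model2 = m2, parameter = p,
            r2 = cor(x, y)^2)
        }
      }
    }
    if (length(rows)) param_r2 <- do.call(rbind, rows)
  }

  structure(list(table = tab, best_waic = best_waic, best_r2 = best_r2,
                 waic_tests = waic_tests, r2_tests = r2_tests,
                 best_counts = best_counts, param_r2 = param_r2,
                 waic = waic_m, r2 = r2_m),
            class = "bandit_comparison")
}

#' @export
print.bandit_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison over", nrow(x$waic), "subjects\n\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("\nBest by choice WAIC:", x$best_waic,
      "  best by confidence R^2:", x$best_r2, "\n")
  cat("Per-subject best-model counts:\n")
  print(x$best_counts, row.names = FALSE)
  invisible(x)
}
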