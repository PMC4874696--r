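# Method-comparison harness: parameter-recovery R2, rank-first rate,
# family-wise empirical type-I error, ROC/AUC over feature scores, a
# random-forest comparator, and the replicated simulation driver that
# pits multiple logistic regression against the enrichment test (and
# optionally random forests) on threshold-model data.

#' Squared correlation between true and estimated parameters, in percent
#'
#' @param true,est Equal-length numeric vectors (length >= 3) of true and
#'   estimated parameter values.
#' @return `100 * cor(true, est)^2`.
#' @export
recovery_r2 <- function(true, est) {
  if (length(true) != length(est) || length(true) < 3) {
    abort("`true` and `est` must be equal-length vectors of length >= 3.")
  }
  if (anyNA(true) || anyNA(est)) abort("Missing values in parameter vectors.")
  if (sd(true) == 0 || sd(est) == 0) {
    abort("Zero variance: recovery R2 is undefined.")
  }
  100 * cor(true, est)^2
}

#' Area under the ROC curve of feature scores
#'
#' Ranks features by score and measures how well known positives separate
#' from negatives; ties are handled by midranks, making the result equal
#' to the Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param scores Numeric score per feature (e.g. MLR betas, enrichment
#'   Wald statistics, RF importances).
#' @param labels Binary/logical known-positive flags, same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (anyNA(scores)) abort("Missing scores.")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present in `labels`.")
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest variable importances as a comparator
#'
#' Trains a random-forest classifier of border status on the feature
#' matrix and returns one importance value per feature (mean decrease in
#' Gini impurity). Deterministic for a given seed.
#'
#' @param data A `tad_matrix` or data frame with binary `Y`.
#' @param features Feature columns (defaults to all).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `feature` and `importance`.
#' @export
rf_importance <- function(data, features = NULL, n_trees = 500,
                          mtry = NULL, seed = NULL) {
  d <- design_matrix(data, features)
  if (length(unique(d$y)) < 2) {
    abort("`Y` is degenerate: both classes are required.")
  }
  n_trees <- check_count(n_trees, "n_trees")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(d$X))))
  rf <- with_seed(seed, randomForest::randomForest(
    x = d$X, y = factor(d$y, levels = c(0, 1)),
    ntree = n_trees, mtry = mtry
  ))
  tibble(feature = d$features,
         importance = unname(rf$importance[, "MeanDecreaseGini"]))
}

#' Fraction of replicates whose top-ranked feature is causal
#'
#' For each replicate and method, the feature with the largest score
#' (beta for regression methods, importance for random forests) is looked
#' up; the rate is the percentage of replicates in which it is causal. A
#' tie at the top counts as a failure.
#'
#' @param records Long tibble with columns `replicate`, `method`,
#'   `feature`, `score`, `causal` (see [run_comparison()]).
#' @return A tibble with `method` and `rank_first` (percent).
#' @export
rank_first_rate <- function(records) {
  need <- c("replicate", "method", "feature", "score", "causal")
  if (!all(need %in% names(records))) {
    abort(sprintf("`records` must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (anyNA(records$score)) abort("Missing scores in `records`.")
  records |>
    dplyr::group_by(.data$method, .data$replicate) |>
    dplyr::summarise(
      hit = sum(.data$score == max(.data$score)) == 1L &&
        .data$causal[which.max(.data$score)],
      .groups = "drop_last"
    ) |>
    dplyr::summarise(rank_first = 100 * mean(.data$hit), .groups = "drop")
}

#' Family-wise empirical type-I error rate
#'
#' The percentage of replicates in which at least one non-causal feature
#' reaches `p < alpha` — the family-wise definition of a false-positive
#' replicate. Methods without p-values (random forests) must be excluded
#' upstream.
#'
#' @param records Long tibble with columns `replicate`, `method`,
#'   `feature`, `p_value`, `causal`.
#' @param alpha Significance threshold in (0, 1); the comparison studies
#'   use `1e-5`.
#' @return A tibble with `method` and `type1_error` (percent).
#' @export
type1_error_rate <- function(records, alpha = 1e-5) {
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  need <- c("replicate", "method", "feature", "p_value", "causal")
  if (!all(need %in% names(records))) {
    abort(sprintf("`records` must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (anyNA(records$p_value)) {
    abort("Missing p-values in `records`; drop methods without p-values first.")
  }
  records |>
    dplyr::group_by(.data$method, .data$replicate) |>
    dplyr::summarise(
      fp = any(!.data$causal & .data$p_value < alpha),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(type1_error = 100 * mean(.data$fp), .groups = "drop")
}

#' Replicated comparison of MLR, enrichment test and random forests
#'
#' For each replicate: generate a sparse correlated feature matrix, draw
#' a random causal subset, derive the threshold-model probabilities
#' `(p0, p1)` from the target odds ratio at the realized exposure rate,
#' simulate border labels, then score every feature with each method
#' (MLR betas + Wald p-values; per-feature enrichment-test betas +
#' p-values; optionally RF importances). Replicates where a fit fails
#' (e.g. separation) are dropped and counted.
#'
#' @param n_reps Number of replicates.
#' @param target_or Exposure odds ratio of the threshold model.
#' @param n_rows Rows (bins) per replicate (default 1e5).
#' @param p_features Number of features (default 11).
#' @param sparsity,correlation Passed to [synth_feature_matrix()].
#' @param border_rate Marginal border probability (default 0.01,
#'   border bins are rare).
#' @param causal_n Candidate causal-set sizes; one is drawn uniformly per
#'   replicate (default `1:3`).
#' @param methods Subset of `c("mlr", "et", "rf")`.
#' @param alpha Significance threshold recorded with the result
#'   (default 1e-5).
#' @param rf_trees Trees for the RF comparator (default 500).
#' @param seed Optional RNG seed governing the whole run.
#' @return A `tad_benchmark` list: `records` (one row per replicate x
#'   method x feature: `score`, `p_value`, `causal`), `summary`
#'   (rank-first and type-I error rates per method), `n_failed`, and the
#'   configuration. `tidy()` returns the records, `glance()` the summary.
#' @export
run_comparison <- function(n_reps, target_or, n_rows = 1e5,
                           p_features = 11, sparsity = 0.97,
                           correlation = 0.25, border_rate = 0.01,
                           causal_n = 1:3,
                           methods = c("mlr", "et"),
                           alpha = 1e-5, rf_trees = 500, seed = NULL) {
  n_reps <- check_number(n_reps, "n_reps", lower = 0)
  methods <- match.arg(methods, c("mlr", "et", "rf"), several.ok = TRUE)
  check_number(target_or, "target_or", lower = 1)
  if (n_reps == 0) {
    return(new_tad_benchmark(list(), 0L, target_or, alpha, methods))
  }
  # pre-calibrate outside the seeded block so the cache state cannot
  # change the replicate RNG stream
  calibrate_latent_rho(sparsity, correlation)
  records <- with_seed(seed, purrr::map(seq_len(n_reps), function(rep) {
    n_c <- if (length(causal_n) == 1) causal_n else sample(causal_n, 1)
    causal <- sample(seq_len(p_features), n_c)
    X <- synth_feature_matrix(n_rows, p_features, sparsity = sparsity,
                              correlation = correlation)
    feats <- feature_names(X)
    exposed <- rowSums(as.matrix(X[feats[causal]]) >= 0.5) > 0
    exposure_rate <- mean(exposed)
    if (exposure_rate <= 0 || exposure_rate >= 1) return(NULL)
    pp <- solve_p0_p1(target_or, border_rate, exposure_rate)
    sim <- simulate_threshold_response(X, causal = feats[causal],
                                       p0 = pp$p0, p1 = pp$p1)
    out <- tryCatch({
      rows <- list()
      if ("mlr" %in% methods) {
        fit <- fit_mlr(sim$data)
        rows$mlr <- tibble(method = "mlr", feature = feats,
                           score = unname(fit$betas),
                           p_value = unname(fit$p_values))
      }
      if ("et" %in% methods) {
        et <- enrichment_scan(sim$data, alpha = alpha)
        if (anyNA(et$estimate)) abort("enrichment test failed")
        rows$et <- tibble(method = "et", feature = et$feature,
                          score = et$estimate, p_value = et$p.value)
      }
      if ("rf" %in% methods) {
        imp <- rf_importance(sim$data, n_trees = rf_trees)
        rows$rf <- tibble(method = "rf", feature = imp$feature,
                          score = imp$importance, p_value = NA_real_)
      }
      purrr::list_rbind(rows)
    }, error = function(e) NULL)
    if (is.null(out)) return(NULL)
    dplyr::mutate(out, replicate = rep, causal = .data$feature %in%
                    feats[causal], .before = 1)
  }))
  new_tad_benchmark(records, n_reps, target_or, alpha, methods)
}

new_tad_benchmark <- function(records, n_reps, target_or, alpha, methods) {
  failed <- sum(vapply(records, is.null, logical(1)))
  records <- purrr::list_rbind(purrr::compact(records))
  if (nrow(records) > 0) {
    summary <- rank_first_rate(records)
    with_p <- dplyr::filter(records, !is.na(.data$p_value))
    if (nrow(with_p) > 0) {
      summary <- dplyr::left_join(summary,
                                  type1_error_rate(with_p, alpha = alpha),
                                  by = "method")
    } else {
      summary$type1_error <- NA_real_
    }
  } else {
    summary <- tibble(method = character(), rank_first = numeric(),
                      type1_error = numeric())
  }
  structure(list(records = records, summary = summary, n_failed = failed,
                 n_reps = n_reps, target_or = target_or, alpha = alpha,
                 methods = methods),
            class = "tad_benchmark")
}

#' @export
print.tad_benchmark <- function(x, ...) {
  cat(sprintf(
    "Method comparison: %d replicate(s), odds ratio %.3g, alpha %.1e (%d failed)\n",
    x$n_reps, x$target_or, x$alpha, x$n_failed
  ))
  print(x$summary, ...)
  invisible(x)
}
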