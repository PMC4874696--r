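# Multiple logistic regression over all features: IRLS maximum likelihood
# with Wald and likelihood-ratio inference, optional interaction expansion,
# and L1-regularized estimation (coordinate descent via glmnet) with
# cross-validated penalty selection.

#' Fit a multiple logistic regression of border status on genomic features
#'
#' Models the log-odds of a bin being a TAD-border bin as a linear function
#' of its feature values: `logit P(Y = 1 | X) = beta0 + beta %*% X`. With
#' `estimator = "irls"` the likelihood is maximized by iteratively
#' reweighted least squares and standard errors come from the inverse
#' Fisher information, giving unbiased estimates and Wald inference. With
#' `estimator = "l1"` the coefficients are estimated by L1-penalized
#' coordinate descent; the penalty that minimizes the mean cross-validated
#' binomial deviance is selected, no standard errors are produced, and a
#' feature counts as influential when its coefficient is non-zero.
#'
#' @param data A `tad_matrix` (see [assemble_matrix()]) or any data frame
#'   with a binary `Y` column and numeric feature columns.
#' @param features Feature columns to include; defaults to all feature
#'   columns of `data`.
#' @param estimator `"irls"` (maximum likelihood, default) or `"l1"`.
#' @param interactions Optional interaction specification passed to
#'   [expand_interactions()] before fitting (`"all"` or pairs like
#'   `c("A:B", "A:C")`).
#' @param tol IRLS convergence tolerance on the maximum absolute
#'   coefficient change (default `1e-8`).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param lambda Optional penalty grid for `estimator = "l1"`; by default
#'   a 100-value log-spaced path down to `1e-4` of the smallest
#'   all-zeroing penalty is used.
#' @param n_folds Cross-validation folds for `estimator = "l1"`
#'   (default 10); folds are stratified by `Y`.
#' @param standardize Standardize features before L1 fitting? Default
#'   `FALSE`: coordinate-mode occupancy fractions already share the
#'   `[0, 1]` scale, and unscaled coefficients stay interpretable as
#'   per-full-bin log-odds effects. Consider `TRUE` for quantitative mode.
#' @param seed Seed for the fold assignment of the L1 cross-validation.
#'
#' @return An object of class `tad_mlr`: a list with the intercept
#'   (`beta0`), named slope estimates (`betas`), and for IRLS fits the
#'   standard errors (`ses`), Wald statistics (`W`), two-sided normal
#'   p-values, confidence bounds, plus `loglik`, `deviance`,
#'   `null_deviance`, `deviance_ratio` (fitted-to-null deviance ratio;
#'   see [fit_metrics()]), `aic`, `converged`, `n_iter`, `estimator` and,
#'   for L1 fits, the selected `lambda`. Use [tidy()] / [glance()] to get
#'   tibbles and [autoplot()] for a coefficient plot.
#' @examples
#' m <- synth_feature_matrix(2000, 3, sparsity = 0.5, correlation = 0,
#'                           seed = 1)
#' sim <- simulate_logistic_response(m, intercept_mean = -1, seed = 2)
#' fit <- fit_mlr(sim$data)
#' tidy(fit)
#' @export
fit_mlr <- function(data, features = NULL,
                    estimator = c("irls", "l1"),
                    interactions = NULL,
                    tol = 1e-8, max_iter = 100L, conf_level = 0.95,
                    lambda = NULL, n_folds = 10L, standardize = FALSE,
                    seed = NULL) {
  estimator <- match.arg(estimator)
  if (!is.null(interactions)) {
    data <- expand_interactions(data, interactions, features = features)
    features <- feature_names(data)
  }
  d <- design_matrix(data, features)
  const <- apply(d$X, 2, function(v) length(unique(v)) == 1L)
  if (ncol(d$X) > 0 && any(const)) {
    abort(sprintf("Constant feature column(s): %s.",
                  paste(d$features[const], collapse = ", ")))
  }
  if (estimator == "irls") {
    fit_mlr_irls(d, tol = tol, max_iter = max_iter, conf_level = conf_level)
  } else {
    fit_mlr_l1(d, lambda = lambda, n_folds = n_folds,
               standardize = standardize, seed = seed)
  }
}

null_deviance_bernoulli <- function(y) {
  pbar <- mean(y)
  -2 * (sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar))
}

fit_mlr_irls <- function(d, tol, max_iter, conf_level) {
  X <- cbind(`(Intercept)` = 1, d$X)
  res <- logistic_irls(X, d$y, tol = tol, max_iter = max_iter)
  ses <- sqrt(diag(res$vcov))
  W <- res$beta / ses
  z <- qnorm(1 - (1 - conf_level) / 2)
  p_coef <- length(d$features)
  deviance <- -2 * res$loglik
  null_dev <- null_deviance_bernoulli(d$y)
  structure(list(
    beta0 = unname(res$beta[1]),
    betas = res$beta[-1],
    ses = ses[-1],
    se0 = unname(ses[1]),
    W = W[-1],
    p_values = 2 * pnorm(-abs(W[-1])),
    ci_low = res$beta[-1] - z * ses[-1],
    ci_high = res$beta[-1] + z * ses[-1],
    conf_level = conf_level,
    loglik = res$loglik,
    deviance = deviance,
    null_deviance = null_dev,
    deviance_ratio = deviance / null_dev,
    aic = -2 * res$loglik + 2 * (p_coef + 1),
    converged = res$converged,
    n_iter = res$n_iter,
    estimator = "irls",
    lambda = NA_real_,
    n = length(d$y),
    p = p_coef,
    features = d$features
  ), class = "tad_mlr")
}

fit_mlr_l1 <- function(d, lambda, n_folds, standardize, seed) {
  n_folds <- check_count(n_folds, "n_folds", lower = 2)
  if (ncol(d$X) < 2) {
    abort("L1 estimation needs at least 2 features.")
  }
  if (all(d$X == 0)) abort("All-zero design matrix.")
  Xs <- Matrix::Matrix(d$X, sparse = TRUE)
  if (!is.null(lambda) && length(lambda) == 1) {
    # a single requested penalty: no cross-validation, fit the path down
    # to it (glmnet's warm starts need a path) and report that lambda
    path <- unique(c(lambda * 10^seq(3, 0, length.out = 30)))
    g <- glmnet::glmnet(Xs, d$y, family = "binomial", lambda = path,
                        standardize = standardize, thresh = 1e-12)
    co <- as.numeric(stats::coef(g, s = lambda, exact = TRUE, x = Xs,
                                 y = d$y))
    lambda_min <- lambda
  } else {
    foldid <- with_seed(seed, stratified_folds(d$y, n_folds))
    cv <- glmnet::cv.glmnet(
      Xs, d$y, family = "binomial", foldid = foldid,
      lambda = lambda, nlambda = 100L, lambda.min.ratio = 1e-4,
      standardize = standardize, thresh = 1e-10
    )
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))
    lambda_min <- cv$lambda.min
  }
  beta0 <- co[1]
  betas <- setNames(co[-1], d$features)
  eta <- drop(d$X %*% betas) + beta0
  loglik <- bernoulli_loglik(d$y, eta)
  deviance <- -2 * loglik
  null_dev <- null_deviance_bernoulli(d$y)
  structure(list(
    beta0 = beta0, betas = betas,
    ses = NULL, se0 = NULL, W = NULL, p_values = NULL,
    ci_low = NULL, ci_high = NULL, conf_level = NA_real_,
    loglik = loglik, deviance = deviance, null_deviance = null_dev,
    deviance_ratio = deviance / null_dev,
    aic = NA_real_,
    converged = TRUE, n_iter = NA_integer_,
    estimator = "l1",
    lambda = lambda_min,
    n = length(d$y), p = length(d$features),
    features = d$features
  ), class = "tad_mlr")
}

# Fold assignment stratified by class so every fold sees both Y = 0 and
# Y = 1 even when borders are rare. Errors only when a class has fewer
# members than folds.
stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) {
      abort(sprintf(
        "Cannot build %d folds with both classes: class %s has only %d rows.",
        n_folds, format(cl), length(idx)
      ))
    }
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' @export
print.tad_mlr <- function(x, ...) {
  cat(sprintf(
    "Multiple logistic regression (%s), n = %d, p = %d\n",
    x$estimator, x$n, x$p
  ))
  if (x$estimator == "l1") {
    cat(sprintf("  lambda = %.6g, non-zero betas: %d\n",
                x$lambda, sum(x$betas != 0)))
  }
  cat(sprintf("  intercept = %.4f, deviance ratio = %.4f%s\n",
              x$beta0, x$deviance_ratio,
              if (is.na(x$aic)) "" else sprintf(", AIC = %.1f", x$aic)))
  print(tidy(x), ...)
  invisible(x)
}

#' Wald inference with Bonferroni correction
#'
#' Computes, per coefficient, the Wald statistic `W = beta / se(beta)`, its
#' two-sided p-value under the standard normal reference, the confidence
#' interval, and a significance flag at the Bonferroni-adjusted threshold
#' `alpha / n_tests`.
#'
#' @param fit A `tad_mlr` fitted with `estimator = "irls"` (L1 fits carry
#'   no valid standard errors and are rejected).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Bonferroni divisor; defaults to the number of slope
#'   coefficients in the model.
#' @return A tibble with one row per slope: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`,
#'   `significant`.
#' @export
wald_inference <- function(fit, alpha = 0.05, n_tests = NULL) {
  stopifnot(inherits(fit, "tad_mlr"))
  if (fit$estimator != "irls" || is.null(fit$ses)) {
    abort("Wald inference needs an unpenalized (IRLS) fit with standard errors.")
  }
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  n_tests <- n_tests %||% fit$p
  n_tests <- check_count(n_tests, "n_tests")
  tibble(
    term = names(fit$betas),
    estimate = unname(fit$betas),
    std.error = unname(fit$ses),
    statistic = unname(fit$W),
    p.value = unname(fit$p_values),
    conf.low = unname(fit$ci_low),
    conf.high = unname(fit$ci_high),
    significant = unname(fit$p_values) < alpha / n_tests
  )
}

#' Likelihood-ratio test for one feature
#'
#' Compares the full model over all requested features (M1) with the model
#' dropping `feature` (M2): `D = 2 (logLik(M1) - logLik(M2))`, referenced
#' to a chi-squared distribution with one degree of freedom. Unlike the
#' Wald test, the LRT is robust to the sparseness of binned genomic
#' matrices.
#'
#' @inheritParams fit_mlr
#' @param feature Name of the feature to test.
#' @return A one-row tibble: `feature`, `D`, `df`, `p.value`,
#'   `loglik_full`, `loglik_reduced`.
#' @export
lrt_test <- function(data, feature, features = NULL, ...) {
  features <- features %||% feature_names(data)
  if (!feature %in% features) {
    abort(sprintf("Feature `%s` is not in the model.", feature))
  }
  col <- data[[feature]]
  if (all(col == 0)) {
    # An absent feature cannot change the likelihood: the two models are
    # identical.
    rest <- setdiff(features, feature)
    ll <- fit_mlr(data, features = rest, ...)$loglik
    return(tibble(feature = feature, D = 0, df = 1L, p_value = 1,
                  loglik_full = ll, loglik_reduced = ll))
  }
  full <- tryCatch(fit_mlr(data, features = features, ...),
                   error = function(e) {
                     abort(sprintf("Full model (M1) failed: %s",
                                   conditionMessage(e)))
                   })
  reduced <- tryCatch(
    fit_mlr(data, features = setdiff(features, feature), ...),
    error = function(e) {
      abort(sprintf("Reduced model (M2) failed: %s", conditionMessage(e)))
    })
  D <- max(2 * (full$loglik - reduced$loglik), 0)
  tibble(feature = feature, D = D, df = 1L,
         p_value = pchisq(D, df = 1, lower.tail = FALSE),
         loglik_full = full$loglik, loglik_reduced = reduced$loglik)
}

#' Append statistical interaction terms
#'
#' Adds one column per feature pair holding the elementwise product
#' `X1 * X2` (named `"X1:X2"`), the standard encoding of a two-way
#' statistical interaction in the logistic model. Marginal columns are
#' retained.
#'
#' @param data A `tad_matrix` or data frame with feature columns.
#' @param pairs `"all"` for every unordered feature pair, a character
#'   vector of `"A:B"` strings, or a list of length-2 character vectors.
#' @param features Marginal feature columns (defaults to the matrix's
#'   feature set).
#' @return `data` with the product columns appended and the feature set
#'   updated.
#' @export
expand_interactions <- function(data, pairs, features = NULL) {
  features <- features %||% feature_names(data)
  if (is.character(pairs) && length(pairs) == 1 && pairs == "all") {
    if (length(features) < 2) abort("Need at least 2 features for `\"all\"`.")
    pairs <- combn(features, 2, simplify = FALSE)
  } else if (is.character(pairs)) {
    pairs <- strsplit(pairs, ":", fixed = TRUE)
  }
  if (length(pairs) == 0) return(data)
  if (!all(lengths(pairs) == 2)) {
    abort("Each interaction must name exactly 2 features.")
  }
  nm <- vapply(pairs, paste, character(1), collapse = ":")
  if (anyDuplicated(nm)) abort("Interaction pairs must be unique.")
  missing <- setdiff(unique(unlist(pairs)), names(data))
  if (length(missing) > 0) {
    abort(sprintf("Interaction names unknown feature(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  mode <- matrix_mode(data)
  for (i in seq_along(pairs)) {
    data[[nm[i]]] <- data[[pairs[[i]][1]]] * data[[pairs[[i]][2]]]
  }
  new_tad_matrix(data, features = c(features, nm), mode = mode)
}

#' Goodness-of-fit metrics of a fitted model
#'
#' Reports the deviance ratio and the Akaike information criterion. The
#' primary `deviance_ratio` is the fitted-model deviance divided by the
#' intercept-only (null) deviance — for 0/1 outcomes the literally
#' saturated model has zero deviance, so the null model is the reference
#' against which the fitted deviance is scaled; smaller is better. The
#' complementary `deviance_explained = 1 - deviance_ratio` (the fraction
#' of null deviance explained) is also returned.
#'
#' @param fit A `tad_mlr`.
#' @return A one-row tibble: `deviance`, `null_deviance`,
#'   `deviance_ratio`, `deviance_explained`, `aic`, `loglik`.
#' @export
fit_metrics <- function(fit) {
  stopifnot(inherits(fit, "tad_mlr"))
  tibble(
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    deviance_ratio = fit$deviance_ratio,
    deviance_explained = 1 - fit$deviance_ratio,
    aic = fit$aic,
    loglik = fit$loglik
  )
}
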