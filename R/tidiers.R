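# broom-style tidiers for the fitted objects.

#' Tidy a multiple logistic regression fit
#'
#' @param x A `tad_mlr` from [fit_mlr()].
#' @param intercept Include the intercept row? Default `TRUE`.
#' @param ... Unused.
#' @return One row per coefficient. IRLS fits carry `estimate`,
#'   `std.error`, `statistic` (Wald W), `p.value` and confidence bounds;
#'   L1 fits carry `estimate` and `influential` (non-zero coefficient).
#' @method tidy tad_mlr
#' @export
tidy.tad_mlr <- function(x, intercept = TRUE, ...) {
  terms <- names(x$betas)
  if (x$estimator == "l1") {
    out <- tibble(term = terms, estimate = unname(x$betas),
                  influential = unname(x$betas) != 0)
    if (intercept) {
      out <- dplyr::bind_rows(
        tibble(term = "(Intercept)", estimate = x$beta0, influential = NA),
        out
      )
    }
    return(out)
  }
  out <- tibble(
    term = terms,
    estimate = unname(x$betas),
    std.error = unname(x$ses),
    statistic = unname(x$W),
    p.value = unname(x$p_values),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high)
  )
  if (intercept) {
    z <- qnorm(1 - (1 - x$conf_level) / 2)
    W0 <- x$beta0 / x$se0
    out <- dplyr::bind_rows(
      tibble(term = "(Intercept)", estimate = x$beta0, std.error = x$se0,
             statistic = W0, p.value = 2 * pnorm(-abs(W0)),
             conf.low = x$beta0 - z * x$se0,
             conf.high = x$beta0 + z * x$se0),
      out
    )
  }
  out
}

#' Model-level summary of a fit
#'
#' @param x A `tad_mlr`.
#' @param ... Unused.
#' @return A one-row tibble: sample size, number of features,
#'   log-likelihood, deviance, null deviance, deviance ratio, AIC,
#'   convergence flag, iteration count, estimator and (for L1) the
#'   selected lambda.
#' @method glance tad_mlr
#' @export
glance.tad_mlr <- function(x, ...) {
  tibble(
    n = x$n, p = x$p, loglik = x$loglik, deviance = x$deviance,
    null_deviance = x$null_deviance, deviance_ratio = x$deviance_ratio,
    aic = x$aic, converged = x$converged, n_iter = x$n_iter,
    estimator = x$estimator, lambda = x$lambda
  )
}

#' @method tidy tad_benchmark
#' @export
tidy.tad_benchmark <- function(x, ...) x$records

#' @method glance tad_benchmark
#' @export
glance.tad_benchmark <- function(x, ...) {
  dplyr::mutate(x$summary, n_reps = x$n_reps, n_failed = x$n_failed,
                target_or = x$target_or, alpha = x$alpha)
}
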