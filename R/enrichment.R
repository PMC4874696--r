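# The enrichment test: 2x2 contingency analysis of feature presence inside
# vs outside border bins, and its reformulation as a simple logistic
# regression whose slope is the log odds ratio, tested by Wald's statistic.

#' Build the 2x2 border-by-feature contingency table
#'
#' Cross-tabulates border status against feature presence. For fractional
#' occupancy values, "present" means a value strictly greater than
#' `threshold` (default 0).
#'
#' @param y Binary border indicator.
#' @param x Feature values (binary, fractional occupancy or signal).
#' @param threshold Presence threshold for non-binary `x` (default 0).
#' @return A one-row tibble with counts `a` (border & present), `b`
#'   (border & absent), `c` (outside & present), `d` (outside & absent).
#' @export
contingency_table <- function(y, x, threshold = 0) {
  y <- check_binary(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  present <- x > threshold
  tibble(
    a = sum(y == 1 & present),
    b = sum(y == 1 & !present),
    c = sum(y == 0 & present),
    d = sum(y == 0 & !present)
  )
}

#' Odds ratio of a 2x2 contingency table
#'
#' `OR = (a/b) / (c/d)`: the ratio of the inside-border odds of feature
#' presence to the outside-border odds. `OR > 1` means enrichment at
#' borders, `OR < 1` depletion.
#'
#' @param a,b,c,d Non-negative counts: inside-border presence/absence and
#'   outside-border presence/absence. Alternatively pass a one-row data
#'   frame from [contingency_table()] as `a`.
#' @param correction Apply the Haldane–Anscombe +0.5 continuity correction
#'   to every cell? Default `FALSE`; without it a zero cell yields a
#'   flagged (0, `Inf` or `NaN`) result with a warning.
#' @return The odds ratio as a single number.
#' @examples
#' odds_ratio(500, 5000, 2000, 200000) # 10
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, correction = FALSE) {
  if (is.data.frame(a)) {
    tab <- a
    if (nrow(tab) != 1 || !all(c("a", "b", "c", "d") %in% names(tab))) {
      abort("Contingency table must be one row with columns a, b, c, d.")
    }
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4 || anyNA(counts) || any(counts < 0)) {
    abort("Counts a, b, c, d must be non-negative numbers.")
  }
  if (sum(counts) == 0) abort("Contingency table is empty.")
  if (correction) counts <- counts + 0.5
  if (!correction && any(counts == 0)) {
    warn("Zero cell in contingency table: odds ratio is degenerate (0, Inf or NaN); consider `correction = TRUE`.")
  }
  unname((counts["a"] / counts["b"]) / (counts["c"] / counts["d"]))
}

resolve_yx <- function(data, feature) {
  if (is.data.frame(data)) {
    if (is.null(feature)) abort("Supply the `feature` column to test.")
    if (!feature %in% names(data)) {
      abort(sprintf("Unknown feature column `%s`.", feature))
    }
    list(y = check_binary(data$Y), x = as.numeric(data[[feature]]),
         name = feature)
  } else {
    if (is.null(feature)) abort("Supply the feature vector `x`.")
    list(y = check_binary(data), x = as.numeric(feature), name = "x")
  }
}

#' Enrichment test as a simple logistic regression
#'
#' Fits `logit P(Y = 1 | Xi) = beta0 + beta * Xi` by maximum likelihood.
#' The slope `beta` equals the natural log of the 2x2 odds ratio when `Xi`
#' is binary; it is tested with the Wald statistic `W = beta / se(beta)`
#' against the standard normal. This is the marginal test: other features
#' are ignored, so correlated passengers of a true driver will also appear
#' enriched.
#'
#' @param data A `tad_matrix`/data frame with a binary `Y` column (then
#'   `feature` names the column to test), or the binary border vector
#'   itself (then `feature` is the feature value vector).
#' @param feature Feature column name, or feature vector.
#' @param conf_level Confidence level of the Wald interval (default 0.95).
#' @param ... Passed to the IRLS fitter (`tol`, `max_iter`).
#' @return A one-row tibble: `feature`, `estimate` (beta), `std.error`,
#'   `statistic` (W), `p.value`, `conf.low`, `conf.high`, `odds_ratio`
#'   (`exp(beta)`).
#' @export
enrichment_test <- function(data, feature = NULL, conf_level = 0.95, ...) {
  v <- resolve_yx(data, feature)
  if (length(unique(v$x)) == 1L) {
    abort(sprintf("Feature `%s` is constant; the enrichment test is undefined.",
                  v$name))
  }
  X <- cbind(`(Intercept)` = 1, x = v$x)
  res <- logistic_irls(X, v$y, ...)
  beta <- unname(res$beta[2])
  se <- sqrt(res$vcov[2, 2])
  z <- qnorm(1 - (1 - conf_level) / 2)
  W <- beta / se
  tibble(
    feature = v$name,
    estimate = beta,
    std.error = se,
    statistic = W,
    p.value = 2 * pnorm(-abs(W)),
    conf.low = beta - z * se,
    conf.high = beta + z * se,
    odds_ratio = exp(beta)
  )
}

#' Marginal enrichment scan over all features
#'
#' Runs [enrichment_test()] independently for every feature and flags
#' significance at the Bonferroni-adjusted threshold `alpha / p`, where
#' `p` is the number of features scanned. A feature whose test fails
#' (constant column, separation) is reported with `NA` statistics and the
#' error message in `note`, never fatally.
#'
#' @param data A `tad_matrix` or data frame with binary `Y` and feature
#'   columns.
#' @param features Features to scan (defaults to all).
#' @param alpha Family-wise significance level (default 0.05).
#' @inheritParams enrichment_test
#' @return A `tad_enrichment` tibble, one row per feature, with the
#'   columns of [enrichment_test()] plus `significant` and `note`.
#' @export
enrichment_scan <- function(data, features = NULL, alpha = 0.05,
                            conf_level = 0.95, ...) {
  features <- features %||% feature_names(data)
  if (length(features) == 0) abort("No features to scan.")
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  rows <- purrr::map(features, function(f) {
    tryCatch(
      dplyr::mutate(
        enrichment_test(data, f, conf_level = conf_level, ...),
        note = NA_character_
      ),
      error = function(e) {
        tibble(feature = f, estimate = NA_real_, std.error = NA_real_,
               statistic = NA_real_, p.value = NA_real_,
               conf.low = NA_real_, conf.high = NA_real_,
               odds_ratio = NA_real_, note = conditionMessage(e))
      }
    )
  })
  out <- purrr::list_rbind(rows)
  out$significant <- !is.na(out$p.value) &
    out$p.value < alpha / length(features)
  structure(out,
            alpha = alpha, n_tests = length(features),
            class = c("tad_enrichment", class(out)))
}
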