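# Maximum-likelihood logistic regression by iteratively reweighted least
# squares (IRLS / Fisher scoring). This is the estimation engine behind both
# the enrichment test (single covariate) and the multiple logistic
# regression over all features.

# Numerically stable log(1 + exp(eta)).
log1pexp <- function(eta) {
  out <- numeric(length(eta))
  big <- eta > 30
  out[big] <- eta[big]
  out[!big] <- log1p(exp(eta[!big]))
  out
}

bernoulli_loglik <- function(y, eta) sum(y * eta) - sum(log1pexp(eta))

# Detect exact collinearity before fitting and name the dependent columns.
check_design_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1, ncol(X))]]
    abort(
      sprintf("Design matrix is singular; linearly dependent column(s): %s.",
              paste(dep, collapse = ", ")),
      class = "tadmlr_error_singular"
    )
  }
  invisible(NULL)
}

# X must include the intercept column. Returns coefficients, the inverse
# observed information (equal to the Fisher information for the logit link),
# the maximized log-likelihood and convergence diagnostics. Convergence is
# declared when the largest absolute coefficient change drops below `tol`.
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 100L,
                          se = TRUE) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort("Need more observations than coefficients (n > p).")
  }
  if (all(y == 0) || all(y == 1)) {
    abort("`Y` must contain both classes (0 and 1).")
  }
  check_design_rank(X)

  beta <- numeric(p)
  beta[1] <- qlogis(mean(y))
  eta <- drop(X %*% beta)
  loglik <- bernoulli_loglik(y, eta)
  converged <- FALSE
  iter <- 0L
  w_floor <- 1e-10
  delta <- Inf

  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), w_floor)
    # Weighted least squares step on the working response, written as a
    # normal-equations solve: X'W X beta_new = X'(W eta + (y - mu)).
    A <- crossprod(X * sqrt(w))
    b <- crossprod(X, w * eta + (y - mu))
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      abort("IRLS failed: weighted design became numerically singular.",
            class = "tadmlr_error_singular")
    }
    step <- drop(backsolve(ch, forwardsolve(t(ch), b))) - beta
    # Guarded scoring: halve the step until the log-likelihood does not
    # decrease, so the iteration cannot overshoot and diverge.
    h <- 1
    repeat {
      beta_new <- beta + h * step
      eta_new <- drop(X %*% beta_new)
      loglik_new <- bernoulli_loglik(y, eta_new)
      if (loglik_new >= loglik - 1e-12 || h < 2^-30) break
      h <- h / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- eta_new
    loglik <- loglik_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged || max(abs(beta)) > 1e3) {
    abort(
      paste0("Logistic regression did not converge (possible complete ",
             "separation): max |coefficient change| = ", format(delta),
             " after ", iter, " iterations; max |beta| = ",
             format(max(abs(beta))), "."),
      class = "tadmlr_error_separation",
      beta = setNames(beta, colnames(X)),
      n_iter = iter
    )
  }

  vcov <- NULL
  if (se) {
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), w_floor)
    vcov <- chol2inv(chol(crossprod(X * sqrt(w))))
    dimnames(vcov) <- list(colnames(X), colnames(X))
  }
  list(beta = setNames(beta, colnames(X)), vcov = vcov, loglik = loglik,
       n_iter = iter, converged = converged, eta = eta)
}
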