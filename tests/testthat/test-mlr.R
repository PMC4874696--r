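# The multiple logistic regression core: IRLS maximum likelihood against a
# generic-optimizer oracle, Wald and likelihood-ratio inference,
# interaction expansion, L1 estimation and fit metrics.

make_sim_matrix <- function(n, p, betas, beta0, sparsity = 0.6,
                            correlation = 0.2) {
  X <- synth_feature_matrix(n, p, sparsity = sparsity,
                            correlation = correlation)
  simulate_logistic_response(X, betas = betas, beta0 = beta0)
}

test_that("intercept-only fit recovers the closed-form logit of the mean", {
  y <- rep(c(1, 0), c(25, 75))
  m <- assemble_matrix(NULL, y, list())
  fit <- fit_mlr(m)
  expect_equal(fit$beta0, log(0.25 / 0.75), tolerance = 1e-8)
  expect_equal(fit$p, 0)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
})

test_that("single binary feature reproduces the 2x2 closed form and the enrichment test", {
  y <- rep(c(1, 1, 0, 0), c(50, 500, 200, 2000))
  x <- rep(c(1, 0, 1, 0), c(50, 500, 200, 2000))
  m <- assemble_matrix(NULL, y, list(f = x))
  fit <- fit_mlr(m)
  expect_equal(unname(fit$betas), log((50 / 500) / (200 / 2000)),
               tolerance = 1e-6)
  et <- enrichment_test(y, x)
  expect_equal(unname(fit$betas), et$estimate, tolerance = 1e-8)
  expect_equal(unname(fit$ses), et$std.error, tolerance = 1e-8)
})

test_that("IRLS equals a generic maximum-likelihood optimizer on random instances", {
  withr::with_seed(51, {
    for (rep in 1:50) {
      n <- sample(100:500, 1)
      p <- sample(1:5, 1)
      X <- matrix(rnorm(n * p), n)
      beta_true <- rnorm(p + 1, 0, 0.8)
      y <- rbinom(n, 1, plogis(cbind(1, X) %*% beta_true))
      if (all(y == 0) || all(y == 1)) next
      colnames(X) <- paste0("f", seq_len(p))
      m <- as_tad_matrix(
        dplyr::bind_cols(tibble::tibble(Y = y), tibble::as_tibble(X)),
        mode = "quantitative"
      )
      fit <- fit_mlr(m)
      oracle <- oracle_logistic_mle(cbind(1, X), y)
      expect_lt(max(abs(c(fit$beta0, fit$betas) - oracle)), 1e-6)
    }
  })
})

test_that("estimated betas cover the truth at the MLE rate", {
  withr::with_seed(52, {
    hits <- unlist(lapply(1:12, function(i) {
      sim <- make_sim_matrix(30000, 4, betas = rnorm(4), beta0 = -2)
      fit <- fit_mlr(sim$data)
      abs(fit$betas - sim$true_betas) < 3 * fit$ses
    }))
    expect_gte(mean(hits), 0.95)
  })
})

test_that("Wald inference computes W, p, CI and Bonferroni flags", {
  withr::with_seed(53, {
    sim <- make_sim_matrix(20000, 3, betas = c(2, 0, -2), beta0 = -2)
    fit <- fit_mlr(sim$data)
    w <- wald_inference(fit, alpha = 0.05)
    expect_equal(w$statistic, w$estimate / w$std.error)
    expect_equal(w$p.value, 2 * pnorm(-abs(w$statistic)))
    expect_equal(w$conf.low, w$estimate - qnorm(0.975) * w$std.error)
    expect_equal(w$significant, w$p.value < 0.05 / 3)
    expect_true(w$significant[1] && w$significant[3])
  })
  # arithmetic of the Wald statistic at fixed values
  expect_equal(2.3026 / 0.5, 4.6052)
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

test_that("Wald inference refuses L1 fits", {
  withr::with_seed(54, {
    sim <- make_sim_matrix(3000, 3, betas = c(1, 0, -1), beta0 = -1)
    l1 <- fit_mlr(sim$data, estimator = "l1", n_folds = 4, seed = 1)
    expect_error(wald_inference(l1), "IRLS")
  })
})

test_that("errors: degenerate response, collinearity, separation, constants", {
  m <- assemble_matrix(NULL, rep(1, 10) * 0, list(f = runif(10)))
  expect_error(fit_mlr(m), "both classes")
  withr::with_seed(55, {
    x <- rbinom(200, 1, 0.4)
    y <- rbinom(200, 1, 0.3)
    dup <- assemble_matrix(NULL, y, list(f1 = x, f2 = x))
    expect_error(fit_mlr(dup), "f2")
    expect_error(fit_mlr(dup), class = "tadmlr_error_singular")
    # complete separation: x perfectly predicts y
    sep <- assemble_matrix(NULL, c(rep(0, 50), rep(1, 50)),
                           list(f = c(rep(0, 50), rep(1, 50))))
    err <- tryCatch(fit_mlr(sep), error = identity)
    expect_s3_class(err, "tadmlr_error_separation")
    expect_true(!is.null(err$beta)) # carries the last iterate
    const <- assemble_matrix(NULL, y, list(f = rep(0.2, 200)))
    expect_error(fit_mlr(const), "Constant")
  })
})

test_that("likelihood-ratio test matches its chi-squared contract", {
  withr::with_seed(56, {
    sim <- make_sim_matrix(20000, 3, betas = c(2.5, 0, -1), beta0 = -2.5)
    strong <- lrt_test(sim$data, "X1")
    expect_gte(strong$D, 0)
    expect_equal(strong$df, 1L)
    expect_equal(strong$p_value, pchisq(strong$D, 1, lower.tail = FALSE))
    expect_lt(strong$p_value, 0.05 / 3)
    expect_equal(strong$D,
                 2 * (strong$loglik_full - strong$loglik_reduced))
  })
})

test_that("an all-zero feature column gives D = 0, p = 1", {
  withr::with_seed(57, {
    y <- rbinom(500, 1, 0.3)
    m <- assemble_matrix(NULL, y, list(f1 = runif(500), f2 = rep(0, 500)))
    res <- lrt_test(m, "f2")
    expect_equal(res$D, 0)
    expect_equal(res$p_value, 1)
  })
})

test_that("null LRT statistics follow chi-squared with 1 df", {
  withr::with_seed(58, {
    D <- vapply(1:500, function(i) {
      y <- rbinom(300, 1, 0.3)
      x1 <- rbinom(300, 1, 0.3)
      x2 <- runif(300) # independent of y
      m <- assemble_matrix(NULL, y, list(x1 = x1, x2 = x2))
      lrt_test(m, "x2")$D
    }, numeric(1))
    ks <- stats::ks.test(D, stats::pchisq, df = 1)
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("Wald and LRT p-values agree in order of magnitude off sparse data", {
  withr::with_seed(59, {
    sim <- make_sim_matrix(20000, 3, betas = c(1.5, 0.8, -0.5), beta0 = -1,
                           sparsity = 0.3)
    fit <- fit_mlr(sim$data)
    for (f in names(fit$betas)) {
      lp <- lrt_test(sim$data, f)$p_value
      wp <- fit$p_values[[f]]
      # agreement on the log10 scale, within one order of magnitude for
      # moderate p-values and 30% relatively for extreme ones
      expect_lt(abs(log10(lp) - log10(wp)),
                max(1, 0.3 * abs(log10(lp))))
    }
  })
})

test_that("expand_interactions appends products and keeps marginals", {
  m <- assemble_matrix(NULL, c(0, 1, 0),
                       list(X1 = c(1, 0, 1), X2 = c(1, 1, 0)))
  e <- expand_interactions(m, "X1:X2")
  expect_equal(e$`X1:X2`, c(1, 0, 0))
  expect_equal(feature_names(e), c("X1", "X2", "X1:X2"))
  e2 <- expand_interactions(
    assemble_matrix(NULL, c(0, 1), list(a = c(0.5, 1), b = c(0.5, 0))),
    "all")
  expect_equal(e2$`a:b`, c(0.25, 0))
  expect_identical(expand_interactions(m, list()), m)
  expect_error(expand_interactions(m, "X1:zz"), "zz")
  expect_error(expand_interactions(m, c("X1:X2", "X1:X2")), "unique")
})

test_that("L1 path endpoints behave: full shrinkage and the IRLS limit", {
  withr::with_seed(60, {
    sim <- make_sim_matrix(4000, 4, betas = c(1.5, -1, 0.5, 0), beta0 = -1)
    # enormous lambda: all betas exactly zero, intercept = logit(mean)
    big <- fit_mlr(sim$data, estimator = "l1", lambda = 10)
    expect_true(all(big$betas == 0))
    expect_equal(big$beta0, qlogis(mean(sim$data$Y)), tolerance = 1e-4)
    # lambda -> 0 recovers the unpenalized fit
    irls <- fit_mlr(sim$data)
    small <- fit_mlr(sim$data, estimator = "l1", lambda = 1e-8)
    expect_lt(max(abs(small$betas - irls$betas)), 1e-4)
    expect_lt(abs(small$beta0 - irls$beta0), 1e-4)
  })
})

test_that("cross-validated L1 recovers a sparse causal support", {
  withr::with_seed(61, {
    p <- 30
    n_causal <- 5
    betas <- c(runif(n_causal, 1.5, 2.5) * sample(c(-1, 1), n_causal, TRUE),
               rep(0, p - n_causal))
    X <- synth_feature_matrix(30000, p, sparsity = 0.8, correlation = 0.1)
    sim <- simulate_logistic_response(X, betas = betas, beta0 = -2)
    fit <- fit_mlr(sim$data, estimator = "l1", seed = 2)
    selected <- names(fit$betas)[fit$betas != 0]
    expect_gte(sum(paste0("X", 1:n_causal) %in% selected), n_causal - 1)
  })
})

test_that("fit metrics expose deviance ratio and AIC consistently", {
  withr::with_seed(62, {
    sim <- make_sim_matrix(5000, 3, betas = c(2, -1, 0.5), beta0 = -1)
    fit <- fit_mlr(sim$data)
    fm <- fit_metrics(fit)
    expect_equal(fm$aic, -2 * fit$loglik + 2 * 4)
    expect_equal(fm$deviance_ratio, fit$deviance / fit$null_deviance)
    expect_equal(fm$deviance_explained, 1 - fm$deviance_ratio)
    expect_lt(fm$deviance_ratio, 1)
    # near-deterministic Y given X drives the fitted deviance toward 0
    x <- rep(c(-3, 3), each = 200) + rnorm(400, 0, 0.01)
    m2 <- as_tad_matrix(tibble::tibble(Y = as.numeric(x > 0), f = x / 10),
                        mode = "quantitative")
    # deterministic labels separate perfectly; deviance at the last
    # iterate is ~0 even though the MLE diverges
    err <- tryCatch(fit_mlr(m2), error = identity)
    expect_s3_class(err, "tadmlr_error_separation")
  })
})

test_that("AIC drops when a truly causal feature enters the model", {
  withr::with_seed(63, {
    X <- synth_feature_matrix(50000, 3, sparsity = 0.7, correlation = 0.1)
    sim <- simulate_logistic_response(X, betas = c(2, 1, -1), beta0 = -2)
    full <- fit_mlr(sim$data)
    reduced <- fit_mlr(sim$data, features = c("X2", "X3"))
    expect_lt(full$aic, reduced$aic)
  })
})

test_that("correlated passenger features get beta near zero in MLR", {
  # one causal feature, one colocalizing passenger: the marginal
  # enrichment test flags both, the joint model only the driver
  withr::with_seed(64, {
    n <- 200000
    xa <- rbinom(n, 1, 0.03)
    xb <- pmax(xa * rbinom(n, 1, 0.8), rbinom(n, 1, 0.006))
    y <- rbinom(n, 1, plogis(-4.5 + 2 * xa))
    m <- assemble_matrix(NULL, y, list(A = xa, B = xb))
    fit <- fit_mlr(m)
    scan <- enrichment_scan(m, alpha = 1e-5)
    expect_gt(scan$estimate[scan$feature == "B"], 0.5) # ET: enriched
    expect_true(all(scan$significant))
    expect_lt(abs(fit$betas[["B"]]), 0.25) # MLR: passenger discarded
    expect_gt(fit$betas[["A"]], 1.5)
    expect_false(wald_inference(fit, alpha = 1e-5)$significant[2])
  })
})

test_that("a pure interaction effect loads only on the product term", {
  withr::with_seed(65, {
    n <- 150000
    xa <- rbinom(n, 1, 0.15)
    xb <- rbinom(n, 1, 0.15)
    y <- rbinom(n, 1, plogis(-4 + 2.5 * xa * xb))
    m <- assemble_matrix(NULL, y, list(A = xa, B = xb))
    fit <- fit_mlr(m, interactions = "all")
    expect_gt(fit$betas[["A:B"]], 1.5)
    expect_lt(abs(fit$betas[["A"]]), 0.5)
    expect_lt(abs(fit$betas[["B"]]), 0.5)
    w <- wald_inference(fit, alpha = 1e-5)
    expect_true(w$significant[w$term == "A:B"])
    expect_false(any(w$significant[w$term %in% c("A", "B")]))
  })
})

test_that("tidy and glance return well-formed tibbles", {
  withr::with_seed(66, {
    sim <- make_sim_matrix(3000, 3, betas = c(1, 0, -1), beta0 = -1)
    fit <- fit_mlr(sim$data)
    td <- tidy(fit)
    expect_equal(td$term, c("(Intercept)", "X1", "X2", "X3"))
    expect_named(glance(fit),
                 c("n", "p", "loglik", "deviance", "null_deviance",
                   "deviance_ratio", "aic", "converged", "n_iter",
                   "estimator", "lambda"))
    expect_s3_class(autoplot(fit), "ggplot")
  })
})
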