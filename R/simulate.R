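# Simulation generators. Two response protocols are provided, mirroring the
# two study designs: (i) a logistic generator (slopes ~ N(0,1), intercept
# ~ N(-4.5,1), Bernoulli responses through the inverse logit) used for
# parameter-recovery studies, and (ii) a deliberately non-linear,
# non-additive threshold generator (border probability p1 when any causal
# feature >= 0.5, else p0) used for method comparison. A fully synthetic
# sparse correlated feature-matrix generator stands in for bootstrap
# resampling of a real binned matrix, so no external data are required.

#' Bootstrap rows of a feature matrix
#'
#' Draws `n` rows uniformly with replacement (nonparametric bootstrap),
#' preserving the between-feature correlation structure of the source
#' matrix in expectation.
#'
#' @param data A `tad_matrix` or data frame.
#' @param n Number of rows to draw.
#' @param seed Optional RNG seed.
#' @return A tibble of `n` resampled rows, retaining the `tad_matrix`
#'   feature set and mode of the input.
#' @export
bootstrap_rows <- function(data, n, seed = NULL) {
  n <- check_count(n, "n")
  if (nrow(data) == 0) abort("`data` has no rows to resample.")
  idx <- with_seed(seed, sample.int(nrow(data), n, replace = TRUE))
  out <- as_tibble(data)[idx, , drop = FALSE]
  if (inherits(data, "tad_matrix")) {
    out <- new_tad_matrix(out, features = feature_names(data),
                          mode = matrix_mode(data))
  }
  out
}

# Map a latent equicorrelated-Gaussian correlation to the correlation
# realized after sparsifying (Monte Carlo, internal fixed seed so the
# calibration is deterministic). Cached per (sparsity, target).
calibrate_latent_rho <- function(sparsity, target, n_cal = 2e5) {
  if (target == 0) return(0)
  key <- paste(format(sparsity, digits = 12), format(target, digits = 12))
  cached <- .tadmlr_cache[[key]]
  if (!is.null(cached)) return(cached)
  observed <- function(rho) {
    withr::with_seed(20160520L, {
      zc <- rnorm(n_cal)
      z1 <- sqrt(rho) * zc + sqrt(1 - rho) * rnorm(n_cal)
      z2 <- sqrt(rho) * zc + sqrt(1 - rho) * rnorm(n_cal)
      cor(sparsify_gaussian(z1, sparsity), sparsify_gaussian(z2, sparsity))
    })
  }
  upper <- 0.999
  if (observed(upper) < target) {
    abort(sprintf(
      "Infeasible sparsity/correlation combination: cannot reach mean pairwise correlation %.3g at sparsity %.3g.",
      target, sparsity
    ))
  }
  rho <- uniroot(function(r) observed(r) - target, c(0, upper),
                 tol = 1e-4)$root
  .tadmlr_cache[[key]] <- rho
  rho
}

.tadmlr_cache <- new.env(parent = emptyenv())

# Threshold a standard normal draw into a sparse occupancy fraction: zero
# below the sparsity quantile, and the tail mass mapped uniformly onto
# (0, 1].
sparsify_gaussian <- function(z, sparsity) {
  ifelse(z < qnorm(sparsity), 0, (pnorm(z) - sparsity) / (1 - sparsity))
}

#' Generate a synthetic sparse correlated feature matrix
#'
#' Emulates a binned ChIP-seq occupancy matrix: features are mostly zero
#' (rare binding) and weakly positively correlated across features
#' (colocalization). Columns are built from equicorrelated latent
#' Gaussians; in `"coordinate"` mode each latent value below the sparsity
#' quantile becomes 0 and the upper tail is mapped uniformly onto
#' `(0, 1]` (fractional bin occupancy), with the latent correlation
#' calibrated so the *observed* mean pairwise correlation matches the
#' target. In `"quantitative"` mode the correlated Gaussians are returned
#' directly (signal-intensity scale, mean 0, sd 1) and `sparsity` is
#' ignored.
#'
#' Defaults mirror the sparse, weakly correlated regime of real binned
#' matrices: 97% zeros and mean pairwise correlation 0.25.
#'
#' @param n Number of rows (bins).
#' @param p Number of features.
#' @param sparsity Target fraction of zeros per coordinate-mode feature,
#'   in `[0, 1)` (default 0.97).
#' @param correlation Target mean pairwise correlation of the realized
#'   feature values, in `[0, 1)` (default 0.25).
#' @param mode `"coordinate"` (default) or `"quantitative"`.
#' @param names Feature names (default `X1..Xp`).
#' @param seed Optional RNG seed.
#' @return A `tad_matrix`-tagged tibble of features (no `Y` column yet;
#'   combine with [simulate_logistic_response()] or
#'   [simulate_threshold_response()]).
#' @export
synth_feature_matrix <- function(n, p, sparsity = 0.97, correlation = 0.25,
                                 mode = c("coordinate", "quantitative"),
                                 names = paste0("X", seq_len(p)),
                                 seed = NULL) {
  n <- check_count(n, "n")
  p <- check_count(p, "p")
  mode <- match.arg(mode)
  check_number(sparsity, "sparsity", lower = 0)
  check_number(correlation, "correlation", lower = 0)
  if (sparsity >= 1) abort("`sparsity` must be in [0, 1).")
  if (correlation >= 1) abort("`correlation` must be in [0, 1).")
  if (length(names) != p || anyDuplicated(names)) {
    abort("`names` must be `p` unique feature names.")
  }
  rho <- if (mode == "coordinate") {
    calibrate_latent_rho(sparsity, correlation)
  } else {
    correlation
  }
  X <- with_seed(seed, {
    zc <- rnorm(n)
    vapply(seq_len(p), function(j) {
      z <- sqrt(rho) * zc + sqrt(1 - rho) * rnorm(n)
      if (mode == "coordinate") sparsify_gaussian(z, sparsity) else z
    }, numeric(n))
  })
  colnames(X) <- names
  structure(as_tibble(as.data.frame(X, check.names = FALSE)),
            features = names, mode = mode,
            class = c("tad_matrix", class(tibble())))
}

#' Plant a rare feature: a fixed number of occupied intervals
#'
#' Builds a coordinate-mode feature column that is zero everywhere except
#' `n_peaks` non-overlapping runs of `peak_bins` consecutive rows set
#' to 1, emulating a protein bound at only a handful of sites genome-wide
#' (each "peak" spans several adjacent bins).
#'
#' @param n Number of rows (bins).
#' @param n_peaks Number of occupied intervals (default 50).
#' @param peak_bins Bins spanned by each interval (default 20, i.e. a
#'   1 kb peak over 50 bp bins).
#' @param seed Optional RNG seed.
#' @return Numeric 0/1 vector of length `n`.
#' @export
rare_feature_column <- function(n, n_peaks = 50, peak_bins = 20,
                                seed = NULL) {
  n <- check_count(n, "n")
  n_peaks <- check_count(n_peaks, "n_peaks")
  peak_bins <- check_count(peak_bins, "peak_bins")
  if (n_peaks * peak_bins * 2 > n) {
    abort("Too many peaks for the number of rows.")
  }
  with_seed(seed, {
    x <- numeric(n)
    starts <- numeric(0)
    while (length(starts) < n_peaks) {
      cand <- sample.int(n - peak_bins + 1, n_peaks)
      keep <- vapply(cand, function(s) {
        all(abs(s - starts) >= peak_bins)
      }, logical(1))
      for (s in cand[keep]) {
        if (length(starts) < n_peaks &&
            all(abs(s - starts) >= peak_bins)) {
          starts <- c(starts, s)
        }
      }
    }
    for (s in starts) x[seq.int(s, s + peak_bins - 1)] <- 1
    x
  })
}

#' Simulate Bernoulli border labels from a logistic model
#'
#' Draws slopes `beta ~ N(beta_mean, beta_sd)` per feature and an
#' intercept `beta0 ~ N(intercept_mean, intercept_sd)` (defaults N(0,1)
#' and N(-4.5,1); the low intercept keeps borders rare, matching real
#' data), computes the linear predictor `Z = beta0 + X beta`, the
#' probability `1 / (1 + exp(-Z))`, and one Bernoulli draw per row.
#'
#' @param X Feature matrix (from [synth_feature_matrix()],
#'   [bootstrap_rows()], or any data frame of numeric features).
#' @param betas,beta0 Optional fixed true parameters; when supplied they
#'   are used instead of random draws.
#' @param beta_mean,beta_sd Mean and sd of the slope draws.
#' @param intercept_mean,intercept_sd Mean and sd of the intercept draw.
#' @param seed Optional RNG seed.
#' @return A `tad_sim` list: `data` (a `tad_matrix` with the simulated
#'   `Y`), the truth (`true_beta0`, `true_betas`), the intermediates
#'   `Z` and `prob`, and the `seed` used.
#' @export
simulate_logistic_response <- function(X, betas = NULL, beta0 = NULL,
                                       beta_mean = 0, beta_sd = 1,
                                       intercept_mean = -4.5,
                                       intercept_sd = 1, seed = NULL) {
  feats <- feature_names(X)
  Xm <- as.matrix(as.data.frame(X, check.names = FALSE)[feats])
  with_seed(seed, {
    betas <- betas %||% rnorm(ncol(Xm), beta_mean, beta_sd)
    beta0 <- beta0 %||% rnorm(1, intercept_mean, intercept_sd)
    if (length(betas) != ncol(Xm)) {
      abort("`betas` must have one value per feature.")
    }
    Z <- unname(drop(Xm %*% betas)) + beta0
    prob <- plogis(Z)
    Y <- rbinom(length(Z), 1L, prob)
    structure(list(
      data = new_tad_matrix(
        dplyr::bind_cols(tibble(Y = Y), as_tibble(as.data.frame(X))[feats]),
        features = feats, mode = matrix_mode(X)
      ),
      true_beta0 = beta0,
      true_betas = setNames(as.numeric(betas), feats),
      Z = Z, prob = prob,
      model = "logistic", seed = seed
    ), class = "tad_sim")
  })
}

#' Simulate border labels from the threshold (non-additive) model
#'
#' The generative model is deliberately non-linear and non-additive so
#' that no fitted model family is favored: a row gets a border with
#' probability `p1` when at least one causal feature value is >= 0.5,
#' and with probability `p0 < p1` otherwise.
#'
#' @param X Feature matrix.
#' @param causal Causal feature names or column indices.
#' @param p0,p1 Border probabilities away from / at causal-feature sites
#'   (`0 <= p0 < p1 <= 1`); see [solve_p0_p1()] to derive them from a
#'   target odds ratio and border rate.
#' @param seed Optional RNG seed.
#' @return A `tad_sim` list with `data` (matrix plus simulated `Y`),
#'   `causal` (feature names), `exposed` (the any-causal >= 0.5 indicator),
#'   `p0`, `p1`.
#' @export
simulate_threshold_response <- function(X, causal, p0, p1, seed = NULL) {
  feats <- feature_names(X)
  if (is.numeric(causal)) causal <- feats[causal]
  if (length(causal) == 0 || !all(causal %in% feats)) {
    abort("`causal` must name features present in `X`.")
  }
  check_number(p0, "p0", lower = 0, upper = 1)
  check_number(p1, "p1", lower = 0, upper = 1)
  if (p0 >= p1) abort("Require p0 < p1.")
  Xc <- as.matrix(as.data.frame(X, check.names = FALSE)[causal])
  exposed <- rowSums(Xc >= 0.5) > 0
  with_seed(seed, {
    Y <- rbinom(length(exposed), 1L, ifelse(exposed, p1, p0))
    structure(list(
      data = new_tad_matrix(
        dplyr::bind_cols(tibble(Y = Y), as_tibble(as.data.frame(X))[feats]),
        features = feats, mode = matrix_mode(X)
      ),
      causal = causal, exposed = exposed, p0 = p0, p1 = p1,
      model = "threshold", seed = seed
    ), class = "tad_sim")
  })
}

#' Solve the threshold-model probabilities for a target odds ratio
#'
#' Finds `(p0, p1)` such that the exposure odds ratio
#' `p1 (1 - p0) / (p0 (1 - p1))` equals `target_or` and the marginal
#' border rate `exposure_rate * p1 + (1 - exposure_rate) * p0` equals
#' `border_rate`. The odds-ratio constraint is satisfied analytically and
#' the marginal constraint by 1-D root finding; both hold to within
#' 1e-10.
#'
#' @param target_or Target odds ratio (>= 1).
#' @param border_rate Marginal `P(Y = 1)`, in (0, 1).
#' @param exposure_rate `P(any causal feature >= 0.5)`, in (0, 1).
#' @return Named list with `p0` and `p1`.
#' @examples
#' solve_p0_p1(4, border_rate = 0.01, exposure_rate = 0.03)
#' @export
solve_p0_p1 <- function(target_or, border_rate, exposure_rate) {
  check_number(target_or, "target_or", lower = 1)
  check_number(border_rate, "border_rate")
  check_number(exposure_rate, "exposure_rate")
  if (border_rate <= 0 || border_rate >= 1) {
    abort("`border_rate` must be in (0, 1).")
  }
  if (exposure_rate <= 0 || exposure_rate >= 1) {
    abort("`exposure_rate` must be in (0, 1).")
  }
  if (target_or == 1) {
    return(list(p0 = border_rate, p1 = border_rate))
  }
  # p1 as a function of p0 under the odds-ratio constraint.
  p1_of <- function(p0) target_or * p0 / (1 + (target_or - 1) * p0)
  f <- function(p0) {
    exposure_rate * p1_of(p0) + (1 - exposure_rate) * p0 - border_rate
  }
  eps <- 1e-14
  if (f(eps) > 0 || f(1 - eps) < 0) {
    abort("No (p0, p1) in (0,1)^2 satisfies the constraints.")
  }
  p0 <- uniroot(f, c(eps, 1 - eps), tol = 1e-14)$root
  # Newton polish on the marginal constraint.
  for (i in 1:5) {
    slope <- exposure_rate * target_or /
      (1 + (target_or - 1) * p0)^2 + (1 - exposure_rate)
    p0 <- p0 - f(p0) / slope
  }
  p1 <- p1_of(p0)
  if (abs(f(p0)) > 1e-10 || p0 <= 0 || p1 >= 1) {
    abort("No (p0, p1) in (0,1)^2 satisfies the constraints.")
  }
  list(p0 = p0, p1 = p1)
}

#' Perturb TAD junction positions with Gaussian noise
#'
#' Shifts every internal TAD edge by an independent draw from
#' `N(0, sd)` rounded to integer bp, emulating border-call inaccuracy.
#' Shifts are clipped to less than half the distance to the neighboring
#' edges so the TAD ordering is always preserved; chromosome-terminal
#' edges are left in place. A junction shared by two abutting TADs moves
#' as one point.
#'
#' @param tads Interval tibble of TADs (non-overlapping per chromosome).
#' @param sd Noise standard deviation in bp (>= 0). `sd = 0` returns the
#'   input unchanged.
#' @param seed Optional RNG seed.
#' @return A tibble of perturbed TADs, sorted by (chrom, start).
#' @export
add_border_noise <- function(tads, sd, seed = NULL) {
  check_number(sd, "sd", lower = 0)
  tads <- sort_check_disjoint(tads, "tads")
  if (sd == 0) return(tads)
  with_seed(seed, {
    tads |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(function(df, key) {
        # Edge positions in order; junctions (end == next start) are one
        # point and move together.
        edges <- sort(unique(c(df$start, df$end)))
        m <- length(edges)
        new_edges <- edges
        if (m > 2) {
          inner <- 2:(m - 1)
          shift <- round(rnorm(length(inner), 0, sd))
          lo <- ceiling((edges[inner - 1] - edges[inner]) / 2) + 1
          hi <- floor((edges[inner + 1] - edges[inner]) / 2) - 1
          shift <- ifelse(lo > hi, 0, pmin(pmax(shift, lo), hi))
          new_edges[inner] <- edges[inner] + shift
        }
        tibble(
          start = new_edges[match(df$start, edges)],
          end = new_edges[match(df$end, edges)],
          df[setdiff(names(df), c("start", "end"))]
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(names(tads)))
  })
}
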