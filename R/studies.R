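# Replicated simulation studies: parameter-recovery protocols (marginal,
# interaction, rare-feature variants) and the border-noise robustness
# study. These wrap the generators and the fitter into the standard
# experimental designs so the same protocol runs in the tests, the
# acceptance script and user analyses.

#' Parameter-recovery study
#'
#' Repeatedly generates a synthetic feature matrix, draws true parameters
#' (slopes ~ N(0,1), intercept ~ N(-4.5,1)), simulates Bernoulli border
#' labels through the logistic model, refits by IRLS maximum likelihood,
#' and pools true and estimated slopes across replicates. The pooled
#' squared correlation (in percent) measures how well the model recovers
#' its own parameters under realistic sparsity and correlation.
#'
#' @param n_reps Number of replicates (default 20).
#' @param n_rows Rows (bins) per replicate (default 1e6, the order of a
#'   50 bp binned fly-scale genome, which keeps sparse features
#'   informative enough for stable slope estimates).
#' @param p Number of features (default 6).
#' @param mode `"coordinate"` or `"quantitative"` feature encoding.
#' @param sparsity,correlation Passed to [synth_feature_matrix()].
#' @param interactions If `TRUE`, all two-way product columns are appended
#'   before drawing the truth, and the pooled R2 is restricted to the
#'   interaction-term parameters.
#' @param rare_feature Optional list with `n_peaks` and `peak_bins`: the
#'   last feature is replaced by a [rare_feature_column()] with that peak
#'   structure (a protein occupying only a handful of sites).
#' @param seed Optional RNG seed for the whole study.
#' @return A list: `true` and `est` (pooled parameter vectors), `r2`
#'   (percent), `n_failed` (replicates whose fit did not converge).
#' @export
recovery_study <- function(n_reps = 20, n_rows = 1e6, p = 6,
                           mode = c("coordinate", "quantitative"),
                           sparsity = 0.97, correlation = 0.25,
                           interactions = FALSE, rare_feature = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  n_reps <- check_count(n_reps, "n_reps")
  if (mode == "coordinate") calibrate_latent_rho(sparsity, correlation)
  reps <- with_seed(seed, purrr::map(seq_len(n_reps), function(rep) {
    X <- synth_feature_matrix(n_rows, p, sparsity = sparsity,
                              correlation = correlation, mode = mode)
    if (!is.null(rare_feature)) {
      X[[p]] <- rare_feature_column(n_rows,
                                    n_peaks = rare_feature$n_peaks,
                                    peak_bins = rare_feature$peak_bins)
    }
    if (interactions) X <- expand_interactions(X, "all")
    sim <- simulate_logistic_response(X)
    fit <- tryCatch(fit_mlr(sim$data), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    keep <- if (interactions) {
      grepl(":", names(sim$true_betas), fixed = TRUE)
    } else {
      rep(TRUE, length(sim$true_betas))
    }
    # identifiability filter: a coefficient whose standard error exceeds
    # the spread of the true-effect distribution (sd = 1) is carrying no
    # information about its parameter — typically quasi-separation on a
    # nearly empty column — so the replicate cannot be scored and counts
    # as failed
    if (max(fit$ses[keep]) > 1) return(NULL)
    list(true = unname(sim$true_betas[keep]),
         est = unname(fit$betas[keep]))
  }))
  failed <- sum(vapply(reps, is.null, logical(1)))
  reps <- purrr::compact(reps)
  if (length(reps) == 0) abort("All replicates failed to fit.")
  true <- unlist(purrr::map(reps, "true"))
  est <- unlist(purrr::map(reps, "est"))
  list(true = true, est = est, r2 = recovery_r2(true, est),
       n_failed = failed)
}

# TADs with exponential size spacing on one chromosome.
sim_tad_layout <- function(chrom, chrom_len, tad_mean) {
  sizes <- pmax(round(stats::rexp(ceiling(2 * chrom_len / tad_mean),
                                  1 / tad_mean)), 10000)
  edges <- c(0, cumsum(sizes))
  edges <- edges[edges < chrom_len]
  tibble(chrom = chrom, start = edges,
         end = c(edges[-1], chrom_len))
}

# Features as genomic peaks spanning the effect spectrum, mirroring the
# N(0,1) slope draws of the recovery protocol: border-attracted features
# carry a peak at each junction with probability q > 0 (jittered around
# the junction), neutral features have background peaks only, and
# border-avoiding features have their background peaks pushed away from
# the junctions, so the fitted slopes range from clearly negative through
# zero to clearly positive.
sim_border_features <- function(junctions, chrom, chrom_len, p,
                                n_background = 400) {
  q <- seq(-0.5, 0.9, length.out = p)
  purrr::map(seq_len(p), function(j) {
    at <- if (q[j] > 0) {
      junctions[runif(length(junctions)) < q[j]]
    } else {
      numeric(0)
    }
    bg <- round(runif(n_background, 0, chrom_len))
    if (q[j] < 0) {
      # avoidance: resample background peaks that fall near a junction
      # with probability |q|
      near <- vapply(bg, function(x) min(abs(x - junctions)) < 3000,
                     logical(1))
      bg <- bg[!(near & runif(length(bg)) < -q[j])]
    }
    centers <- c(at + round(runif(length(at), -300, 300)), bg)
    width <- pmax(round(stats::rnorm(length(centers), 400, 80)), 50)
    start <- pmax(centers - width %/% 2, 0)
    tibble(chrom = chrom, start = start,
           end = pmin(start + width, chrom_len)) |>
      dplyr::filter(.data$start < .data$end)
  }) |>
    setNames(paste0("X", seq_len(p)))
}

#' Border-noise robustness study
#'
#' Simulates a binned genome with planted TAD borders and peak features
#' enriched at the junctions, estimates the model slopes from the true
#' borders, then perturbs every junction with Gaussian positional noise,
#' relabels the border bins and refits. The squared correlation between
#' the two slope vectors quantifies how robust the estimates are to
#' border-call inaccuracy.
#'
#' @param sd Junction noise standard deviation in bp (e.g. 2000 for 2 kb).
#' @param n_reps Number of replicate genomes (default 5).
#' @param chrom_len Simulated chromosome length in bp (default 1e7).
#' @param bin_size Bin size in bp (default 50).
#' @param window Border window in bp (default 1000).
#' @param tad_mean Mean TAD size in bp (default 70000).
#' @param p Number of features (default 6).
#' @param seed Optional RNG seed.
#' @return A list: `beta_clean`, `beta_noisy` (pooled slope vectors),
#'   `r2` (percent squared correlation between them), and `n_failed`
#'   (replicates dropped because a fit did not converge).
#' @export
border_noise_study <- function(sd, n_reps = 5, chrom_len = 1e7,
                               bin_size = 50, window = 1000,
                               tad_mean = 7e4, p = 6, seed = NULL) {
  check_number(sd, "sd", lower = 0)
  n_reps <- check_count(n_reps, "n_reps")
  layout <- genome_layout(setNames(chrom_len, "sim"))
  bins <- make_bins(layout, bin_size)
  reps <- with_seed(seed, purrr::map(seq_len(n_reps), function(rep) {
    tads <- sim_tad_layout("sim", chrom_len, tad_mean)
    junctions <- border_points(tads)$pos
    features <- sim_border_features(junctions, "sim", chrom_len, p)
    enc <- purrr::map(features, function(iv) {
      encode_coordinate_feature(bins, iv, unknown_chrom = "drop")
    })
    fit_for <- function(tad_set) {
      Y <- label_borders(bins, tad_set, window)
      fit_mlr(assemble_matrix(bins, Y, enc))
    }
    # a replicate whose clean or noisy fit fails (e.g. quasi-separation
    # when an avoiding feature misses every border bin) is dropped
    tryCatch({
      clean <- fit_for(tads)
      noisy <- fit_for(add_border_noise(tads, sd))
      list(clean = unname(clean$betas), noisy = unname(noisy$betas))
    }, error = function(e) NULL)
  }))
  failed <- sum(vapply(reps, is.null, logical(1)))
  reps <- purrr::compact(reps)
  if (length(reps) == 0) abort("All replicates failed to fit.")
  beta_clean <- unlist(purrr::map(reps, "clean"))
  beta_noisy <- unlist(purrr::map(reps, "noisy"))
  list(beta_clean = beta_clean, beta_noisy = beta_noisy,
       r2 = recovery_r2(beta_clean, beta_noisy), n_failed = failed)
}
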