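# Genome tiling, border labeling and per-bin feature encoding, verified
# against brute-force per-base oracles on small random genomes.

test_that("make_bins tiles chromosomes without gaps or overlaps", {
  bins <- make_bins(genome_layout(c(a = 250)), 100)
  expect_equal(bins$start, c(0, 100, 200))
  expect_equal(bins$end, c(100, 200, 250))
  bins2 <- make_bins(genome_layout(c(a = 1000, b = 130)), 50)
  expect_equal(nrow(bins2), 20 + 3)
  expect_equal(sum(bins2$end - bins2$start), 1130)
  # per chromosome: starts abut previous ends
  for (ch in c("a", "b")) {
    b <- bins2[bins2$chrom == ch, ]
    expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  expect_error(make_bins(genome_layout(c(a = 100)), 0), "> 0")
})

test_that("label_borders marks windowed junction bins", {
  bins <- make_bins(genome_layout(c(a = 250000)), 50)
  tads <- tibble::tibble(chrom = "a",
                         start = c(0, 100000), end = c(100000, 200000))
  y <- label_borders(bins, tads, window = 1000)
  expect_equal(sum(y), 20)
  marked <- bins[y == 1, ]
  expect_equal(min(marked$start), 99500)
  expect_equal(max(marked$end), 100500)
  # single TAD on a chromosome: no internal junction, all zero
  y1 <- label_borders(bins, tads[1, ], window = 1000)
  expect_equal(sum(y1), 0)
  # terminal edges count only when requested
  y2 <- label_borders(bins, tads[1, ], window = 1000,
                      include_chrom_ends = TRUE)
  expect_gt(sum(y2), 0)
  expect_error(label_borders(bins, tibble::tibble(
    chrom = "a", start = c(0, 500), end = c(1000, 1500)
  ), 1000), "overlap")
})

test_that("border labeling matches the per-base oracle and is record-order invariant", {
  layout <- genome_layout(c(a = 6000, b = 4000))
  bins <- make_bins(layout, 50)
  withr::with_seed(7, {
    for (rep in 1:5) {
      tads <- dplyr::bind_rows(random_tads("a", 6000, 1200),
                               random_tads("b", 4000, 900))
      window <- sample(c(100, 300, 500), 1)
      y <- label_borders(bins, tads, window)
      pts <- border_points(tads)
      expect_equal(y, oracle_border_labels(bins, pts, window))
      shuffled <- tads[sample(nrow(tads)), ]
      expect_equal(label_borders(bins, shuffled, window), y)
    }
  })
})

test_that("close border points union their windows without double counting", {
  bins <- make_bins(genome_layout(c(a = 10000)), 50)
  # junctions at 4000 and 4400, window 1000 -> overlapping windows
  tads <- tibble::tibble(chrom = "a", start = c(0, 4000, 4400),
                         end = c(4000, 4400, 10000))
  y <- label_borders(bins, tads, 1000)
  pts <- border_points(tads)
  expect_equal(y, oracle_border_labels(bins, pts, 1000))
  # union [3500,4900) = 1400 bp -> 28 bins of 50 bp
  expect_equal(sum(y), 28)
})

test_that("gap between TADs yields border points at both gap edges", {
  tads <- tibble::tibble(chrom = "a", start = c(0, 5000),
                         end = c(4000, 9000))
  pts <- border_points(tads)
  expect_equal(pts$pos, c(4000, 5000))
})

test_that("coordinate encoding equals per-base union coverage", {
  bins <- make_bins(genome_layout(c(a = 100)), 100)
  expect_equal(encode_coordinate_feature(
    bins, tibble::tibble(chrom = "a", start = 10, end = 60)), 0.5)
  # overlapping peaks are unioned, not summed
  expect_equal(encode_coordinate_feature(
    bins, tibble::tibble(chrom = "a", start = c(0, 40), end = c(60, 100))),
    1.0)
  layout <- genome_layout(c(a = 700, b = 430))
  bins2 <- make_bins(layout, 50)
  withr::with_seed(21, {
    for (rep in 1:5) {
      iv <- random_intervals(layout, 25)
      expect_equal(encode_coordinate_feature(bins2, iv),
                   oracle_bin_coverage(bins2, iv))
    }
  })
})

test_that("unknown chromosomes are skipped with a warning by default", {
  bins <- make_bins(genome_layout(c(a = 100)), 50)
  iv <- tibble::tibble(chrom = c("a", "zz"), start = c(0, 0),
                       end = c(50, 50))
  expect_warning(v <- encode_coordinate_feature(bins, iv), "zz")
  expect_equal(v, c(1, 0))
  expect_error(encode_coordinate_feature(bins, iv, unknown_chrom = "error"),
               "zz")
})

test_that("quantitative encoding is the 0-filled per-base mean", {
  bins <- make_bins(genome_layout(c(a = 100)), 100)
  expect_equal(encode_quantitative_feature(
    bins, tibble::tibble(chrom = "a", start = 0, end = 100, value = 2)), 2)
  expect_equal(encode_quantitative_feature(
    bins, tibble::tibble(chrom = "a", start = 0, end = 50, value = 2)), 1)
  expect_equal(encode_quantitative_feature(
    bins, tibble::tibble(chrom = "zz", start = 0, end = 50, value = 2)), 0)
  layout <- genome_layout(c(a = 500))
  bins2 <- make_bins(layout, 50)
  withr::with_seed(22, {
    starts <- seq(0, 450, by = 50) + sample(0:20, 10, replace = TRUE)
    track <- tibble::tibble(chrom = "a", start = starts,
                            end = pmin(starts + sample(5:25, 10, TRUE), 500),
                            value = round(rnorm(10), 2))
    expect_equal(encode_quantitative_feature(bins2, track),
                 oracle_bin_signal(bins2, track))
  })
})

test_that("assemble_matrix validates shapes, names and value ranges", {
  bins <- make_bins(genome_layout(c(a = 500)), 50)
  y <- rep(c(0, 1), 5)
  m <- assemble_matrix(bins, y, list(f1 = runif(10), f2 = runif(10)))
  expect_s3_class(m, "tad_matrix")
  expect_equal(feature_names(m), c("f1", "f2"))
  expect_equal(nrow(m), 10)
  # intercept-only matrix is allowed
  m0 <- assemble_matrix(bins, y, list())
  expect_equal(feature_names(m0), character(0))
  expect_error(assemble_matrix(bins, y, list(f = runif(3))), "length")
  expect_error(
    assemble_matrix(bins, y, stats::setNames(list(runif(10), runif(10)),
                                             c("f", "f"))),
    "unique")
  expect_error(assemble_matrix(bins, y, list(f = runif(10) + 1)), "\\[0, 1\\]")
})

test_that("feature matrix TSV round trip preserves values and mode", {
  m <- synth_feature_matrix(50, 3, sparsity = 0.5, correlation = 0,
                            seed = 1)
  sim <- simulate_logistic_response(m, seed = 2, intercept_mean = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(sim$data, path)
  back <- read_feature_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$data),
               tolerance = 1e-12)
  expect_equal(feature_names(back), feature_names(sim$data))
})

test_that("realized sparsity matches the analytic expectation", {
  # Poisson-placed peaks at density lambda per bp, mean width w: a bin of
  # size b is zero iff no peak starts in the preceding (w + b - 1) bases.
  layout <- genome_layout(c(a = 2e5))
  bins <- make_bins(layout, 50)
  withr::with_seed(33, {
    w <- 40
    lambda <- 2e-4
    starts <- which(runif(2e5) < lambda) - 1
    iv <- tibble::tibble(chrom = "a", start = starts,
                         end = pmin(starts + w, 2e5))
    v <- encode_coordinate_feature(bins, iv)
    expected_zero <- (1 - lambda)^(w + 50 - 1)
    expect_lt(abs(mean(v == 0) - expected_zero), 0.02)
  })
})
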