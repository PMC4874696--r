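# Independent brute-force oracles used to verify the vectorized
# implementations on small inputs, plus small fixture builders.

# Per-base union coverage of intervals over each bin.
oracle_bin_coverage <- function(bins, intervals) {
  vapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    bases <- seq(b$start, b$end - 1)
    covered <- vapply(bases, function(pos) {
      any(intervals$chrom == b$chrom &
            intervals$start <= pos & pos < intervals$end)
    }, logical(1))
    mean(covered)
  }, numeric(1))
}

# Per-base mean of a non-overlapping signal track over each bin (0 fill).
oracle_bin_signal <- function(bins, track) {
  vapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    bases <- seq(b$start, b$end - 1)
    vals <- vapply(bases, function(pos) {
      hit <- which(track$chrom == b$chrom &
                     track$start <= pos & pos < track$end)
      if (length(hit) == 0) 0 else track$value[hit[1]]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}

# Per-base border labeling: a bin is a border bin iff any of its bases
# lies in [point - window/2, point + window/2).
oracle_border_labels <- function(bins, points, window) {
  half <- window / 2
  vapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    p <- points$pos[points$chrom == b$chrom]
    if (length(p) == 0) return(0L)
    bases <- seq(b$start, b$end - 1)
    as.integer(any(vapply(bases, function(pos) {
      any(p - half <= pos & pos < p + half)
    }, logical(1))))
  }, integer(1))
}

IUPAC_MATCH <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Position-by-position sliding-window IUPAC match on both strands,
# reported in forward coordinates, deduplicated and sorted.
oracle_scan_motif <- function(seqs, pattern) {
  match_at <- function(sq, pat, pos) {
    letters_p <- strsplit(pat, "")[[1]]
    letters_s <- strsplit(substr(sq, pos, pos + nchar(pat) - 1), "")[[1]]
    all(vapply(seq_along(letters_p), function(k) {
      letters_s[k] %in% IUPAC_MATCH[[letters_p[k]]]
    }, logical(1)))
  }
  hits <- list()
  for (chrom in names(seqs)) {
    sq <- seqs[[chrom]]
    L <- nchar(sq)
    w <- nchar(pattern)
    if (w > L) next
    for (pat in unique(c(pattern, oracle_revcomp(pattern)))) {
      for (pos in seq_len(L - w + 1)) {
        if (match_at(sq, pat, pos)) {
          hits[[length(hits) + 1]] <-
            data.frame(chrom = chrom, start = pos - 1, end = pos - 1 + w)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# AUC by enumeration of all positive-negative score pairs (ties = 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- expand.grid(p = pos, n = neg)
  mean(ifelse(grid$p > grid$n, 1, ifelse(grid$p == grid$n, 0.5, 0)))
}

# Generic maximum-likelihood logistic fit by direct optimization of the
# Bernoulli log-likelihood (independent of the IRLS code path).
oracle_logistic_mle <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -(sum(y * eta) - sum(ifelse(eta > 30, eta, log1p(exp(eta)))))
  }
  opt <- stats::optim(numeric(ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# Random small genome fixtures ----------------------------------------------

random_intervals <- function(layout, n, max_len = 40) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[match(chrom, layout$chrom)]
  start <- floor(runif(n, 0, len - 1))
  width <- pmax(1, floor(runif(n, 1, max_len)))
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + width, len))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A genome in which wild-type motif placements coincide with planted TAD
# junctions while variant placements are scattered at random (shared by
# the motif and CLI tests).
build_snp_genome <- function(n_borders = 60, chrom_len = 3e5) {
  wt <- "CGATA"
  variants <- tadmlr::enumerate_snp_variants(wt, 2)$pattern
  base <- strsplit(random_dna(chrom_len), "")[[1]]
  junctions <- sort(sample(seq(5000, chrom_len - 5000, by = 2500),
                           n_borders))
  for (j in junctions) {
    for (off in c(-150, 0, 150)) {
      base[(j + off):(j + off + 4)] <- strsplit(wt, "")[[1]]
    }
  }
  scatter <- sample(seq(10, chrom_len - 10), 120)
  for (i in seq_along(scatter)) {
    pat <- variants[2 + (i %% 3)]
    base[scatter[i]:(scatter[i] + 4)] <- strsplit(pat, "")[[1]]
  }
  tad_edges <- c(0, junctions, chrom_len)
  list(
    seqs = c(g = paste(base, collapse = "")),
    tads = tibble::tibble(chrom = "g",
                          start = tad_edges[-length(tad_edges)],
                          end = tad_edges[-1])
  )
}

# Non-overlapping TADs tiling most of a chromosome.
random_tads <- function(chrom, chrom_len, mean_size) {
  edges <- c(0, cumsum(pmax(floor(rexp(ceiling(2 * chrom_len / mean_size),
                                       1 / mean_size)), 1000)))
  edges <- edges[edges <= chrom_len]
  if (length(edges) < 3) edges <- c(0, floor(chrom_len / 2), chrom_len)
  tibble::tibble(chrom = chrom, start = edges[-length(edges)],
                 end = edges[-1])
}
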