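# IUPAC consensus-motif scanning and single-base variant (SNP) effect
# analysis: map the wild-type motif and its three alternative alleles at a
# position genome-wide, and estimate their border influence jointly in one
# multiple logistic regression.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0) {
    abort("`pattern` must be a single non-empty string.")
  }
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], IUPAC_CODES)
  if (length(bad) > 0) {
    abort(sprintf("Invalid IUPAC letter(s) in pattern: %s.",
                  paste(unique(bad), collapse = ", ")))
  }
  pattern
}

#' Scan a genome for exact IUPAC consensus matches
#'
#' Finds all matches of an IUPAC consensus pattern (N matches any base,
#' R/Y/S/W/... their usual degenerate sets) on both strands. Reverse-strand
#' hits are located by matching the reverse complement of the pattern and
#' are reported in forward coordinates; hits found on both strands at the
#' same position are collapsed to one interval.
#'
#' @param sequences Named character vector of sequences (see
#'   [read_genome_fasta()]) or a `Biostrings::DNAStringSet`.
#' @param pattern IUPAC consensus string, e.g. `"CCANNAGNNGGCA"` (CTCF) or
#'   `"CGATA"` (BEAF-32).
#' @param name Optional label stored in the `name` column (defaults to the
#'   pattern itself).
#' @return Interval tibble (`chrom`, `start`, `end`, `name`, `score`) of
#'   deduplicated matches, 0-based half-open, sorted by position. A pattern
#'   longer than every sequence simply yields no matches.
#' @export
scan_motif <- function(sequences, pattern, name = NULL) {
  pattern <- check_pattern(pattern)
  name <- name %||% pattern
  if (is.character(sequences)) {
    if (is.null(names(sequences))) abort("`sequences` must be named.")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  fwd <- Biostrings::DNAString(pattern)
  rev <- Biostrings::reverseComplement(fwd)
  hits <- purrr::map(seq_along(sequences), function(i) {
    subj <- sequences[[i]]
    if (nchar(pattern) > length(subj)) return(NULL)
    h <- purrr::map2(list(fwd, rev), c("+", "-"), function(pat, strand) {
      m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
      if (length(m) == 0) return(NULL)
      tibble(chrom = names(sequences)[i],
             start = IRanges::start(m) - 1,
             end = IRanges::end(m),
             strand = strand)
    })
    purrr::list_rbind(purrr::compact(h))
  })
  out <- purrr::list_rbind(purrr::compact(hits))
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric()))
  }
  out |>
    dplyr::distinct(.data$chrom, .data$start, .data$end) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(name = name, score = NA_real_)
}

#' Enumerate the three single-base variants at a motif position
#'
#' Substitutes each alternative concrete base at `position` of the
#' consensus. The base at that position must itself be concrete (A, C, G
#' or T): ambiguity codes, in particular N, have no defined alternative
#' alleles and raise an error.
#'
#' @param pattern IUPAC consensus string (the wild type).
#' @param position 1-based position within the pattern.
#' @return A tibble with one row per allele (wild type first): `allele`,
#'   `pattern`, `wild_type` (logical), `position`.
#' @examples
#' enumerate_snp_variants("CCANNAGNNGGCA", 1)
#' @export
enumerate_snp_variants <- function(pattern, position) {
  pattern <- check_pattern(pattern)
  position <- check_count(position, "position")
  if (position > nchar(pattern)) {
    abort("`position` is beyond the end of the pattern.")
  }
  base <- substr(pattern, position, position)
  if (!base %in% c("A", "C", "G", "T")) {
    abort(sprintf(
      "Position %d holds ambiguity code '%s'; variants are only defined for concrete bases (A/C/G/T).",
      position, base
    ))
  }
  alleles <- c(base, setdiff(c("A", "C", "G", "T"), base))
  tibble(
    allele = alleles,
    pattern = unname(vapply(alleles, function(al) {
      p <- pattern
      substr(p, position, position) <- al
      p
    }, character(1))),
    wild_type = alleles == base,
    position = position
  )
}

#' Joint SNP-effect analysis of a consensus motif
#'
#' Scans the genome for the wild-type motif and for its three alternative
#' alleles at one position, encodes each match set as a fractional-
#' occupancy feature over the bins, and fits all four in one multiple
#' logistic regression against the border labels. An allele whose beta
#' falls below the wild-type beta diminishes the motif's influence on
#' borders. Alleles with no genomic match are dropped with a warning.
#'
#' @param bins Bins from [make_bins()].
#' @param Y Binary border labels, one per bin (see [label_borders()]).
#' @param sequences Genome sequences (named character vector or
#'   `DNAStringSet`); chromosome names must match the bin layout.
#' @param pattern Wild-type IUPAC consensus.
#' @param position 1-based motif position to mutate.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble with one row per retained allele: `allele`, `pattern`,
#'   `wild_type`, `n_matches`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
snp_effect_analysis <- function(bins, Y, sequences, pattern, position,
                                conf_level = 0.95) {
  variants <- enumerate_snp_variants(pattern, position)
  Y <- check_binary(Y)
  scans <- purrr::map(variants$pattern,
                      function(p) scan_motif(sequences, p))
  n_matches <- vapply(scans, nrow, integer(1))
  keep <- n_matches > 0
  if (!any(keep)) {
    abort("No allele of the motif matches the genome at all.")
  }
  if (any(!keep)) {
    warn(sprintf("Dropping allele(s) with zero genomic matches: %s.",
                 paste(variants$allele[!keep], collapse = ", ")))
  }
  feats <- purrr::map(scans[keep], function(iv) {
    encode_coordinate_feature(bins, iv, unknown_chrom = "drop")
  })
  names(feats) <- variants$pattern[keep]
  mat <- assemble_matrix(bins = NULL, Y = Y, features = feats,
                         mode = "coordinate")
  fit <- fit_mlr(mat, conf_level = conf_level)
  dplyr::left_join(
    dplyr::mutate(variants[keep, ], n_matches = n_matches[keep]),
    dplyr::rename(tidy(fit, intercept = FALSE), pattern = "term"),
    by = "pattern"
  )
}
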