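# Reading and writing the standard genomic text formats the framework
# consumes: BED3+ intervals, bedGraph signal, chrom.sizes and FASTA.
# All coordinates are 0-based half-open throughout the package, exactly as
# stored in BED/bedGraph.

#' Describe a genome as an ordered set of chromosome lengths
#'
#' @param x Either a named numeric vector of chromosome lengths in bp, or a
#'   data frame with columns `chrom` and `length`.
#'
#' @return A tibble with columns `chrom` (character) and `length` (double),
#'   one row per chromosome, in the order given.
#' @examples
#' genome_layout(c(chr2L = 23513712, chr2R = 25286936))
#' @export
genome_layout <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("chrom", "length") %in% names(x))) {
      abort("`x` must have columns `chrom` and `length`.")
    }
    out <- tibble(chrom = as.character(x$chrom), length = as.numeric(x$length))
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- tibble(chrom = names(x), length = as.numeric(x))
  } else {
    abort("`x` must be a named numeric vector or a data frame.")
  }
  if (anyDuplicated(out$chrom)) abort("Chromosome names must be unique.")
  if (any(out$length <= 0) || anyNA(out$length)) {
    abort("Chromosome lengths must be positive.")
  }
  if (any(out$chrom == "")) abort("Chromosome names must be non-empty.")
  out
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with chromosome name and length per line.
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome_layout(x)
}

# Split raw lines on tabs, dropping header/browser/comment lines but keeping
# the original line numbers for error messages.
split_bed_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       line_no = which(keep))
}

parse_coord <- function(x, line_no, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-integer %s coordinate at line %d.",
                  path, what, line_no[bad[1]]))
  }
  out
}

#' Read genomic intervals from a BED file
#'
#' Reads the minimal BED3+ dialect: three mandatory tab-separated columns
#' (chrom, start, end), with optional column 4 mapped to `name` and column 5
#' to `score`. Coordinates are kept 0-based half-open, exactly as in the
#' file. `track`, `browser` and `#` lines are skipped. Chromosome names are
#' never normalized (no "chr" prefix handling).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   in file order. `name`/`score` are `NA` when absent.
#' @export
read_bed <- function(path) {
  parsed <- split_bed_lines(path)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric()))
  }
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: fewer than 3 tab-separated fields at line %d.",
                  path, line_no[which(nf < 3)[1]]))
  }
  grab <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  out <- tibble(
    chrom = grab(1),
    start = parse_coord(grab(2), line_no, "start", path),
    end   = parse_coord(grab(3), line_no, "end", path),
    name  = grab(4),
    score = suppressWarnings(as.numeric(grab(5)))
  )
  bad <- which(out$start >= out$end | out$start < 0 | out$chrom == "")
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval (need 0 <= start < end) at line %d.",
                  path, line_no[bad[1]]))
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes chrom/start/end plus `name` and `score`
#' columns when any are non-missing (absent names are written as ".").
#'
#' @param x Interval tibble with at least `chrom`, `start`, `end`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  nm <- if ("name" %in% names(x)) x$name else rep(NA_character_, nrow(x))
  sc <- if ("score" %in% names(x)) x$score else rep(NA_real_, nrow(x))
  has_name <- any(!is.na(nm))
  has_score <- any(!is.na(sc))
  if (has_name || has_score) {
    cols <- c(cols, list(ifelse(is.na(nm), ".", nm)))
  }
  if (has_score) {
    cols <- c(cols, list(ifelse(is.na(sc), ".", as.character(sc))))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a quantitative signal track from a bedGraph file
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`, sorted by
#'   (chrom, start). Intervals within a chromosome must not overlap;
#'   abutting intervals are allowed.
#' @export
read_bedgraph <- function(path) {
  parsed <- split_bed_lines(path)
  fields <- parsed$fields
  line_no <- parsed$line_no
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  value = numeric()))
  }
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(sprintf("%s: bedGraph needs 4 fields, line %d has %d.",
                  path, line_no[which(nf < 4)[1]], nf[which(nf < 4)[1]]))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = parse_coord(vapply(fields, `[[`, character(1), 2), line_no,
                        "start", path),
    end   = parse_coord(vapply(fields, `[[`, character(1), 3), line_no,
                        "end", path),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4)))
  )
  if (anyNA(out$value)) {
    abort(sprintf("%s: non-numeric value at line %d.",
                  path, line_no[which(is.na(out$value))[1]]))
  }
  check_intervals(out, "bedGraph intervals")
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  ovl <- out |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(ovl$bad)) {
    abort(sprintf("%s: overlapping intervals on chromosome(s): %s.",
                  path, paste(ovl$chrom[ovl$bad], collapse = ", ")))
  }
  out
}

#' Read genome sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences, one per record,
#'   in file order. Record names are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(sprintf("Duplicate FASTA record name(s): %s.",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  setNames(toupper(as.character(set)), nm)
}
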