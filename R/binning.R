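# Building the binned data matrix: tile the genome into fixed-size bins,
# mark bins that fall inside TAD-border windows (the response Y), and encode
# genomic features per bin either as fractional occupancy by interval
# coordinates ("coordinate" mode) or as the length-weighted mean of a
# quantitative signal ("quantitative" mode).

#' Tile a genome into fixed-size bins
#'
#' Each chromosome is covered by consecutive, non-overlapping bins of
#' `bin_size` bp; the last bin of a chromosome may be shorter. Typical
#' choices are 50 bp bins (fly-scale genomes, 1 kb border windows) and
#' 1 kb bins (human-scale genomes, 20 kb border windows).
#'
#' @param layout Genome layout tibble from [genome_layout()] or
#'   [read_chrom_sizes()].
#' @param bin_size Bin width in bp (> 0).
#' @return A `tad_bins` tibble with columns `chrom`, `start`, `end` and the
#'   bin size and layout stored as attributes.
#' @examples
#' make_bins(genome_layout(c(chrA = 250)), bin_size = 100)
#' @export
make_bins <- function(layout, bin_size) {
  layout <- genome_layout(layout)
  check_number(bin_size, "bin_size")
  if (bin_size <= 0) abort("`bin_size` must be > 0.")
  bins <- purrr::map2(layout$chrom, layout$length, function(chrom, len) {
    start <- seq(0, len - 1, by = bin_size)
    tibble(chrom = chrom, start = start, end = pmin(start + bin_size, len))
  }) |>
    purrr::list_rbind()
  structure(bins,
            bin_size = bin_size,
            layout = layout,
            class = c("tad_bins", class(bins)))
}

bins_attrs <- function(bins) {
  bs <- attr(bins, "bin_size")
  layout <- attr(bins, "layout")
  if (is.null(bs) || is.null(layout)) {
    abort("`bins` must be created by `make_bins()`.")
  }
  list(bin_size = bs, layout = layout)
}

# Border points are TAD junctions: positions where one TAD ends and the next
# begins on the same chromosome. When adjacent TADs are separated by a gap,
# both gap edges are border points. The first start and last end on each
# chromosome are terminal edges, excluded unless `include_chrom_ends`.
#' Locate TAD border points
#'
#' @param tads Interval tibble of TAD coordinates; per chromosome they must
#'   be non-overlapping (any record order is accepted).
#' @param include_chrom_ends Also treat each chromosome's first TAD start
#'   and last TAD end as border points? Default `FALSE`.
#' @return A tibble with columns `chrom` and `pos` (0-based position).
#' @export
border_points <- function(tads, include_chrom_ends = FALSE) {
  tads <- sort_check_disjoint(tads, "tads")
  tads |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(pos = {
      k <- length(start)
      inner <- if (k > 1) {
        e <- end[-k]
        s <- start[-1]
        # junction -> one point; gap -> both edges
        unique(as.numeric(rbind(e, s)))
      } else numeric(0)
      if (include_chrom_ends) c(start[1], inner, end[k]) else inner
    }) |>
    dplyr::distinct()
}

#' Label bins that fall inside TAD-border windows
#'
#' A window of `window` bp is centered on every border point (see
#' [border_points()]); a bin gets `Y = 1` if it overlaps any window at all,
#' else `Y = 0`. Windows of nearby borders are implicitly unioned, so a bin
#' is never counted twice.
#'
#' @inheritParams border_points
#' @param bins Bins from [make_bins()].
#' @param window Total border-window width in bp (> 0), e.g. 1000 for 50 bp
#'   bins or 20000 for 1 kb bins.
#' @return Integer vector of 0/1 border labels, one per bin.
#' @export
label_borders <- function(bins, tads, window, include_chrom_ends = FALSE) {
  at <- bins_attrs(bins)
  check_number(window, "window")
  if (window <= 0) abort("`window` must be > 0.")
  pts <- border_points(tads, include_chrom_ends = include_chrom_ends)
  y <- integer(nrow(bins))
  half <- window / 2
  offsets <- cumsum(c(0, rle(bins$chrom)$lengths))
  chrom_order <- rle(bins$chrom)$values
  n_per <- diff(offsets)
  for (i in seq_along(chrom_order)) {
    p <- pts$pos[pts$chrom == chrom_order[i]]
    if (length(p) == 0) next
    nb <- n_per[i]
    lo <- pmax(floor((p - half) / at$bin_size), 0)
    hi <- pmin(ceiling((p + half) / at$bin_size) - 1, nb - 1)
    for (j in seq_along(p)) {
      if (lo[j] > hi[j]) next
      idx <- offsets[i] + seq.int(lo[j], hi[j]) + 1L
      y[idx] <- 1L
    }
  }
  y
}

# Shared scaffolding for per-bin aggregation over one chromosome: returns a
# list of per-chromosome bin index ranges within the genome-wide vector.
split_bins_by_chrom <- function(bins) {
  r <- rle(bins$chrom)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  setNames(purrr::map2(starts, ends, seq.int), r$values)
}

#' Encode a coordinate feature as fractional bin occupancy
#'
#' For each bin, the value is the fraction of its bases covered by the
#' union of the supplied intervals: a feature fully covering a bin scores 1,
#' a feature overlapping x% of the bin scores x/100, no overlap scores 0.
#' Overlapping intervals are unioned, never summed.
#'
#' @param bins Bins from [make_bins()].
#' @param intervals Interval tibble (e.g. from [read_bed()]).
#' @param unknown_chrom What to do with intervals on chromosomes absent from
#'   the bin layout: `"warn"` (skip with a warning, default), `"error"`, or
#'   `"drop"` (skip silently).
#' @return Numeric vector in `[0, 1]`, one value per bin.
#' @export
encode_coordinate_feature <- function(bins, intervals,
                                      unknown_chrom = c("warn", "error",
                                                        "drop")) {
  at <- bins_attrs(bins)
  check_intervals(intervals)
  unknown_chrom <- match.arg(unknown_chrom)
  unknown <- setdiff(unique(intervals$chrom), at$layout$chrom)
  if (length(unknown) > 0) {
    msg <- sprintf("Skipping intervals on unknown chromosome(s): %s.",
                   paste(unknown, collapse = ", "))
    if (unknown_chrom == "error") abort(msg)
    if (unknown_chrom == "warn") warn(msg)
    intervals <- dplyr::filter(intervals, !.data$chrom %in% unknown)
  }
  out <- numeric(nrow(bins))
  idx <- split_bins_by_chrom(bins)
  for (chrom in names(idx)) {
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0) next
    len <- at$layout$length[at$layout$chrom == chrom]
    ir <- IRanges::restrict(
      IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end)),
      start = 1, end = len
    )
    cov <- IRanges::coverage(ir, width = len)
    b <- bins[idx[[chrom]], , drop = FALSE]
    covered <- IRanges::viewSums(IRanges::Views(cov, b$start + 1, b$end))
    out[idx[[chrom]]] <- covered / (b$end - b$start)
  }
  out
}

#' Encode a quantitative signal as the per-bin mean
#'
#' For each bin, the value is the length-weighted mean of the signal over
#' the bin, with uncovered bases contributing 0 (so a signal of 2.0 over
#' half a bin yields 1.0).
#'
#' @param bins Bins from [make_bins()].
#' @param track Signal tibble with columns `chrom`, `start`, `end`, `value`
#'   (e.g. from [read_bedgraph()]); intervals must not overlap within a
#'   chromosome.
#' @return Numeric vector, one value per bin.
#' @export
encode_quantitative_feature <- function(bins, track) {
  at <- bins_attrs(bins)
  check_intervals(track, "track")
  if (!"value" %in% names(track)) abort("`track` must have a `value` column.")
  track <- sort_check_disjoint(track, "track")
  out <- numeric(nrow(bins))
  idx <- split_bins_by_chrom(bins)
  for (chrom in names(idx)) {
    iv <- track[track$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0) next
    len <- at$layout$length[at$layout$chrom == chrom]
    keep <- iv$start < len
    iv <- iv[keep, , drop = FALSE]
    ir <- IRanges::restrict(IRanges::IRanges(iv$start + 1, iv$end),
                            start = 1, end = len)
    cov <- IRanges::coverage(ir, width = len, weight = iv$value)
    b <- bins[idx[[chrom]], , drop = FALSE]
    sums <- IRanges::viewSums(IRanges::Views(cov, b$start + 1, b$end))
    out[idx[[chrom]]] <- sums / (b$end - b$start)
  }
  out
}

#' Assemble a binned feature matrix
#'
#' Combines bins, the border indicator `Y` and named feature vectors into
#' the central analysis object: one row per genomic bin, one column per
#' feature, plus `Y`.
#'
#' @param bins Bins from [make_bins()], or `NULL` for a matrix without
#'   genomic coordinates (e.g. simulated data).
#' @param Y Binary border indicator, one value per bin.
#' @param features Named list of numeric vectors, or a data frame, one
#'   column per feature. May be empty (intercept-only matrix).
#' @param mode `"coordinate"` (fractional occupancy values in `[0, 1]`) or
#'   `"quantitative"` (real-valued signal means).
#' @return A `tad_matrix` tibble with columns `chrom`, `start`, `end` (when
#'   `bins` is given), `Y`, and one column per feature.
#' @export
assemble_matrix <- function(bins = NULL, Y, features,
                            mode = c("coordinate", "quantitative")) {
  mode <- match.arg(mode)
  Y <- check_binary(Y)
  features <- as.data.frame(features, optional = TRUE,
                            check.names = FALSE)
  if (ncol(features) > 0 && anyDuplicated(names(features))) {
    abort("Feature names must be unique.")
  }
  if (ncol(features) > 0 && any(names(features) %in% c("chrom", "start",
                                                       "end", "Y"))) {
    abort("Feature names must not clash with `chrom`, `start`, `end`, `Y`.")
  }
  if (ncol(features) > 0 && any(vapply(features, length, 1L) != length(Y))) {
    abort("All feature vectors must have the same length as `Y`.")
  }
  base <- if (!is.null(bins)) {
    bins_attrs(bins)
    if (nrow(bins) != length(Y)) {
      abort("`Y` must have one value per bin.")
    }
    tibble(chrom = bins$chrom, start = bins$start, end = bins$end, Y = Y)
  } else {
    tibble(Y = Y)
  }
  out <- if (ncol(features) > 0) {
    dplyr::bind_cols(base, as_tibble(features))
  } else {
    base
  }
  new_tad_matrix(out, features = names(features), mode = mode)
}

new_tad_matrix <- function(data, features, mode) {
  if (mode == "coordinate" && length(features) > 0) {
    vals <- as.matrix(data[features])
    if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
      abort("Coordinate-mode feature values must lie in [0, 1].")
    }
  }
  structure(as_tibble(data),
            features = features,
            mode = mode,
            class = c("tad_matrix", class(as_tibble(data))))
}

#' Mark an existing data frame as a binned feature matrix
#'
#' @param data Data frame with a binary `Y` column and numeric feature
#'   columns.
#' @param features Feature column names; defaults to every column other
#'   than `chrom`, `start`, `end`, `Y`.
#' @param mode Feature encoding, `"coordinate"` or `"quantitative"`.
#' @return A `tad_matrix` tibble.
#' @export
as_tad_matrix <- function(data, features = NULL,
                          mode = c("coordinate", "quantitative")) {
  mode <- match.arg(mode)
  if (!"Y" %in% names(data)) abort("`data` must have a `Y` column.")
  check_binary(data$Y)
  features <- features %||%
    setdiff(names(data), c("chrom", "start", "end", "Y"))
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Unknown feature column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  new_tad_matrix(data, features = features, mode = mode)
}

#' Feature column names of a binned matrix
#'
#' @param data A `tad_matrix`, or any data frame (falls back to all columns
#'   except `chrom`, `start`, `end`, `Y`).
#' @return Character vector of feature names.
#' @export
feature_names <- function(data) {
  attr(data, "features") %||%
    setdiff(names(data), c("chrom", "start", "end", "Y"))
}

matrix_mode <- function(data) attr(data, "mode") %||% "coordinate"

# Numeric design matrix (no intercept) + response for the fitting code.
design_matrix <- function(data, features = NULL) {
  features <- features %||% feature_names(data)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Unknown feature column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(data, check.names = FALSE)[features])
  storage.mode(X) <- "double"
  list(X = X, y = check_binary(data$Y), features = features)
}

#' Write / read a feature matrix as TSV
#'
#' The TSV holds one row per bin (`chrom`, `start`, `end` when present,
#' then `Y`, then one column per feature); the encoding mode is recorded in
#' a `# mode:` header line.
#'
#' @param data A `tad_matrix`.
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `tad_matrix`.
#' @export
write_feature_matrix <- function(data, path) {
  writeLines(sprintf("# mode: %s", matrix_mode(data)), path)
  readr::write_tsv(as_tibble(data), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  mode <- if (grepl("^# mode:", first)) {
    trimws(sub("^# mode:", "", first))
  } else {
    "coordinate"
  }
  data <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                          progress = FALSE)
  as_tad_matrix(data, mode = match.arg(mode, c("coordinate", "quantitative")))
}
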