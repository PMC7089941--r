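#' Absolute copy-number segment tables
#'
#' A segment table holds per-sample absolute copy-number profiles, one row per
#' segment, with 1-based closed genomic coordinates (SEG convention): columns
#' `sample`, `chrom`, `start`, `end`, `total_cn` and optionally `major_cn`
#' (major allele copy number). `as_segments()` validates a data frame and
#' returns a canonically sorted `cn_segments` tibble; it is called by every
#' function that consumes segments, so readers and generators agree on the
#' invariants:
#'
#' * `end >= start` and segment length `end - start + 1 > 0`;
#' * `total_cn` a non-negative integer, `major_cn <= total_cn` when present;
#' * within each sample and chromosome, segments are non-overlapping.
#'
#' Chromosome labels are opaque strings; no "chr" prefix normalisation is
#' attempted beyond an optional case fold.
#'
#' @param x A data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `total_cn` and optionally `major_cn`.
#' @param casefold_chrom Lower-case chromosome labels before sorting
#'   (default `FALSE`).
#' @return A tibble of class `cn_segments`, sorted by sample, chromosome and
#'   start position.
#' @examples
#' seg <- tibble::tibble(
#'   sample = "S1", chrom = "1",
#'   start = c(1, 30000001), end = c(30000000, 60000000),
#'   total_cn = c(2, 3), major_cn = c(1, 2)
#' )
#' as_segments(seg)
#' @export
as_segments <- function(x, casefold_chrom = FALSE) {
  stopifnot(is.data.frame(x))
  required <- c("sample", "chrom", "start", "end", "total_cn")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("segment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"major_cn" %in% names(x)) x$major_cn <- NA_real_
  if (is.logical(x$major_cn) && all(is.na(x$major_cn))) x$major_cn <- NA_real_
  x <- x[, c("sample", "chrom", "start", "end", "total_cn", "major_cn")]
  x$sample <- as.character(x$sample)
  x$chrom <- as.character(x$chrom)
  if (casefold_chrom) x$chrom <- tolower(x$chrom)

  for (col in c("start", "end", "total_cn", "major_cn")) {
    v <- x[[col]]
    if (!is.numeric(v)) abort(paste0("column '", col, "' must be numeric"))
    bad <- which(is.finite(v) & v %% 1 != 0)
    if (length(bad) > 0) {
      abort(paste0("non-integer value in column '", col, "' at row ", bad[1],
                   " (", v[bad[1]], ")"))
    }
  }
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$total_cn)) {
    abort("start, end and total_cn must not contain missing values")
  }
  if (any(x$start < 1)) abort("start positions must be >= 1 (1-based coordinates)")
  if (any(x$end < x$start)) {
    i <- which(x$end < x$start)[1]
    abort(paste0("segment with end < start at row ", i, " (", x$sample[i], " ",
                 x$chrom[i], ":", x$start[i], "-", x$end[i], ")"))
  }
  if (any(x$total_cn < 0)) abort("total_cn must be non-negative")
  has_major <- !is.na(x$major_cn)
  if (any(x$major_cn[has_major] < 0)) abort("major_cn must be non-negative")
  if (any(x$major_cn[has_major] > x$total_cn[has_major])) {
    i <- which(has_major)[which(x$major_cn[has_major] > x$total_cn[has_major])[1]]
    abort(paste0("major_cn exceeds total_cn at row ", i, " (", x$sample[i], " ",
                 x$chrom[i], ":", x$start[i], ")"))
  }

  x <- arrange(x, .data$sample, .data$chrom, .data$start)
  # overlap check per sample/chromosome on the sorted table
  grp <- paste(x$sample, x$chrom, sep = "\r")
  same_grp <- grp[-1] == grp[-nrow(x)]
  if (nrow(x) > 1) {
    ovl <- which(same_grp & x$start[-1] <= x$end[-nrow(x)])
    if (length(ovl) > 0) {
      i <- ovl[1]
      pos <- function(v) format(v, scientific = FALSE, trim = TRUE)
      abort(paste0(
        "overlapping segments for sample '", x$sample[i], "' chrom '",
        x$chrom[i], "': ", pos(x$start[i]), "-", pos(x$end[i]), " overlaps ",
        pos(x$start[i + 1]), "-", pos(x$end[i + 1])
      ))
    }
  }
  class(x) <- c("cn_segments", class(x))
  x
}

#' @rdname as_segments
#' @export
is_segments <- function(x) inherits(x, "cn_segments")

seg_length <- function(x) x$end - x$start + 1

#' Read and write SEG-like segment files
#'
#' `read_seg()` parses a tab-delimited segment file with header columns
#' `sample`, `chrom`, `start`, `end`, `total_cn` and optionally `major_cn`
#' (1-based closed coordinates) and returns a validated [as_segments()] table.
#' Parsing is strict: overlapping segments, non-integer copy numbers or
#' malformed coordinates are rejected with the offending sample, chromosome
#' and position. `write_seg()` writes the same dialect; writing then reading
#' is the identity.
#'
#' @param path File path.
#' @param casefold_chrom Passed to [as_segments()].
#' @return `read_seg()` returns a `cn_segments` tibble; `write_seg()` returns
#'   `path` invisibly.
#' @export
read_seg <- function(path, casefold_chrom = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    chrom = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("sample", "chrom", "start", "end", "total_cn")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "': missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("start", "end", "total_cn", "major_cn"), names(x))) {
    bad <- which(is.finite(x[[col]]) & x[[col]] %% 1 != 0)
    if (length(bad) > 0) {
      abort(paste0("'", path, "', line ", bad[1] + 1L, ": non-integer '",
                   col, "' (", x[[col]][bad[1]], ")"))
    }
  }
  as_segments(x, casefold_chrom = casefold_chrom)
}

#' @rdname read_seg
#' @param segments A segment table coercible with [as_segments()].
#' @export
write_seg <- function(segments, path) {
  segments <- as_segments(segments)
  out <- as_tibble(segments)
  if (all(is.na(out$major_cn))) out$major_cn <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read centromere intervals from a BED file
#'
#' Centromere intervals delimit chromosome arms for arm-aware LST counting.
#' BED input is 0-based half-open; coordinates are converted to the package's
#' 1-based closed convention.
#'
#' @param path BED file path (columns chrom, start, end; no header).
#' @return A tibble with columns `chrom`, `start`, `end` (1-based closed).
#' @export
read_centromeres_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd", progress = FALSE)
  if (any(x$end <= x$start)) abort(paste0("'", path, "': empty BED interval"))
  tibble(chrom = x$chrom, start = x$start + 1, end = x$end)
}
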