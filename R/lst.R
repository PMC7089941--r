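#' DNA index of copy-number profiles
#'
#' The DNA index is the segment-length-weighted mean total copy number,
#' rescaled so that a uniformly diploid genome scores 1.0:
#' \deqn{\mathrm{DI} = \frac{\sum_i \ell_i \, c_i}{2 \sum_i \ell_i}}
#' where \eqn{\ell_i} is segment length and \eqn{c_i} total copy number. The
#' division by two puts the 1.3 diploid/tetraploid decision threshold on the
#' conventional flow-cytometry scale; `raw = TRUE` gives the unscaled mean
#' copy number instead.
#'
#' @param segments A segment table ([as_segments()]).
#' @param raw If `TRUE`, return the raw length-weighted mean copy number
#'   without the division by two.
#' @return A tibble with columns `sample`, `dna_index`.
#' @examples
#' seg <- tibble::tibble(sample = "S1", chrom = "1",
#'                       start = c(1, 50e6 + 1), end = c(50e6, 100e6),
#'                       total_cn = c(2, 4))
#' compute_dna_index(seg)   # (2 + 4)/2 / 2 = 1.5
#' @export
compute_dna_index <- function(segments, raw = FALSE) {
  segments <- as_segments(segments)
  if (nrow(segments) == 0) abort("empty segment profile")
  out <- segments %>%
    mutate(len = seg_length(segments)) %>%
    group_by(.data$sample) %>%
    summarise(dna_index = sum(.data$len * .data$total_cn) / sum(.data$len),
              total_len = sum(.data$len), .groups = "drop")
  if (any(out$total_len <= 0)) abort("zero total segment length")
  if (!raw) out$dna_index <- out$dna_index / 2
  select(out, "sample", "dna_index")
}

#' Ploidy class from the DNA index
#'
#' Near-diploid below 1.3, near-tetraploid at or above 1.3 (the boundary is
#' tetraploid). The class picks the LST cut-off (15 vs 20) in [call_hrd()].
#'
#' @param dna_index Positive numeric vector of DNA indices.
#' @return Character vector, `"near_diploid"` or `"near_tetraploid"`.
#' @export
classify_ploidy <- function(dna_index) {
  if (!is.numeric(dna_index) || any(!is.finite(dna_index)) || any(dna_index <= 0)) {
    abort("dna_index must be positive and finite")
  }
  ifelse(dna_index < 1.3, "near_diploid", "near_tetraploid")
}

# state id per segment: total_cn and, when available anywhere in the profile,
# major_cn; NA major compares equal to NA
seg_state <- function(total_cn, major_cn, use_major) {
  if (use_major) paste(total_cn, ifelse(is.na(major_cn), ".", major_cn))
  else as.character(total_cn)
}

# merge runs of equal-state consecutive segments of one sample/chromosome;
# df sorted by start
merge_equal_runs <- function(df, use_major) {
  if (nrow(df) <= 1) return(df)
  st <- seg_state(df$total_cn, df$major_cn, use_major)
  run <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
  if (max(run) == nrow(df)) return(df)
  first <- !duplicated(run)
  out <- df[first, , drop = FALSE]
  out$end <- tapply(df$end, run, max)[unique(run)]
  out
}

# iterative sub-threshold deletion for one sample/chromosome block
filter_small_chrom <- function(df, min_len, use_major) {
  df <- merge_equal_runs(df, use_major)
  repeat {
    len <- df$end - df$start + 1
    small <- which(len < min_len)
    if (length(small) == 0 || nrow(df) == 0) break
    # shortest first, genomic position breaks ties
    i <- small[order(len[small], df$start[small])][1]
    if (nrow(df) == 1) {
      df <- df[0, , drop = FALSE]  # lone variant region: filtered out entirely
      break
    }
    if (i == 1) {
      df$start[2] <- df$start[1]          # extend right neighbour leftward
      df <- df[-1, , drop = FALSE]
    } else if (i == nrow(df)) {
      df$end[i - 1] <- df$end[i]          # extend left neighbour rightward
      df <- df[-i, , drop = FALSE]
    } else {
      st <- seg_state(df$total_cn, df$major_cn, use_major)
      if (st[i - 1] == st[i + 1]) {
        df$end[i - 1] <- df$end[i + 1]    # bridge: neighbours re-merge
        df <- df[-c(i, i + 1), , drop = FALSE]
      } else {
        df$end[i - 1] <- df$end[i]        # extend left neighbour over the gap
        df <- df[-i, , drop = FALSE]
      }
    }
    df <- merge_equal_runs(df, use_major)
  }
  df
}

#' Smooth and filter a segment profile
#'
#' Prepares a profile for LST counting: adjacent same-state segments (equal
#' total and major copy number) are merged, then copy-number variant regions
#' shorter than `min_variant_mb` are iteratively deleted, shortest first with
#' ties broken by genomic position. When a deleted segment's neighbours share
#' a state they re-merge across it; otherwise the left neighbour extends over
#' the freed interval (the right neighbour for a leading segment). The result
#' is a fixed point: idempotent and independent of input row order.
#'
#' @param segments A segment table.
#' @param min_variant_mb Minimum segment length retained, in Mb (default 3).
#' @return A `cn_segments` tibble.
#' @export
smooth_and_filter <- function(segments, min_variant_mb = 3) {
  segments <- as_segments(segments)
  min_len <- min_variant_mb * MB
  use_major <- any(!is.na(segments$major_cn))
  parts <- split(as_tibble(segments),
                 paste(segments$sample, segments$chrom, sep = "\r"))
  out <- bind_rows(lapply(parts, filter_small_chrom,
                          min_len = min_len, use_major = use_major))
  as_segments(out)
}

# split segments of one chromosome at a centromere interval; returns arm ids
split_arms <- function(df, cent_start, cent_end) {
  p <- df %>% filter(.data$start < cent_start) %>%
    mutate(end = pmin(.data$end, cent_start - 1), arm = "p")
  q <- df %>% filter(.data$end > cent_end) %>%
    mutate(start = pmax(.data$start, cent_end + 1), arm = "q")
  bind_rows(p, q)
}

#' Count large-scale state transitions (LST)
#'
#' An LST is a chromosomal breakpoint — a change in total copy number or
#' major allele count between consecutive retained segments — whose two
#' flanking segments are each at least `min_region_mb` long. Counting is
#' genome-wide; chromosome (or arm, when centromere intervals are supplied)
#' boundaries never count as breakpoints. The profile is smoothed and
#' sub-3 Mb variant regions removed first ([smooth_and_filter()]) unless
#' `smooth = FALSE` asserts this has already been done.
#'
#' Profiles lacking `major_cn` fall back to a total-copy-number-only
#' breakpoint predicate, with one warning per call.
#'
#' @param segments A segment table.
#' @param min_region_mb Minimum flanking-region length in Mb (default 10).
#' @param arm_boundaries Optional centromere intervals (tibble `chrom`,
#'   `start`, `end`, 1-based closed, e.g. from [read_centromeres_bed()]);
#'   when supplied, transitions are counted within arms. Every listed
#'   chromosome must exist in the profile.
#' @param smooth Apply [smooth_and_filter()] first (default `TRUE`).
#' @param min_variant_mb Filtering threshold forwarded to
#'   [smooth_and_filter()].
#' @return A tibble with columns `sample`, `lst_count`.
#' @export
count_lst <- function(segments, min_region_mb = 10, arm_boundaries = NULL,
                      smooth = TRUE, min_variant_mb = 3) {
  segments <- as_segments(segments)
  samples <- unique(segments$sample)
  if (!any(!is.na(segments$major_cn))) {
    warn("no major_cn in profile; breakpoints use total copy number only")
  }
  if (smooth) segments <- smooth_and_filter(segments, min_variant_mb = min_variant_mb)
  use_major <- any(!is.na(segments$major_cn))
  df <- as_tibble(segments)
  df$unit <- df$chrom
  if (!is.null(arm_boundaries)) {
    unknown <- setdiff(arm_boundaries$chrom, unique(df$chrom))
    if (length(unknown) > 0) {
      abort(paste0("arm_boundaries reference unknown chromosome(s): ",
                   paste(unknown, collapse = ", ")))
    }
    pieces <- lapply(split(df, df$chrom), function(d) {
      cb <- arm_boundaries[arm_boundaries$chrom == d$chrom[1], ]
      if (nrow(cb) == 0) { d$arm <- "whole"; return(d) }
      split_arms(d, cb$start[1], cb$end[1])
    })
    df <- bind_rows(pieces)
    df$unit <- paste(df$chrom, df$arm)
  }
  min_len <- min_region_mb * MB
  counts <- df %>%
    arrange(.data$sample, .data$unit, .data$start) %>%
    group_by(.data$sample, .data$unit) %>%
    summarise(k = {
      st <- seg_state(.data$total_cn, .data$major_cn, use_major)
      len <- .data$end - .data$start + 1
      n <- length(st)
      if (n < 2) 0L
      else sum(st[-1] != st[-n] & len[-1] >= min_len & len[-n] >= min_len)
    }, .groups = "drop") %>%
    group_by(.data$sample) %>%
    summarise(lst_count = as.integer(sum(.data$k)), .groups = "drop")
  # samples whose profile vanished entirely in filtering still get a count
  left_join(tibble(sample = samples), counts, by = "sample") %>%
    mutate(lst_count = dplyr::coalesce(.data$lst_count, 0L))
}

#' Call HRD status from segment profiles
#'
#' Composes the genomic caller end to end: DNA index, ploidy class, smoothing
#' and variant filtering, LST counting, and classification against the
#' ploidy-specific cut-off — 15 LST per genome for near-diploid tumours, 20
#' for near-tetraploid. Tumours at or above the cut-off are `LST_high` (the
#' HRD pattern), below it `LST_low`.
#'
#' @inheritParams count_lst
#' @param dna_index_raw Use the raw mean copy number as DNA index instead of
#'   the conventional halved scale (see [compute_dna_index()]).
#' @return A tibble of class `hrd_calls` with columns `sample`, `dna_index`,
#'   `ploidy_class`, `lst_count`, `cutoff`, `lst_class`.
#' @examples
#' cohort <- gen_cohort(list(n = 8), seed = 1)
#' call_hrd(cohort$segments)
#' @export
call_hrd <- function(segments, min_region_mb = 10, min_variant_mb = 3,
                     arm_boundaries = NULL, dna_index_raw = FALSE) {
  segments <- as_segments(segments)
  di <- compute_dna_index(segments, raw = dna_index_raw)
  counts <- count_lst(segments, min_region_mb = min_region_mb,
                      arm_boundaries = arm_boundaries, smooth = TRUE,
                      min_variant_mb = min_variant_mb)
  out <- di %>%
    mutate(ploidy_class = classify_ploidy(.data$dna_index)) %>%
    left_join(counts, by = "sample") %>%
    mutate(
      cutoff = ifelse(.data$ploidy_class == "near_diploid", 15L, 20L),
      lst_class = ifelse(.data$lst_count >= .data$cutoff, "LST_high", "LST_low")
    )
  class(out) <- c("hrd_calls", class(out))
  out
}
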