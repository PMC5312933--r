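# Tag counting in peak windows, knockdown fold changes with the
# low-count exclusion filter, and the Wilcoxon group tests.

#' Count tags in peak windows
#'
#' A tag counts toward a peak iff its presumed fragment (5' position
#' extended `extend_to` bp in the tag's strand direction) overlaps the
#' peak. Normalized counts are tags per 10 million library tags.
#'
#' @param tags A [TagSet].
#' @param peaks A `GRanges`.
#' @param extend_to Fragment length in bp (default 200).
#' @return Data frame with one row per peak: `chrom`, `start` (0-based),
#'   `end`, `raw_count`, `normalized_count`.
#' @export
count_in_peaks <- function(tags, peaks, extend_to = 200L) {
  stopifnot(is(tags, "TagSet"), is(peaks, "GRanges"))
  frags <- tag_fragments(tags, extend_to)
  raw <- countOverlaps(peaks, frags, ignore.strand = TRUE)
  norm <- if (tags$library_size > 0) raw * 1e7 / tags$library_size
          else rep(0, length(peaks))
  data.frame(chrom = as.character(seqnames(peaks)),
             start = start(peaks) - 1L, end = end(peaks),
             raw_count = as.integer(raw), normalized_count = norm,
             stringsAsFactors = FALSE)
}

#' Per-peak knockdown fold changes with low-count exclusion
#'
#' Counts control and knockdown tags in each peak window, excludes peaks
#' whose combined raw count across the two samples is below `min_tags`,
#' and reports the ratio of normalized (tags per 10 million) counts with a
#' pseudocount.
#'
#' @param ctrl,kd [TagSet]s for the control and knockdown samples.
#' @param peaks A `GRanges`.
#' @param min_tags Combined raw-count exclusion threshold (default 50).
#' @param pseudocount Added to both normalized counts (default 1).
#' @param extend_to Fragment length for counting (default 200).
#' @param classes Optional per-peak labels carried into the table.
#' @return Data frame with one row per retained peak: coordinates, raw and
#'   normalized counts for both samples, `fold_change`
#'   (knockdown / control), `log2_fold_change`, and `class` when given.
#'   Warns and returns zero rows when every peak is excluded.
#' @export
knockdown_foldchange <- function(ctrl, kd, peaks, min_tags = 50L,
                                 pseudocount = 1, extend_to = 200L,
                                 classes = NULL) {
  stopifnot(is(ctrl, "TagSet"), is(kd, "TagSet"))
  cc <- count_in_peaks(ctrl, peaks, extend_to)
  ck <- count_in_peaks(kd, peaks, extend_to)
  df <- data.frame(chrom = cc$chrom, start = cc$start, end = cc$end,
                   ctrl_count = cc$raw_count, kd_count = ck$raw_count,
                   ctrl_norm = cc$normalized_count,
                   kd_norm = ck$normalized_count,
                   stringsAsFactors = FALSE)
  if (!is.null(classes)) df$class <- as.character(classes)
  keep <- df$ctrl_count + df$kd_count >= min_tags
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    warning("all peaks excluded by the ", min_tags, "-tag filter")
    df$fold_change <- numeric(0)
    df$log2_fold_change <- numeric(0)
    return(df)
  }
  df$fold_change <- (df$kd_norm + pseudocount) / (df$ctrl_norm + pseudocount)
  df$log2_fold_change <- log2(df$fold_change)
  rownames(df) <- NULL
  df
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null enumeration for combined sample sizes up to 20 (ties force
#' the approximation), normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (Mann-Whitney U of `group_a`), `p.value`
#'   (two-sided) and `method`.
#' @export
ranksum_test <- function(group_a, group_b) {
  stop_if(length(group_a) == 0 || length(group_b) == 0,
          "both groups must be non-empty")
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  n <- length(group_a) + length(group_b)
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = n <= 20, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before ranking; exact enumeration for up
#' to 20 nonzero differences (ties force the approximation), normal
#' approximation otherwise.
#'
#' @param paired_diffs Numeric vector of paired differences with at least
#'   one nonzero entry.
#' @return List with `statistic` (V), `p.value` (two-sided) and `method`.
#' @export
signedrank_test <- function(paired_diffs) {
  stopifnot(is.numeric(paired_diffs))
  d <- paired_diffs[paired_diffs != 0]
  stop_if(length(d) == 0, "all paired differences are zero")
  res <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = length(d) <= 20, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}
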