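# Classification of consensus peaks: cofactor-overlap combinatorics
# (gypsy-like versus non-gypsy-like), HP1a adjacency (class 1 borders
# versus class 2), signed border offsets, and PWM motif scanning.

.gypsy_core <- c("Su(Hw)", "Mod(mdg4)", "CP190")

#' Label peaks by their combination of overlapping cofactor reference sets
#'
#' A peak carries cofactor `c` iff it overlaps (>= 1 bp) any interval of
#' reference set `c`. The combination label joins the carried cofactors
#' with `;` (`"none"` when empty). A peak is gypsy-like iff it carries all
#' of Su(Hw), Mod(mdg4) and CP190. Combinations with fewer than
#' `min_group_size` members are flagged as below the display threshold but
#' retained in the data.
#'
#' @param peaks A `GRanges`.
#' @param references Named list of reference peak `GRanges`, one per
#'   cofactor.
#' @param min_group_size Display threshold for combination groups
#'   (default 11).
#' @return A list with `labels` (data frame: `combination`, `gypsy_like`,
#'   one logical column per cofactor) and `table` (data frame:
#'   `combination`, `n`, `gypsy_like`, `displayed`, decreasing `n`).
#' @export
cofactor_combinations <- function(peaks, references, min_group_size = 11L) {
  stopifnot(is(peaks, "GRanges"), is.list(references))
  stop_if(length(references) == 0 || is.null(names(references)) ||
            any(!nzchar(names(references))),
          "references must be a non-empty named list of GRanges")
  hit <- vapply(references,
                function(r) overlapsAny(peaks, r, ignore.strand = TRUE),
                logical(length(peaks)))
  if (length(peaks) == 1) hit <- matrix(hit, nrow = 1,
                                        dimnames = list(NULL,
                                                        names(references)))
  combo <- if (length(peaks) == 0) character(0) else
    apply(hit, 1, function(z) {
      if (!any(z)) "none" else paste(names(references)[z], collapse = ";")
    })
  core_present <- .gypsy_core %in% names(references)
  gypsy <- if (all(core_present) && length(peaks) > 0)
    rowSums(hit[, .gypsy_core, drop = FALSE]) == 3L
  else rep(FALSE, length(peaks))
  labels <- data.frame(combination = combo, gypsy_like = gypsy,
                       stringsAsFactors = FALSE)
  for (nm in names(references)) labels[[nm]] <- hit[, nm]
  tab <- as.data.frame(table(combination = combo),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab <- tab[order(-tab$n, tab$combination), , drop = FALSE]
  tab$gypsy_like <- vapply(strsplit(tab$combination, ";"),
                           function(cf) all(.gypsy_core %in% cf), logical(1))
  tab$displayed <- tab$n >= min_group_size
  rownames(tab) <- NULL
  list(labels = labels, table = tab)
}

#' Classify peaks by adjacency to HP1a domains
#'
#' A peak is class 1 iff it overlaps a domain or its center lies within
#' `proximity_window` bp of a domain edge; otherwise class 2. Domains must
#' be non-overlapping (merge first with `reduce()`).
#'
#' @param peaks A `GRanges`.
#' @param hp1a_domains Non-overlapping `GRanges` of heterochromatin
#'   domains.
#' @param proximity_window Distance window in bp (default 1000).
#' @return Factor of `"class1"`/`"class2"`, one level per peak.
#' @export
classify_hp1a_adjacency <- function(peaks, hp1a_domains,
                                    proximity_window = 1000L) {
  stopifnot(is(peaks, "GRanges"), is(hp1a_domains, "GRanges"))
  stop_if(length(hp1a_domains) > 1 &&
            any(countOverlaps(hp1a_domains, hp1a_domains,
                              ignore.strand = TRUE) > 1),
          "hp1a domains overlap; merge them first (reduce)")
  cls <- rep("class2", length(peaks))
  if (length(hp1a_domains) > 0 && length(peaks) > 0) {
    ov <- overlapsAny(peaks, hp1a_domains, ignore.strand = TRUE)
    ctr <- GRanges(seqnames(peaks),
                   IRanges(floor(interval_center0(peaks)) + 1L, width = 1L))
    dn <- distanceToNearest(ctr, granges(hp1a_domains),
                            ignore.strand = TRUE)
    near <- rep(FALSE, length(peaks))
    near[queryHits(dn)] <- mcols(dn)$distance <= proximity_window
    cls[ov | near] <- "class1"
  }
  factor(cls, levels = c("class1", "class2"))
}

#' Signed offset from peak centers to the nearest domain edge
#'
#' The distance (bp) from each peak center to the nearest edge of any
#' domain on the same chromosome, negative when the center lies inside a
#' domain and positive outside; `NA` when no domain shares the chromosome.
#' Arithmetic follows the 0-based half-open convention of the reported
#' coordinates.
#'
#' @param peaks A `GRanges`.
#' @param domains A `GRanges` of domains.
#' @return Numeric vector of signed offsets (bp).
#' @export
border_offset <- function(peaks, domains) {
  stopifnot(is(peaks, "GRanges"), is(domains, "GRanges"))
  ctr <- interval_center0(peaks)
  pchr <- as.character(seqnames(peaks))
  dchr <- as.character(seqnames(domains))
  d0s <- start(domains) - 1
  d0e <- end(domains)
  vapply(seq_along(peaks), function(i) {
    j <- which(dchr == pchr[i])
    if (!length(j)) return(NA_real_)
    edges <- c(d0s[j], d0e[j])
    d <- min(abs(ctr[i] - edges))
    inside <- any(d0s[j] < ctr[i] & ctr[i] < d0e[j])
    if (inside) -d else d
  }, numeric(1))
}

#' Scan peak sequences for PWM motif occurrences
#'
#' Log2-odds scores are computed at every offset on both strands of each
#' peak sequence; a peak is a hit iff some offset scores at least
#' `score_fraction` of the maximum attainable score.
#'
#' @param peaks A `GRanges` within the bounds of `genome_sequence`.
#' @param genome_sequence A named `DNAStringSet` (one entry per
#'   chromosome).
#' @param pwm A [pwm()] object.
#' @param score_fraction Hit threshold as a fraction of the maximum score
#'   (default 0.8).
#' @return A list with `hit` (logical per peak) and `fraction` (share of
#'   peaks with >= 1 hit).
#' @export
scan_motif <- function(peaks, genome_sequence, pwm, score_fraction = 0.8) {
  stopifnot(is(peaks, "GRanges"), is(genome_sequence, "DNAStringSet"),
            is(pwm, "PWM"))
  chr <- as.character(seqnames(peaks))
  stop_if(!all(chr %in% names(genome_sequence)),
          "peak chromosome(s) missing from the sequence set")
  lens <- setNames(width(genome_sequence), names(genome_sequence))
  stop_if(length(peaks) > 0 &&
            any(start(peaks) < 1 | end(peaks) > lens[chr]),
          "peak(s) outside sequence bounds")
  lo <- pwm_log_odds(pwm)
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(lo_rc) <- rownames(lo)
  thr <- score_fraction * pwm_max_score(pwm)
  hit <- vapply(seq_along(peaks), function(i) {
    if (width(peaks)[i] < ncol(lo)) return(FALSE)
    s <- subseq(genome_sequence[[chr[i]]], start(peaks)[i], end(peaks)[i])
    countPWM(lo, s, min.score = thr) > 0 ||
      countPWM(lo_rc, s, min.score = thr) > 0
  }, logical(1))
  list(hit = hit,
       fraction = if (length(hit)) mean(hit) else NA_real_)
}

#' Full per-peak classification table
#'
#' Convenience wrapper combining [cofactor_combinations()],
#' [classify_hp1a_adjacency()], [border_offset()] and (when a sequence and
#' PWM are given) [scan_motif()] into one data frame mirroring a
#' supplementary peak table: position, cofactor combination, gypsy-like
#' flag, HP1a class, border offset and motif hit.
#'
#' @param peaks A `GRanges` of consensus peaks.
#' @param references Named list of cofactor reference `GRanges`.
#' @param hp1a_domains `GRanges` of HP1a domains.
#' @param genome_sequence Optional `DNAStringSet`.
#' @param pwm Optional [pwm()].
#' @param proximity_window Passed to [classify_hp1a_adjacency()].
#' @param min_group_size Passed to [cofactor_combinations()].
#' @param score_fraction Passed to [scan_motif()].
#' @return A list with `peaks` (data frame, one row per peak) and
#'   `combination_table`.
#' @export
classify_peaks <- function(peaks, references, hp1a_domains,
                           genome_sequence = NULL, pwm = NULL,
                           proximity_window = 1000L, min_group_size = 11L,
                           score_fraction = 0.8) {
  cc <- cofactor_combinations(peaks, references, min_group_size)
  cls <- classify_hp1a_adjacency(peaks, hp1a_domains, proximity_window)
  off <- border_offset(peaks, hp1a_domains)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   combination = cc$labels$combination,
                   gypsy_like = cc$labels$gypsy_like,
                   hp1a_class = as.character(cls),
                   border_offset = off,
                   stringsAsFactors = FALSE)
  if (!is.null(genome_sequence) && !is.null(pwm)) {
    df$motif_hit <- scan_motif(peaks, genome_sequence, pwm,
                               score_fraction)$hit
  }
  list(peaks = df, combination_table = cc$table)
}
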