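# Fixed-width peak calling against an input control, broad-domain
# segmentation and replicate-consensus selection. Tag 5' positions are
# shifted by half a fragment to estimated fragment midpoints before any
# window counting, so that candidate windows center on binding sites.

#' Parameters for fixed-width peak calling
#'
#' @param peak_width Width of every called peak in bp (default 200).
#' @param min_fold_over_input Minimum library-size-normalized IP/input fold
#'   in the candidate window (default 4).
#' @param poisson_alpha Upper-tail Poisson probability threshold for the IP
#'   count given the input-derived expectation (default 1e-4).
#' @param min_tags Minimum IP tags in the window (default 10).
#' @param merge_distance Candidate windows closer than this are resolved by
#'   keeping the higher-count one (default `peak_width`).
#' @param fragment_length Fragment size used to shift 5' tag positions to
#'   midpoints before counting (default 200).
#' @return An object of class `PeakCallParams`.
#' @export
peak_call_params <- function(peak_width = 200L, min_fold_over_input = 4,
                             poisson_alpha = 1e-4, min_tags = 10L,
                             merge_distance = peak_width,
                             fragment_length = 200L) {
  stop_if(peak_width <= 0, "peak_width must be > 0")
  stop_if(min_fold_over_input < 1, "min_fold_over_input must be >= 1")
  structure(list(peak_width = as.integer(peak_width),
                 min_fold_over_input = min_fold_over_input,
                 poisson_alpha = poisson_alpha,
                 min_tags = as.integer(min_tags),
                 merge_distance = as.integer(merge_distance),
                 fragment_length = as.integer(fragment_length)),
            class = "PeakCallParams")
}

#' Parameters for broad-domain calling
#'
#' @param window Sliding-window size in bp (default 5000).
#' @param step Step between window starts in bp (default 500).
#' @param min_fold Minimum normalized IP/input fold per window (default 2).
#' @param max_gap Passing windows closer than this are merged (default
#'   2500).
#' @param min_domain_length Domains shorter than this are discarded
#'   (default 10000).
#' @return An object of class `DomainCallParams`.
#' @export
domain_call_params <- function(window = 5000L, step = 500L, min_fold = 2,
                               max_gap = 2500L, min_domain_length = 10000L) {
  stop_if(window < step, "window must be >= step")
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_fold = min_fold, max_gap = as.integer(max_gap),
                 min_domain_length = as.integer(min_domain_length)),
            class = "DomainCallParams")
}

# strand-aware shift of 5' positions to estimated fragment midpoints
.tag_midpoints <- function(tags, fragment_length, genome) {
  gr <- tags$tags
  f2 <- fragment_length %/% 2
  pos <- ifelse(as.character(strand(gr)) == "+", start(gr) + f2,
                start(gr) - f2)
  lens <- seqlengths(genome)
  chr <- as.character(seqnames(gr))
  pos <- pmax(1L, pmin(as.integer(lens[chr]), as.integer(pos)))
  split(pos, chr)
}

# every distinct count value of windows [s, s + width - 1] over a point set
# is attained at one of these starts; the leftmost integer start attaining
# the maximum is among them
.window_candidates <- function(pos, width, chrom_len) {
  if (length(pos) == 0)
    return(data.frame(start = integer(0), count = integer(0)))
  pos <- sort(pos)
  s <- unique(sort(c(1L, pos - as.integer(width) + 1L, pos + 1L)))
  s <- s[s >= 1L & s <= chrom_len - width + 1L]
  cnt <- findInterval(s + width - 1 + 0.5, pos) - findInterval(s - 0.5, pos)
  data.frame(start = s, count = cnt)
}

.count_in_windows <- function(starts, width, pos) {
  pos <- sort(pos)
  findInterval(starts + width - 1 + 0.5, pos) - findInterval(starts - 0.5, pos)
}

# greedy resolution: accept by decreasing count (ties: leftmost), reject
# candidates whose window lies within merge_distance of an accepted one
.greedy_select <- function(starts, counts, width, merge_distance) {
  ord <- order(-counts, starts)
  acc <- integer(0)
  lim <- width + merge_distance
  for (i in ord) {
    s <- starts[i]
    if (!length(acc) || all(abs(acc - s) >= lim)) acc <- c(acc, s)
  }
  sort(acc)
}

#' Call fixed-width peaks from IP and input tag sets
#'
#' Candidate windows of exactly `peak_width` are centered on local maxima
#' of midpoint-shifted tag density; a candidate is retained iff its IP tag
#' count is at least `min_tags`, its library-size-normalized fold over the
#' input expectation is at least `min_fold_over_input`, and the Poisson
#' upper-tail probability of the IP count given the input-derived
#' expectation is at most `poisson_alpha`. The input expectation is the
#' local input count scaled to the IP library, floored at the uniform
#' genome-wide expectation. Overlapping or nearby candidates (within
#' `merge_distance`) are resolved by keeping the higher-count window,
#' leftmost on ties.
#'
#' @param ip,input [TagSet]s (input library must be non-empty; an empty IP
#'   yields an empty peak list).
#' @param genome A `Seqinfo`.
#' @param params A [peak_call_params()].
#' @return A sorted `GRanges` of peaks, all of width `peak_width`, with
#'   mcols `score` (IP tags per 10 million), `count`, `input_count`,
#'   `fold`, `pval`.
#' @export
call_fixed_width_peaks <- function(ip, input, genome,
                                   params = peak_call_params()) {
  stopifnot(is(ip, "TagSet"), is(input, "TagSet"), is(genome, "Seqinfo"),
            is(params, "PeakCallParams"))
  w <- params$peak_width
  stop_if(any(seqlengths(genome) < w),
          "peak_width exceeds a chromosome length")
  stop_if(input$library_size == 0, "input library is empty")
  empty <- GRanges(seqinfo = genome)
  mcols(empty) <- DataFrame(score = numeric(0), count = integer(0),
                            input_count = integer(0), fold = numeric(0),
                            pval = numeric(0))
  if (ip$library_size == 0) return(empty)

  glen <- genome_size(genome)
  mid_ip <- .tag_midpoints(ip, params$fragment_length, genome)
  mid_in <- .tag_midpoints(input, params$fragment_length, genome)
  lib_ratio <- ip$library_size / input$library_size
  floor_in <- as.numeric(input$library_size) * w / glen

  out <- list()
  for (chr in names(mid_ip)) {
    L <- seqlengths(genome)[[chr]]
    cand <- .window_candidates(mid_ip[[chr]], w, L)
    cand <- cand[cand$count >= params$min_tags, , drop = FALSE]
    if (nrow(cand) == 0) next
    icnt <- .count_in_windows(cand$start, w, mid_in[[chr]] %||% integer(0))
    lambda <- pmax(icnt, floor_in) * lib_ratio
    fold <- cand$count / lambda
    pval <- ppois(cand$count - 1, lambda, lower.tail = FALSE)
    keep <- fold >= params$min_fold_over_input & pval <= params$poisson_alpha
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    icnt <- icnt[keep]; fold <- fold[keep]; pval <- pval[keep]
    sel <- .greedy_select(cand$start, cand$count, w, params$merge_distance)
    idx <- match(sel, cand$start)
    gr <- GRanges(chr, IRanges(sel, width = w), seqinfo = genome)
    mcols(gr) <- DataFrame(score = cand$count[idx] * 1e7 / ip$library_size,
                           count = cand$count[idx],
                           input_count = icnt[idx],
                           fold = fold[idx], pval = pval[idx])
    out[[chr]] <- gr
  }
  if (!length(out)) return(empty)
  sort(do.call(c, unname(out)))
}

#' Call broad enriched domains (HP1a-type) from IP and input tag sets
#'
#' Sliding windows of `window` bp every `step` bp are scored by
#' library-size-normalized IP/input fold (input floored at its uniform
#' expectation). The center `step`-slice of every passing window is kept;
#' slices separated by gaps of at most `max_gap` are merged and domains
#' shorter than `min_domain_length` are discarded. Center-slice
#' segmentation keeps boundary overshoot well below the window size.
#'
#' @param ip,input [TagSet]s.
#' @param genome A `Seqinfo`.
#' @param params A [domain_call_params()].
#' @param fragment_length Fragment size for the midpoint shift.
#' @return A sorted `GRanges` of domains.
#' @export
call_domains <- function(ip, input, genome, params = domain_call_params(),
                         fragment_length = 200L) {
  stopifnot(is(ip, "TagSet"), is(input, "TagSet"), is(genome, "Seqinfo"),
            is(params, "DomainCallParams"))
  stop_if(input$library_size == 0, "input library is empty")
  if (ip$library_size == 0) return(GRanges(seqinfo = genome))
  w <- params$window
  glen <- genome_size(genome)
  mid_ip <- .tag_midpoints(ip, fragment_length, genome)
  mid_in <- .tag_midpoints(input, fragment_length, genome)
  lib_ratio <- ip$library_size / input$library_size
  floor_in <- as.numeric(input$library_size) * w / glen
  slices <- list()
  for (chr in names(mid_ip)) {
    L <- seqlengths(genome)[[chr]]
    if (L < w) next
    starts <- seq(1L, L - w + 1L, by = params$step)
    cnt <- .count_in_windows(starts, w, mid_ip[[chr]])
    icnt <- .count_in_windows(starts, w, mid_in[[chr]] %||% integer(0))
    fold <- cnt / (pmax(icnt, floor_in) * lib_ratio)
    keep <- which(fold >= params$min_fold)
    if (!length(keep)) next
    ctr <- starts[keep] + w %/% 2
    half <- params$step / 2
    slices[[chr]] <- GRanges(chr, IRanges(
      pmax(1, floor(ctr - half)), pmin(L, ceiling(ctr + half - 1))),
      seqinfo = genome)
  }
  if (!length(slices)) return(GRanges(seqinfo = genome))
  dom <- reduce(do.call(c, unname(slices)),
                min.gapwidth = params$max_gap + 1L)
  sort(dom[width(dom) >= params$min_domain_length])
}

#' Select consensus peaks supported by multiple replicates
#'
#' A peak is supported by a replicate iff it overlaps (>= 1 bp) a peak in
#' that replicate (its own replicate always supports it). Peaks with
#' support below `min_support` are dropped; each group of mutually
#' overlapping supported peaks is represented by one interval of width
#' `peak_width` centered on the count-weighted mean center (weights from
#' the `count` or `score` mcol when present, otherwise 1).
#'
#' @param replicates List of peak `GRanges` (one per biological replicate).
#' @param min_support Minimum number of supporting replicates (default 2,
#'   i.e. "2 of 3").
#' @param peak_width Width of representative peaks; defaults to the median
#'   width of the supported peaks.
#' @return A sorted `GRanges` with mcols `support` (maximum support in the
#'   group) and `n_members`.
#' @export
consensus_peaks <- function(replicates, min_support = 2L,
                            peak_width = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 1,
            all(vapply(replicates, is, logical(1), "GRanges")))
  stop_if(min_support > length(replicates),
          "min_support exceeds the number of replicates")
  supp_of <- function(gr) {
    hits <- vapply(replicates,
                   function(r) overlapsAny(gr, r, ignore.strand = TRUE),
                   logical(length(gr)))
    rowSums(matrix(hits, nrow = length(gr)))
  }
  peaks <- lapply(replicates, function(gr) {
    if (length(gr) == 0) {
      mcols(gr)$.support <- integer(0)
    } else {
      mcols(gr)$.support <- as.integer(supp_of(gr))
    }
    gr
  })
  all <- do.call(c, lapply(peaks, function(gr) {
    g2 <- granges(gr)
    mcols(g2)$.support <- gr$.support
    wcol <- if ("count" %in% names(mcols(gr))) gr$count
            else if ("score" %in% names(mcols(gr))) gr$score
            else rep(1, length(gr))
    mcols(g2)$.weight <- as.numeric(wcol)
    g2
  }))
  sup <- all[all$.support >= min_support]
  if (length(sup) == 0) {
    out <- GRanges()
    mcols(out) <- DataFrame(support = integer(0), n_members = integer(0))
    return(out)
  }
  peak_width <- as.integer(peak_width %||% median(width(sup)))
  red <- reduce(sup, min.gapwidth = 0L, ignore.strand = TRUE)
  grp <- subjectHits(findOverlaps(sup, red, ignore.strand = TRUE))
  ctr <- interval_center0(sup)
  wctr <- vapply(split(seq_along(sup), grp), function(ii)
    sum(ctr[ii] * sup$.weight[ii]) / sum(sup$.weight[ii]), numeric(1))
  starts <- pmax(1L, as.integer(round(wctr - (peak_width - 2) / 2)))
  out <- GRanges(seqnames(red), IRanges(starts, width = peak_width),
                 seqinfo = seqinfo(red))
  mcols(out) <- DataFrame(
    support = vapply(split(sup$.support, grp), max, integer(1)),
    n_members = as.integer(table(grp)))
  sort(out)
}
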