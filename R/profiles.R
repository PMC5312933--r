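# Anchor-centered composite profiles and heatmap matrices, peak density
# histograms, and a scaled gene-body metaprofile.

.extract_padded <- function(rle, from, to) {
  n <- length(rle)
  lpad <- max(0L, 1L - from)
  rpad <- max(0L, to - n)
  v <- if (from > n || to < 1) numeric(0)
       else as.numeric(window(rle, max(1L, from), min(n, to)))
  c(numeric(lpad), v, numeric(rpad))
}

.bin_rows <- function(m, bin) {
  nb <- ncol(m) / bin
  grp <- rep(seq_len(nb), each = bin)
  t(rowsum(t(m), grp)) / bin
}

#' Anchor-centered profile matrix and composite
#'
#' Computes, for each anchor, the library-normalized (tags per 10 million)
#' coverage of extended tag fragments in `bin`-bp bins over the window
#' `center +/- flank`, plus the composite (column means). Heatmap export
#' sorts rows by decreasing row sum (see [profile_order()]); rows can be
#' flipped for oriented anchors.
#'
#' @param tags A [TagSet].
#' @param anchors A `GRanges`; each anchor's center is the profile origin.
#' @param flank Half-window in bp (default 2000); must be divisible by
#'   `bin`.
#' @param bin Bin size in bp (default 10).
#' @param extend_to Fragment length for coverage (default 200).
#' @param flip Optional logical per anchor; `TRUE` rows are mirrored
#'   (e.g. to orient class-1 peaks so the HP1a domain lies on one side).
#' @return An object of class `ProfileMatrix`: list with `matrix`
#'   (anchors x bins), `positions` (bin midpoints relative to the anchor
#'   center), `composite` (column means), `flank`, `bin`, `sample_id`.
#' @export
composite_profile <- function(tags, anchors, flank = 2000L, bin = 10L,
                              extend_to = 200L, flip = NULL) {
  stopifnot(is(tags, "TagSet"), is(anchors, "GRanges"))
  stop_if(flank %% bin != 0, "flank must be divisible by bin")
  stop_if(length(anchors) == 0, "no anchors given")
  cov <- coverage(tag_fragments(tags, extend_to))
  ctr <- floor(interval_center0(anchors)) + 1L   # 1-based center position
  chr <- as.character(seqnames(anchors))
  m <- t(vapply(seq_along(anchors), function(i) {
    rle <- if (chr[i] %in% names(cov)) cov[[chr[i]]] else Rle(0L, 0)
    .extract_padded(rle, ctr[i] - flank, ctr[i] + flank - 1L)
  }, numeric(2 * flank)))
  m <- .bin_rows(m, bin) * if (tags$library_size > 0)
    1e7 / tags$library_size else 0
  if (!is.null(flip)) {
    stopifnot(length(flip) == length(anchors))
    m[flip, ] <- m[flip, rev(seq_len(ncol(m))), drop = FALSE]
  }
  structure(list(matrix = m,
                 positions = seq(-flank + bin / 2, flank - bin / 2,
                                 by = bin),
                 composite = colMeans(m),
                 flank = flank, bin = bin,
                 sample_id = tags$sample_id),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat("ProfileMatrix '", x$sample_id, "': ", nrow(x$matrix),
      " anchors x ", ncol(x$matrix), " bins (", x$bin, " bp), flank ",
      x$flank, " bp\n", sep = "")
  invisible(x)
}

#' Heatmap row order of a profile matrix
#'
#' Rows sorted by decreasing total signal ("sorted by intensity"), ties
#' broken by row index (coordinate order).
#'
#' @param pm A [composite_profile()] result.
#' @return Integer permutation of the rows.
#' @export
profile_order <- function(pm) {
  stopifnot(is(pm, "ProfileMatrix"))
  order(-rowSums(pm$matrix), seq_len(nrow(pm$matrix)))
}

#' Full width at half maximum of a composite profile
#'
#' The baseline is the mean of the outer 10% of bins on each side; the
#' half-maximum is halfway between baseline and peak, and the crossings
#' are linearly interpolated.
#'
#' @param pm A [composite_profile()] result (or a list with `composite`
#'   and `positions`).
#' @return Width in bp (`NA` if the profile never drops to half-maximum).
#' @export
profile_fwhm <- function(pm) {
  y <- pm$composite
  x <- pm$positions
  k <- max(1L, floor(length(y) * 0.1))
  base <- mean(c(head(y, k), tail(y, k)))
  imax <- which.max(y)
  half <- base + (y[imax] - base) / 2
  left <- which(y[seq_len(imax)] < half)
  right <- which(y[seq(imax, length(y))] < half) + imax - 1L
  if (!length(left) || !length(right)) return(NA_real_)
  i <- max(left)
  xl <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  j <- min(right)
  xr <- x[j] - (half - y[j]) / (y[j - 1] - y[j]) * (x[j] - x[j - 1])
  unname(xr - xl)
}

#' Histogram of peak density along the genome
#'
#' Counts peak centers per fixed-size genomic bin, optionally per
#' classification class. Bin counts sum to the number of peaks.
#'
#' @param peaks A `GRanges`.
#' @param genome A `Seqinfo`.
#' @param bin Bin size in bp (default 1e5).
#' @param classes Optional per-peak labels; when given, counts are
#'   reported per class.
#' @return Data frame with `chrom`, `bin_start` (0-based), `bin_end`,
#'   `class` (when requested) and `count`, covering every genomic bin.
#' @export
peak_density_histogram <- function(peaks, genome, bin = 100000L,
                                   classes = NULL) {
  stopifnot(is(peaks, "GRanges"), is(genome, "Seqinfo"))
  stop_if(bin <= 0, "bin must be > 0")
  lens <- seqlengths(genome)
  grid <- do.call(rbind, lapply(names(lens), function(chr) {
    s <- seq(0, lens[[chr]] - 1, by = bin)
    data.frame(chrom = chr, bin_start = s,
               bin_end = pmin(s + bin, lens[[chr]]),
               stringsAsFactors = FALSE)
  }))
  ctr <- floor(interval_center0(peaks))
  key <- paste(as.character(seqnames(peaks)), (ctr %/% bin) * bin)
  gkey <- paste(grid$chrom, grid$bin_start)
  cls_levels <- if (is.null(classes)) "all" else
    sort(unique(as.character(classes)))
  cls <- if (is.null(classes)) rep("all", length(peaks))
         else as.character(classes)
  out <- do.call(rbind, lapply(cls_levels, function(cl) {
    g <- grid
    if (!is.null(classes)) g$class <- cl
    tab <- table(factor(key[cls == cl], levels = gkey))
    g$count <- as.integer(tab)
    g
  }))
  rownames(out) <- NULL
  out
}

#' Scaled TSS / gene-body / TTS metaprofile
#'
#' Library-normalized fragment coverage over each gene, with fixed-size
#' flanks and the gene body rescaled to `body_bins` bins; minus-strand
#' genes are mirrored so all rows run TSS to TTS.
#'
#' @param tags A [TagSet].
#' @param genes A `GRanges` with strand.
#' @param flank Flank size in bp on each side (default 500).
#' @param flank_bins Number of bins per flank (default 10).
#' @param body_bins Number of bins for the rescaled gene body
#'   (default 50).
#' @param extend_to Fragment length (default 200).
#' @return List with `matrix` (genes x bins), `composite`, and
#'   `bin_type` (`"flank5"`, `"body"`, `"flank3"` per column).
#' @export
gene_body_profile <- function(tags, genes, flank = 500L, flank_bins = 10L,
                              body_bins = 50L, extend_to = 200L) {
  stopifnot(is(tags, "TagSet"), is(genes, "GRanges"))
  stop_if(flank %% flank_bins != 0, "flank must be divisible by flank_bins")
  cov <- coverage(tag_fragments(tags, extend_to))
  fb <- flank %/% flank_bins
  rows <- lapply(seq_along(genes), function(i) {
    chr <- as.character(seqnames(genes))[i]
    rle <- if (chr %in% names(cov)) cov[[chr]] else Rle(0L, 0)
    v <- .extract_padded(rle, start(genes)[i] - flank,
                         end(genes)[i] + flank)
    if (as.character(strand(genes))[i] == "-") v <- rev(v)
    n <- length(v)
    left <- v[seq_len(flank)]
    body <- v[(flank + 1):(n - flank)]
    right <- v[(n - flank + 1):n]
    grp <- pmin(body_bins,
                floor((seq_along(body) - 1) * body_bins / length(body)) + 1)
    c(as.numeric(rowsum(left, rep(seq_len(flank_bins), each = fb))) / fb,
      as.numeric(rowsum(body, grp) / tabulate(grp, body_bins)),
      as.numeric(rowsum(right, rep(seq_len(flank_bins), each = fb))) / fb)
  })
  m <- do.call(rbind, rows) * if (tags$library_size > 0)
    1e7 / tags$library_size else 0
  list(matrix = m, composite = colMeans(m),
       bin_type = rep(c("flank5", "body", "flank3"),
                      c(flank_bins, body_bins, flank_bins)))
}
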