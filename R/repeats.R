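# Per-repeat-consensus enrichment statistics (RPKM, log2 fold change with
# a display filter) and per-position consensus coverage with a 5'-segment
# enrichment ratio.

#' Per-repeat enrichment table (RPKM and log2 fold change)
#'
#' RPKM is `count * 1e9 / (length * library_size)`. A pseudocount on the
#' RPKM scale (default 0.5 RPKM, i.e. half a read per kb per million
#' reads, added to both sides) guards against zero input counts while
#' keeping the statistic exactly invariant to joint rescaling of counts
#' and library sizes. The `displayed` flag marks repeats at or above
#' `min_fold_display`-fold enrichment, mirroring the display filter of
#' repeat-enrichment scatter plots; the full table is always returned.
#'
#' @param counts Data frame with columns `repeat_id`, `length`,
#'   `ip_count`, `input_count` (unique reads only).
#' @param ip_library,input_library Total mapped reads per library.
#' @param pseudocount Density added on both sides, in RPKM (default 0.5).
#' @param min_fold_display Display threshold in linear fold (default 2,
#'   i.e. `log2fc >= 1`).
#' @return Data frame with `repeat_id`, `length`, `ip_count`,
#'   `input_count`, `ip_rpkm`, `input_rpkm`, `log2fc`, `displayed`.
#' @export
repeat_enrichment <- function(counts, ip_library, input_library,
                              pseudocount = 0.5, min_fold_display = 2) {
  need <- c("repeat_id", "length", "ip_count", "input_count")
  stop_if(!all(need %in% names(counts)),
          "counts needs columns: ", paste(need, collapse = ", "))
  stop_if(anyDuplicated(counts$repeat_id) > 0, "duplicate repeat ids")
  stop_if(any(counts$length <= 0), "repeat lengths must be > 0")
  stop_if(ip_library <= 0 || input_library <= 0,
          "library sizes must be > 0")
  rpkm <- function(n, len, lib) n * 1e9 / (len * lib)
  ip_rpkm <- rpkm(counts$ip_count, counts$length, ip_library)
  input_rpkm <- rpkm(counts$input_count, counts$length, input_library)
  log2fc <- log2((ip_rpkm + pseudocount) / (input_rpkm + pseudocount))
  data.frame(repeat_id = counts$repeat_id, length = counts$length,
             ip_count = counts$ip_count, input_count = counts$input_count,
             ip_rpkm = ip_rpkm, input_rpkm = input_rpkm, log2fc = log2fc,
             displayed = log2fc >= log2(min_fold_display),
             stringsAsFactors = FALSE)
}

#' Binned consensus coverage and 5'-segment enrichment ratio
#'
#' Bins a per-position read count vector along a repeat consensus,
#' normalizes to reads per bp per 10 million library reads, and reports
#' the ratio of mean per-bp density in a stated 5' window to the mean
#' density over the remainder (quantifying 5'-insulator-type
#' localization). A pseudocount density stabilizes the ratio for sparse
#' coverage.
#'
#' @param positional_counts Integer vector of per-position read counts
#'   (length = consensus length).
#' @param library_size Total mapped reads of the library.
#' @param smoothing_bin Bin size in bp (default 25).
#' @param five_prime_window 5' window size in bp; default the first 10%
#'   of the consensus.
#' @param pseudocount Reads spread over the consensus for the ratio
#'   (default 0.5).
#' @return List with `track` (data frame: `bin_start` 0-based, `raw`,
#'   `density`) and `five_prime_ratio`.
#' @export
consensus_coverage <- function(positional_counts, library_size,
                               smoothing_bin = 25L,
                               five_prime_window = NULL,
                               pseudocount = 0.5) {
  L <- length(positional_counts)
  stop_if(L == 0, "zero-length repeat")
  stop_if(library_size <= 0, "library size must be > 0")
  win <- as.integer(five_prime_window %||% max(1, floor(L * 0.1)))
  stop_if(win < 1 || win >= L, "five_prime_window must be in [1, length)")
  grp <- (seq_len(L) - 1L) %/% smoothing_bin
  raw <- as.numeric(rowsum(positional_counts, grp))
  size <- as.numeric(rowsum(rep(1L, L), grp))
  track <- data.frame(bin_start = sort(unique(grp)) * smoothing_bin,
                      raw = raw,
                      density = raw / size * 1e7 / library_size)
  p <- pseudocount / L
  m5 <- mean(positional_counts[seq_len(win)])
  mr <- mean(positional_counts[(win + 1):L])
  list(track = track, five_prime_ratio = (m5 + p) / (mr + p))
}
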