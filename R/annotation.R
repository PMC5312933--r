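# Peak annotation to genomic landmarks with a fixed priority scheme, and
# expression comparisons between classes of bound genes.

#' Annotate peaks to genomic landmarks
#'
#' Each peak's center receives exactly one category with priority
#' `promoter_tss > tts > exon > intron > intergenic`. The promoter window
#' spans `promoter_upstream` bp upstream to `promoter_downstream` bp
#' downstream of the TSS in gene orientation (the TTS window analogously
#' around the transcription end). Genes without exon structure are treated
#' as single-exon spans. The nearest gene minimizes the absolute
#' strand-aware TSS distance (negative upstream of the TSS in gene
#' orientation); peaks on chromosomes without genes stay `intergenic` with
#' no nearest gene.
#'
#' @param peaks A `GRanges`.
#' @param genes A `GRanges` with strand and mcols `gene_id` (and
#'   optionally `tss`; derived from strand otherwise).
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS in bp (defaults 1000 / 100).
#' @param tts_upstream,tts_downstream TTS window in bp (defaults
#'   100 / 1000).
#' @param exons Optional `GRangesList` of exons per gene (same order as
#'   `genes`).
#' @return Data frame with one row per peak: `chrom`, `start` (0-based),
#'   `end`, `category`, `nearest_gene`, `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_upstream = 1000L,
                           promoter_downstream = 100L,
                           tts_upstream = 100L, tts_downstream = 1000L,
                           exons = NULL) {
  stopifnot(is(peaks, "GRanges"), is(genes, "GRanges"))
  cats <- c("promoter_tss", "tts", "exon", "intron", "intergenic")
  out <- data.frame(chrom = as.character(seqnames(peaks)),
                    start = start(peaks) - 1L, end = end(peaks),
                    category = rep("intergenic", length(peaks)),
                    nearest_gene = rep(NA_character_, length(peaks)),
                    tss_distance = rep(NA_real_, length(peaks)),
                    stringsAsFactors = FALSE)
  if (length(genes) == 0) {
    warning("empty gene set: all peaks annotated intergenic")
    out$category <- factor(out$category, levels = cats)
    return(out)
  }
  gstrand <- as.character(strand(genes))
  stop_if(any(!gstrand %in% c("+", "-")), "genes need strand + or -")
  tss <- mcols(genes)$tss %||% ifelse(gstrand == "+", start(genes),
                                      end(genes))
  tts <- ifelse(gstrand == "+", end(genes), start(genes))
  plus <- gstrand == "+"
  win <- function(anchor, up, down) {
    GRanges(seqnames(genes),
            IRanges(ifelse(plus, anchor - up, anchor - down),
                    ifelse(plus, anchor + down, anchor + up)))
  }
  prom <- win(tss, promoter_upstream, promoter_downstream)
  ttsw <- win(tts, tts_upstream, tts_downstream)
  ctr1 <- floor(interval_center0(peaks)) + 1L  # 1-based center position
  ctrgr <- GRanges(seqnames(peaks), IRanges(ctr1, width = 1L))
  in_prom <- overlapsAny(ctrgr, prom, ignore.strand = TRUE)
  in_tts <- overlapsAny(ctrgr, ttsw, ignore.strand = TRUE)
  in_gene <- overlapsAny(ctrgr, genes, ignore.strand = TRUE)
  in_exon <- if (is.null(exons)) in_gene else
    overlapsAny(ctrgr, unlist(exons), ignore.strand = TRUE)
  out$category <- ifelse(in_prom, "promoter_tss",
                  ifelse(in_tts, "tts",
                  ifelse(in_gene & in_exon, "exon",
                  ifelse(in_gene, "intron", "intergenic"))))
  # nearest gene by |strand-aware TSS distance|, same chromosome only
  pchr <- as.character(seqnames(peaks))
  gchr <- as.character(seqnames(genes))
  for (chr in unique(pchr)) {
    gi <- which(gchr == chr)
    if (!length(gi)) next
    pi <- which(pchr == chr)
    o <- order(tss[gi])
    stss <- tss[gi][o]
    idx <- findInterval(ctr1[pi], stss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(stss))
    pick <- ifelse(abs(ctr1[pi] - stss[lo]) <= abs(ctr1[pi] - stss[hi]),
                   lo, hi)
    g <- gi[o][pick]
    out$nearest_gene[pi] <- mcols(genes)$gene_id[g]
    d <- ctr1[pi] - tss[g]
    out$tss_distance[pi] <- ifelse(gstrand[g] == "+", d, -d)
  }
  out$category <- factor(out$category, levels = cats)
  out
}

#' Landmark-category fractions per classification class
#'
#' @param annotation Result of [annotate_peaks()].
#' @param classes Per-peak class labels (same length).
#' @return Data frame with `class`, `category`, `n`, `fraction`; fractions
#'   sum to 1 within each class.
#' @export
annotation_fractions <- function(annotation, classes) {
  stopifnot(nrow(annotation) == length(classes))
  tab <- table(class = as.character(classes),
               category = annotation$category)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  tot <- rowSums(tab)
  df$fraction <- df$n / tot[df$class]
  df[order(df$class, df$category), c("class", "category", "n", "fraction")]
}

.box_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqd <- q[3] - q[1]
  c(median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(x[x >= q[1] - 1.5 * iqd]),
    whisker_high = max(x[x <= q[3] + 1.5 * iqd]))
}

#' Compare expression of class-bound genes against all genes
#'
#' In mode `"levels"` each class's wild-type expression levels are
#' compared with the all-gene distribution by a Wilcoxon signed-rank test
#' of the per-gene differences from the all-gene median (pairing
#' `"median"`) or by an unpaired rank-sum test (pairing `"unpaired"`). In
#' mode `"mutant_log2fc"` per-class mutant log2 fold changes are compared
#' with all analyzed genes by a rank-sum test. Box-plot summaries use
#' whiskers at 1.5 times the interquartile distance.
#'
#' @param bound_genes_by_class Named list mapping class labels to gene id
#'   vectors.
#' @param expression Data frame with `gene_id` plus `wt_level` and/or
#'   `mut_log2fc` (as from [simulate_expression()]).
#' @param mode `"levels"` or `"mutant_log2fc"`.
#' @param pairing `"median"` (signed-rank vs the all-gene median) or
#'   `"unpaired"` (rank-sum), used in mode `"levels"`.
#' @return Data frame with one row per class plus an `all_genes` row:
#'   `class`, `n`, box statistics, `p_value`, `test`.
#' @export
compare_expression <- function(bound_genes_by_class, expression,
                               mode = c("levels", "mutant_log2fc"),
                               pairing = c("median", "unpaired")) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  valcol <- if (mode == "levels") "wt_level" else "mut_log2fc"
  stop_if(!valcol %in% names(expression),
          "expression table lacks column ", valcol)
  allv <- expression[[valcol]]
  rows <- list(data.frame(class = "all_genes", n = length(allv),
                          t(.box_stats(allv)), p_value = NA_real_,
                          test = NA_character_, stringsAsFactors = FALSE))
  for (cl in names(bound_genes_by_class)) {
    ids <- bound_genes_by_class[[cl]]
    v <- allv[match(ids, expression$gene_id)]
    stop_if(length(v) == 0 || all(is.na(v)),
            "class '", cl, "' has no genes resolvable in the expression ",
            "table")
    v <- v[!is.na(v)]
    if (mode == "levels" && pairing == "median") {
      tst <- signedrank_test(v - median(allv))
      method <- "signed-rank vs all-gene median"
    } else {
      tst <- ranksum_test(v, allv)
      method <- "rank-sum vs all genes"
    }
    rows[[cl]] <- data.frame(class = cl, n = length(v), t(.box_stats(v)),
                             p_value = tst$p.value, test = method,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
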