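# Brute-force oracles (plain double loops over extracted base vectors,
# independent of the package's IRanges-based machinery) and small shared
# fixtures.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# plain-vector view of a GRanges for loop-based oracles
gr_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

# 1-based closed interval overlap (>= 1 bp)
oracle_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

oracle_overlaps_any <- function(q, set) {
  qd <- gr_df(q); sd <- gr_df(set)
  if (nrow(sd) == 0) return(rep(FALSE, nrow(qd)))
  vapply(seq_len(nrow(qd)), function(i) {
    any(vapply(seq_len(nrow(sd)), function(j) {
      qd$chrom[i] == sd$chrom[j] &&
        oracle_overlap(qd$start[i], qd$end[i], sd$start[j], sd$end[j])
    }, logical(1)))
  }, logical(1))
}

# exhaustive scan over every window start: max count and leftmost maximizer
oracle_window_max <- function(pos, width, chrom_len) {
  starts <- seq_len(chrom_len - width + 1)
  cnt <- vapply(starts, function(s) sum(pos >= s & pos <= s + width - 1),
                integer(1))
  list(max = max(cnt), leftmost = starts[which.max(cnt)])
}

# replicate support: number of replicate lists in which a peak overlaps
# some peak (its own list included)
oracle_support <- function(replicates) {
  dfs <- lapply(replicates, gr_df)
  lapply(seq_along(dfs), function(r) {
    d <- dfs[[r]]
    vapply(seq_len(nrow(d)), function(i) {
      sum(vapply(dfs, function(d2) {
        any(d2$chrom == d$chrom[i] & d2$start <= d$end[i] &
              d$start[i] <= d2$end)
      }, logical(1)))
    }, integer(1))
  })
}

oracle_combination <- function(peaks, references) {
  pd <- gr_df(peaks)
  rds <- lapply(references, gr_df)
  vapply(seq_len(nrow(pd)), function(i) {
    carried <- names(references)[vapply(rds, function(rd) {
      any(rd$chrom == pd$chrom[i] & rd$start <= pd$end[i] &
            pd$start[i] <= rd$end)
    }, logical(1))]
    if (!length(carried)) "none" else paste(carried, collapse = ";")
  }, character(1))
}

# tag counts per peak: fragment = 5' position extended in strand direction
oracle_count_in_peaks <- function(tags, peaks, extend_to = 200) {
  td <- gr_df(tags$tags)
  pd <- gr_df(peaks)
  fs <- ifelse(td$strand == "+", td$start, td$start - extend_to + 1)
  fe <- ifelse(td$strand == "+", td$start + extend_to - 1, td$start)
  vapply(seq_len(nrow(pd)), function(i) {
    sum(td$chrom == pd$chrom[i] & fs <= pd$end[i] & pd$start[i] <= fe)
  }, integer(1))
}

# per-offset PWM scoring on both strands of a character sequence
oracle_pwm_hit <- function(seq, pw, score_fraction = 0.8) {
  lo <- pwm_log_odds(pw)
  L <- ncol(lo)
  thr <- score_fraction * pwm_max_score(pw)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sc <- function(sub) sum(lo[cbind(match(sub, rownames(lo)), seq_len(L))])
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < L) return(FALSE)
  for (o in seq_len(length(chars) - L + 1)) {
    sub <- chars[o:(o + L - 1)]
    if (sc(sub) >= thr) return(TRUE)
    if (sc(rev(unname(comp[sub]))) >= thr) return(TRUE)
  }
  FALSE
}

# landmark category by peak center with the fixed priority scheme
oracle_annotate <- function(center1, chrom, genes, up = 1000, down = 100,
                            tts_up = 100, tts_down = 1000) {
  gd <- gr_df(genes)
  tss <- ifelse(gd$strand == "+", gd$start, gd$end)
  tts <- ifelse(gd$strand == "+", gd$end, gd$start)
  same <- gd$chrom == chrom
  prom <- same & ifelse(gd$strand == "+",
                        center1 >= tss - up & center1 <= tss + down,
                        center1 >= tss - down & center1 <= tss + up)
  ttsw <- same & ifelse(gd$strand == "+",
                        center1 >= tts - tts_up & center1 <= tts + tts_down,
                        center1 >= tts - tts_down & center1 <= tts + tts_up)
  body <- same & center1 >= gd$start & center1 <= gd$end
  if (any(prom)) "promoter_tss"
  else if (any(ttsw)) "tts"
  else if (any(body)) "exon"
  else "intergenic"
}

# exact two-sided rank-sum p by enumeration of all rank assignments
# (distinct values only), matching wilcox.test's two-sided rule
oracle_ranksum_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  us <- apply(sets, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  if (u > na * nb / 2) {
    min(1, 2 * mean(us >= u))
  } else {
    min(1, 2 * mean(us <= u))
  }
}

# exact two-sided signed-rank p by enumeration of all sign patterns
oracle_signedrank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  v <- sum(r[d > 0])
  if (v > n * (n + 1) / 4) {
    min(1, 2 * mean(vs >= v))
  } else {
    min(1, 2 * mean(vs <= v))
  }
}

# small world shared across unit tests (built lazily, cached)
.fixtures <- new.env(parent = emptyenv())

small_spec <- function(...) {
  args <- list(
    genome = bc_genome(c("chrA", "chrB"), c(300000L, 150000L)),
    n_hp1a_domains = 4, domain_length = c(8000, 12000),
    min_domain_gap = 12000, n_insulator_sites = 12,
    n_border_sites = 8, n_genes = 40, n_tags = 80000,
    insulator_domain_clearance = 6000, edge_margin = 3000,
    seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

small_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$world <- build_world(small_spec())
  }
  .fixtures$world
}

random_intervals <- function(n, chrom = "chrA", max_pos = 10000,
                             width_range = c(20, 200)) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  GRanges(chrom, IRanges(s, width = w))
}
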