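# Truth-tracked generator for a toy genome with HP1a-type heterochromatin
# domains, insulator sites of defined cofactor composition (with planted
# motif instances), heterochromatin-border sites paired with active genes,
# a repeat-consensus library, and fragment-based ChIP/input/knockdown tag
# sampling. Every placement is recorded so downstream stages can be tested
# by parameter recovery.

#' Default repeat-consensus library
#'
#' A deterministic library of named consensus elements: two gypsy-type
#' retrotransposons carrying concentrated 5' enrichment (emulating the
#' gypsy 5' insulator), three unenriched named elements, and 45 generic
#' unenriched elements. `fold` is the true IP/input enrichment.
#'
#' @return A data frame with columns `repeat_id`, `length`, `copies`,
#'   `fold`, `five_prime_enriched`.
#' @export
default_repeat_library <- function() {
  named <- data.frame(
    repeat_id = c("gypsy", "gtwin", "DMRT1A", "DMRT1B", "DMSAT6"),
    length = c(7469L, 7411L, 5443L, 3806L, 1688L),
    copies = c(20L, 12L, 30L, 25L, 60L),
    fold = c(8, 6, 1, 1, 1),
    five_prime_enriched = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  generic <- data.frame(
    repeat_id = sprintf("TE%03d", 1:45),
    length = as.integer(800 + (1:45) * 137),
    copies = 10L,
    fold = 1,
    five_prime_enriched = FALSE,
    stringsAsFactors = FALSE)
  rbind(named, generic)
}

#' Specify a simulated ChIP-seq study
#'
#' Collects every tunable of the synthetic world: the genome, the number
#' and geometry of HP1a domains, insulator sites with their
#' cofactor-composition fractions, heterochromatin-border sites paired
#' with active genes, the repeat library, and the tag-sampling model
#' (fragment length, enrichment folds, background rate, per-sample totals,
#' knockdown scaling, nucleosome depletion). Defaults describe a 2 Mb
#' three-chromosome genome with 100 planted sites at 10-fold enrichment
#' and 5e5 tags per sample.
#'
#' @param genome A `Seqinfo` (see [bc_genome()]).
#' @param n_hp1a_domains Number of broad heterochromatin domains.
#' @param domain_length Length range (bp) for domains.
#' @param min_domain_gap Minimum gap between domains (bp).
#' @param n_insulator_sites Number of insulator sites (away from domains).
#' @param cofactor_fractions Named fractions over cofactor subsets
#'   (names are `;`-separated cofactor lists); must sum to 1. Counts per
#'   subset use largest-remainder rounding.
#' @param n_border_sites Number of border (class-1-like) sites, each
#'   adjacent to a domain edge and paired with a gene TSS; at most two per
#'   domain (one per edge).
#' @param site_width Width of every planted site (bp).
#' @param n_genes Total genes (border-paired genes included).
#' @param gene_length Length range (bp) for genes.
#' @param repeat_library Data frame as [default_repeat_library()].
#' @param fragment_length Average sheared-chromatin fragment size in bp
#'   (200, matching single-end 50 bp sequencing of 200 bp fragments).
#' @param enrichment_fold Named fold enrichments per site class
#'   (`gypsy_like`, `border`, `other`); all >= 1.
#' @param background_rate Relative background tag weight per bp.
#' @param n_tags Tags per sample.
#' @param knockdown_scaling Factor in (0, 1] applied to site enrichment in
#'   the `ip_knockdown` sample.
#' @param knockdown_classes Site classes affected by the knockdown
#'   (all three for a direct HMR-type knockdown; `"gypsy_like"` alone for a
#'   CP190-type knockdown that spares border sites).
#' @param h3_depletion Factor in (0, 1] multiplying nucleosome (H3) signal
#'   inside planted sites; 1 disables the depletion.
#' @param h3_depleted_classes Site classes carrying the H3 depletion.
#' @param hp1a_fold Broad enrichment fold of the `hp1a` sample over its
#'   domains.
#' @param repeat_read_rate Reads per bp per copy for repeat counts.
#' @param insulator_domain_clearance Minimum distance (bp) between an
#'   insulator site and any domain (keeps the class-2 assignment
#'   unambiguous).
#' @param border_edge_offset Range (bp) between a domain edge and the start
#'   of its border site, on the non-domain side.
#' @param border_tss_offset Range (bp) between a border-site center and its
#'   paired TSS, further from the domain.
#' @param edge_margin Margin (bp) kept free at chromosome ends.
#' @param motif PWM planted (as its consensus) at insulator-site centers.
#' @param seed Master seed; per-sample seeds derive via [child_seed()].
#' @return A validated object of class `SimulationSpec` (a list).
#' @export
simulation_spec <- function(
    genome = bc_genome(c("chr2L", "chr2R", "chr4"),
                       c(800000L, 800000L, 400000L)),
    n_hp1a_domains = 20,
    domain_length = c(10000, 25000),
    min_domain_gap = 15000,
    n_insulator_sites = 60,
    cofactor_fractions = c("Su(Hw);Mod(mdg4);CP190" = 0.6,
                           "Su(Hw);Mod(mdg4);CP190;CTCF" = 0.1,
                           "BEAF-32" = 0.1,
                           "CP190;BEAF-32" = 0.1,
                           "Su(Hw)" = 0.1),
    n_border_sites = 40,
    site_width = 200L,
    n_genes = 200,
    gene_length = c(1500, 4000),
    repeat_library = default_repeat_library(),
    fragment_length = 200L,
    enrichment_fold = c(gypsy_like = 10, border = 10, other = 10),
    background_rate = 0.2,
    n_tags = 5e5,
    knockdown_scaling = 0.5,
    knockdown_classes = c("gypsy_like", "border", "other"),
    h3_depletion = 0.3,
    h3_depleted_classes = c("gypsy_like", "border", "other"),
    hp1a_fold = 10,
    repeat_read_rate = 0.05,
    insulator_domain_clearance = 10000,
    border_edge_offset = c(100, 300),
    border_tss_offset = c(100, 300),
    edge_margin = 5000,
    motif = consensus_pwm("ATTGCATACTTT"),
    seed = 1L) {
  spec <- structure(as.list(environment()), class = "SimulationSpec")
  stop_if(abs(sum(cofactor_fractions) - 1) > 1e-8,
          "cofactor_fractions must sum to 1")
  stop_if(any(enrichment_fold < 1), "enrichment_fold must be >= 1")
  stop_if(!all(c("gypsy_like", "border", "other") %in%
                 names(enrichment_fold)),
          "enrichment_fold needs entries gypsy_like, border, other")
  stop_if(knockdown_scaling <= 0 || knockdown_scaling > 1,
          "knockdown_scaling must be in (0, 1]")
  stop_if(h3_depletion <= 0 || h3_depletion > 1,
          "h3_depletion must be in (0, 1]")
  stop_if(n_border_sites > 2 * n_hp1a_domains,
          "n_border_sites exceeds available domain edges (2 per domain)")
  stop_if(fragment_length < 2, "fragment_length must be >= 2 bp")
  placed <- n_hp1a_domains * (max(domain_length) + min_domain_gap) +
    n_insulator_sites * (site_width + 2 * insulator_domain_clearance / 10)
  stop_if(placed >= genome_size(genome),
          "infeasible placement: requested features exceed genome length")
  spec
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat("SimulationSpec:", genome_size(x$genome) / 1e6, "Mb genome,",
      x$n_hp1a_domains, "HP1a domains,", x$n_insulator_sites,
      "insulator +", x$n_border_sites, "border sites,",
      x$n_genes, "genes,", format(x$n_tags, big.mark = ","),
      "tags/sample, seed", x$seed, "\n")
  invisible(x)
}

.place_intervals <- function(genome, widths, min_gap, margin,
                             occupied = GRanges(), max_tries = 2000) {
  lens <- seqlengths(genome)
  out <- occupied
  new <- GRanges(seqinfo = genome)
  for (w in widths) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(names(lens), 1, prob = as.numeric(lens))
      hi <- lens[[chr]] - margin - w
      if (hi <= margin + 1) next
      s <- floor(runif(1, margin + 1, hi))
      cand <- GRanges(chr, IRanges(s, width = w), seqinfo = genome)
      grown <- GRanges(chr, IRanges(max(1, s - min_gap),
                                    min(lens[[chr]], s + w - 1 + min_gap)))
      if (!overlapsAny(grown, out, ignore.strand = TRUE)) {
        out <- c(out, cand)
        new <- c(new, cand)
        ok <- TRUE
        break
      }
    }
    stop_if(!ok, "infeasible placement after ", max_tries,
            " retries; reduce feature count or genome occupancy")
  }
  new
}

#' Build the synthetic world
#'
#' Places HP1a domains, border sites (one per sampled domain edge, within
#' `border_edge_offset` of the edge on the non-domain side, each paired
#' with an active gene whose TSS lies just beyond the site), insulator
#' sites of the requested cofactor composition away from all domains, and
#' the remaining genes; optionally generates the genome sequence with the
#' motif consensus planted at every insulator-site center. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param sequence Generate the genome FASTA sequence (set `FALSE` for
#'   large tag-only worlds).
#' @return An object of class `bc_world`: a list with `spec`, `genome`,
#'   `sequence` (`DNAStringSet` or `NULL`), `sites` (GRanges with mcols
#'   `site_id`, `site_class`, `cofactors`, `enrichment_fold`,
#'   `domain_side`), `domains`, `genes` (GRanges with `gene_id`, `tss`,
#'   `expression_class`, `bound_site`), `cofactor_refs` (named list of
#'   GRanges reference peak sets) and `repeat_truth`.
#' @export
build_world <- function(spec, sequence = TRUE) {
  stopifnot(is(spec, "SimulationSpec"))
  set.seed(child_seed(spec$seed, "world"))
  genome <- spec$genome
  lens <- seqlengths(genome)

  dom_w <- round(runif(spec$n_hp1a_domains, spec$domain_length[1],
                       spec$domain_length[2]))
  domains <- .place_intervals(genome, dom_w, spec$min_domain_gap,
                              margin = spec$edge_margin +
                                spec$insulator_domain_clearance)
  domains <- sort(domains)

  # border sites: sample edges (2 per domain) without replacement
  edges <- data.frame(dom = rep(seq_along(domains), 2),
                      side = rep(c("left", "right"),
                                 each = length(domains)),
                      stringsAsFactors = FALSE)
  pick <- if (spec$n_border_sites > 0)
    edges[sample(nrow(edges), spec$n_border_sites), , drop = FALSE]
  else edges[integer(0), , drop = FALSE]
  w <- spec$site_width
  bs <- vector("list", nrow(pick))
  bgenes <- vector("list", nrow(pick))
  glen_rng <- spec$gene_length
  for (i in seq_len(nrow(pick))) {
    d <- domains[pick$dom[i]]
    off <- round(runif(1, spec$border_edge_offset[1],
                       spec$border_edge_offset[2]))
    toff <- round(runif(1, spec$border_tss_offset[1],
                        spec$border_tss_offset[2]))
    glen <- round(runif(1, glen_rng[1], glen_rng[2]))
    chr <- as.character(seqnames(d))
    if (pick$side[i] == "right") {
      s <- end(d) + off
      site <- GRanges(chr, IRanges(s, width = w), seqinfo = genome)
      cpos <- (s + s + w - 1) %/% 2
      tss <- cpos + toff
      gene <- GRanges(chr, IRanges(tss, width = glen), strand = "+",
                      seqinfo = genome)
      side <- "left"     # the domain lies left of the site
    } else {
      e <- start(d) - off
      site <- GRanges(chr, IRanges(e - w + 1, width = w), seqinfo = genome)
      cpos <- (e - w + 1 + e) %/% 2
      tss <- cpos - toff
      gene <- GRanges(chr, IRanges(tss - glen + 1, width = glen),
                      strand = "-", seqinfo = genome)
      side <- "right"
    }
    mcols(site)$domain_side <- side
    bs[[i]] <- site
    bgenes[[i]] <- gene
  }
  border_sites <- if (length(bs)) do.call(c, bs) else GRanges(seqinfo = genome)
  border_genes <- if (length(bgenes)) do.call(c, bgenes) else
    GRanges(seqinfo = genome)

  # insulator sites: clear of domains and of each other
  grown_dom <- domains + spec$insulator_domain_clearance
  occupied <- c(granges(grown_dom), granges(border_sites) + 2000)
  ins_sites <- .place_intervals(genome, rep(w, spec$n_insulator_sites),
                                min_gap = 2000, margin = spec$edge_margin,
                                occupied = occupied)

  combos <- rep(names(spec$cofactor_fractions),
                largest_remainder(spec$cofactor_fractions,
                                  spec$n_insulator_sites))
  gypsy_core <- c("Su(Hw)", "Mod(mdg4)", "CP190")
  is_gypsy <- vapply(strsplit(combos, ";"),
                     function(cf) all(gypsy_core %in% cf), logical(1))

  sites <- c(ins_sites, granges(border_sites))
  cls <- c(ifelse(is_gypsy, "gypsy_like", "other"),
           rep("border", length(border_sites)))
  cof <- c(combos, rep("BEAF-32", length(border_sites)))
  mcols(sites)$site_id <- sprintf("site_%03d", seq_along(sites))
  mcols(sites)$site_class <- cls
  mcols(sites)$cofactors <- cof
  mcols(sites)$enrichment_fold <- unname(spec$enrichment_fold[cls])
  mcols(sites)$domain_side <- c(rep(NA_character_, length(ins_sites)),
                                border_sites$domain_side)

  cof_names <- unique(unlist(strsplit(cof, ";")))
  cofactor_refs <- lapply(setNames(cof_names, cof_names), function(nm) {
    granges(sites[vapply(strsplit(cof, ";"), function(x) nm %in% x,
                         logical(1))])
  })

  # remaining genes, placed freely
  n_free <- spec$n_genes - length(border_genes)
  stop_if(n_free < 0, "n_genes smaller than n_border_sites")
  free_genes <- GRanges(seqinfo = genome)
  if (n_free > 0) {
    glen <- round(runif(n_free, glen_rng[1], glen_rng[2]))
    chr <- sample(names(lens), n_free, replace = TRUE,
                  prob = as.numeric(lens))
    s <- floor(runif(n_free, 2000, lens[chr] - 2000 - glen))
    free_genes <- GRanges(chr, IRanges(s, width = glen),
                          strand = sample(c("+", "-"), n_free, TRUE),
                          seqinfo = genome)
  }
  genes <- c(granges(border_genes, use.mcols = FALSE), free_genes)
  strand(genes)[seq_along(border_genes)] <- strand(border_genes)
  mcols(genes)$gene_id <- sprintf("gene_%04d", seq_along(genes))
  mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "+",
                             start(genes), end(genes))
  mcols(genes)$expression_class <- c(
    rep("active", length(border_genes)),
    sample(c("active", "inactive"), n_free, TRUE))
  nb <- length(border_genes)
  mcols(genes)$bound_site <- c(
    sites$site_id[length(ins_sites) + seq_len(nb)],
    rep(NA_character_, n_free))

  seqs <- NULL
  if (sequence) {
    consensus <- pwm_consensus(spec$motif)
    ml <- nchar(consensus)
    seqs <- lapply(setNames(names(lens), names(lens)), function(chr) {
      x <- paste(sample(c("A", "C", "G", "T"), lens[[chr]], replace = TRUE),
                 collapse = "")
      here <- ins_sites[as.character(seqnames(ins_sites)) == chr]
      for (i in seq_along(here)) {
        cpos <- floor(interval_center0(here[i]))
        m1 <- cpos - ml %/% 2 + 1
        substr(x, m1, m1 + ml - 1) <- consensus
      }
      x
    })
    seqs <- DNAStringSet(unlist(seqs))
  }

  structure(list(spec = spec, genome = genome, sequence = seqs,
                 sites = sort(sites), domains = domains, genes = sort(genes),
                 cofactor_refs = cofactor_refs,
                 repeat_truth = spec$repeat_library),
            class = "bc_world")
}

#' @export
print.bc_world <- function(x, ...) {
  cat("bc_world:", length(x$sites), "planted sites (",
      sum(x$sites$site_class == "gypsy_like"), "gypsy-like,",
      sum(x$sites$site_class == "border"), "border ),",
      length(x$domains), "HP1a domains,", length(x$genes), "genes",
      if (is.null(x$sequence)) "(no sequence)" else "(with sequence)", "\n")
  invisible(x)
}

#' Simulate a ChIP, input or knockdown tag sample
#'
#' Background tags are uniform at `background_rate`; site tags are fragment
#' midpoints jittered uniformly within half a fragment of the site center,
#' in numbers proportional to `(enrichment_fold - 1)` (scaled by
#' `knockdown_scaling` in the `ip_knockdown` sample for the classes in
#' `knockdown_classes`). The `input` sample has no site enrichment; the
#' `hp1a` sample is enriched broadly over HP1a domains; the `h3` sample is
#' uniform nucleosome signal depleted by `h3_depletion` inside planted
#' sites. Midpoints are converted to strand-aware 5' tag positions. The
#' total equals `n_tags` exactly (multinomial allocation); output is
#' deterministic given the spec seed and `sample_id`.
#'
#' @param world A [build_world()] result.
#' @param sample One of `"ip"`, `"input"`, `"ip_knockdown"`, `"h3"`,
#'   `"hp1a"`.
#' @param sample_id Label used for the child seed (vary it to get
#'   independent replicates of the same sample type).
#' @param n_tags Total tags (default `spec$n_tags`).
#' @param overrides Named list of spec fields to override for this sample
#'   (e.g. `list(knockdown_classes = "gypsy_like")`).
#' @return A [TagSet].
#' @export
simulate_tags <- function(world, sample = c("ip", "input", "ip_knockdown",
                                            "h3", "hp1a"),
                          sample_id = NULL, n_tags = NULL,
                          overrides = list()) {
  stopifnot(is(world, "bc_world"))
  sample <- match.arg(sample)
  sample_id <- sample_id %||% sample
  spec <- world$spec
  if (length(overrides)) spec[names(overrides)] <- overrides
  n_tags <- n_tags %||% spec$n_tags
  set.seed(child_seed(spec$seed, sample_id))
  genome <- world$genome
  lens <- seqlengths(genome)
  frag <- spec$fragment_length
  f2 <- frag %/% 2
  rate <- spec$background_rate
  # with background off, site/domain weights are relative among themselves
  wrate <- if (rate > 0) rate else 1
  sites <- world$sites

  kind <- character(0); weight <- numeric(0)
  cat_chr <- character(0); cat_idx <- integer(0)

  add_cat <- function(k, w, chr, idx) {
    kind <<- c(kind, k); weight <<- c(weight, w)
    cat_chr <<- c(cat_chr, chr); cat_idx <<- c(cat_idx, idx)
  }

  if (sample == "h3") {
    depl <- sites[sites$site_class %in% spec$h3_depleted_classes]
    zone_len <- sum(as.numeric(sum(coverage(depl) > 0)))
    per_chr_zone <- vapply(names(lens), function(chr)
      sum(width(depl[as.character(seqnames(depl)) == chr])), numeric(1))
    for (chr in names(lens))
      add_cat("bg_free", rate * (lens[[chr]] - per_chr_zone[[chr]]), chr, NA)
    for (i in seq_along(depl))
      add_cat("zone", rate * width(depl[i]) * spec$h3_depletion,
              as.character(seqnames(depl[i])), i)
  } else {
    for (chr in names(lens)) add_cat("bg", rate * lens[[chr]], chr, NA)
    if (sample %in% c("ip", "ip_knockdown")) {
      scl <- rep(1, length(sites))
      if (sample == "ip_knockdown")
        scl[sites$site_class %in% spec$knockdown_classes] <-
          spec$knockdown_scaling
      for (i in seq_along(sites))
        add_cat("site",
                (sites$enrichment_fold[i] - 1) * wrate * frag * scl[i],
                as.character(seqnames(sites[i])), i)
    } else if (sample == "hp1a") {
      for (i in seq_along(world$domains))
        add_cat("domain", (spec$hp1a_fold - 1) * wrate *
                  width(world$domains[i]),
                as.character(seqnames(world$domains[i])), i)
    }
  }

  if (n_tags == 0 || sum(weight) == 0) {
    counts <- rep(0L, length(weight))
  } else {
    counts <- as.vector(rmultinom(1, n_tags, prob = weight))
  }

  mids <- integer(0); chroms <- character(0)
  depl_zones <- if (sample == "h3")
    sites[sites$site_class %in% spec$h3_depleted_classes] else NULL
  for (j in seq_along(counts)) {
    n <- counts[j]
    if (n == 0) next
    chr <- cat_chr[j]
    L <- lens[[chr]]
    m <- switch(kind[j],
      bg = round(runif(n, f2 + 1, L - f2)),
      bg_free = {
        zc <- depl_zones[as.character(seqnames(depl_zones)) == chr]
        x <- round(runif(n, f2 + 1, L - f2))
        if (length(zc)) {
          repeat {
            inz <- overlapsAny(GRanges(chr, IRanges(x, width = 1)), zc)
            if (!any(inz)) break
            x[inz] <- round(runif(sum(inz), f2 + 1, L - f2))
          }
        }
        x
      },
      zone = {
        z <- depl_zones[cat_idx[j]]
        round(runif(n, start(z), end(z)))
      },
      site = {
        ctr <- floor(interval_center0(sites[cat_idx[j]]))
        pmax(f2 + 1, pmin(L - f2, ctr + round(runif(n, -f2, f2))))
      },
      domain = {
        d <- world$domains[cat_idx[j]]
        round(runif(n, start(d), end(d)))
      })
    mids <- c(mids, as.integer(m)); chroms <- c(chroms, rep(chr, n))
  }

  strands <- if (length(mids)) sample(c("+", "-"), length(mids), TRUE)
             else character(0)
  pos5 <- ifelse(strands == "+", mids - (f2 - 1L), mids + f2)
  pos5 <- pmax(1L, pmin(as.integer(lens[chroms]), as.integer(pos5)))
  gr <- GRanges(chroms, IRanges(pos5, width = 1L), strand = strands,
                seqinfo = genome)
  TagSet(sort(gr), sample_id)
}

#' Simulate per-repeat read counts and per-position coverage
#'
#' Input counts are Poisson with mean `length * copies * repeat_read_rate`;
#' IP counts additionally scale with the repeat's true fold. For repeats
#' flagged `five_prime_enriched`, the IP enrichment mass is concentrated in
#' the 5' `five_prime_fraction` of the consensus, emulating a 5'-insulator
#' profile; otherwise coverage is uniform.
#'
#' @param world A [build_world()] result.
#' @param five_prime_fraction Fraction of the consensus length forming the
#'   5' window (default 0.1).
#' @return A list: `counts` (data frame with `repeat_id`, `length`,
#'   `copies`, `true_fold`, `ip_count`, `input_count`), `coverage` (named
#'   list of per-repeat lists with integer vectors `ip`, `input`),
#'   `ip_library`, `input_library`.
#' @export
simulate_repeat_counts <- function(world, five_prime_fraction = 0.1) {
  stopifnot(is(world, "bc_world"))
  spec <- world$spec
  lib <- spec$repeat_library
  stop_if(nrow(lib) == 0, "repeat library is empty")
  set.seed(child_seed(spec$seed, "repeats"))
  lam_in <- lib$length * lib$copies * spec$repeat_read_rate
  input_count <- rpois(nrow(lib), lam_in)
  ip_count <- rpois(nrow(lib), lam_in * lib$fold)
  coverage <- vector("list", nrow(lib))
  names(coverage) <- lib$repeat_id
  for (i in seq_len(nrow(lib))) {
    L <- lib$length[i]
    wlen <- max(1L, floor(L * five_prime_fraction))
    w_ip <- rep(1, L)
    if (lib$five_prime_enriched[i] && lib$fold[i] > 1)
      w_ip[seq_len(wlen)] <- w_ip[seq_len(wlen)] +
        (lib$fold[i] - 1) * L / wlen
    cov_one <- function(n, w) {
      if (n == 0) return(integer(L))
      tabulate(sample.int(L, n, replace = TRUE, prob = w), nbins = L)
    }
    coverage[[i]] <- list(ip = cov_one(ip_count[i], w_ip),
                          input = cov_one(input_count[i], rep(1, L)))
  }
  list(counts = data.frame(repeat_id = lib$repeat_id, length = lib$length,
                           copies = lib$copies, true_fold = lib$fold,
                           ip_count = ip_count, input_count = input_count,
                           stringsAsFactors = FALSE),
       coverage = coverage,
       ip_library = spec$n_tags, input_library = spec$n_tags)
}

#' Simulate wild-type expression levels and mutant fold changes
#'
#' Wild-type levels are log-normal, higher for active genes; genes paired
#' with a border site receive a mutant log2 fold change centered at
#' `-effect`, all others at 0.
#'
#' @param world A [build_world()] result.
#' @param effect Mean downregulation (in log2 units) of border-bound genes
#'   in the mutant.
#' @param sd_log2fc Standard deviation of per-gene log2 fold changes.
#' @return Data frame with `gene_id`, `expression_class`, `border_bound`,
#'   `wt_level`, `mut_log2fc`.
#' @export
simulate_expression <- function(world, effect = 1, sd_log2fc = 0.3) {
  stopifnot(is(world, "bc_world"))
  spec <- world$spec
  set.seed(child_seed(spec$seed, "expression"))
  g <- world$genes
  active <- g$expression_class == "active"
  bound <- !is.na(g$bound_site)
  data.frame(
    gene_id = g$gene_id,
    expression_class = g$expression_class,
    border_bound = bound,
    wt_level = rlnorm(length(g), meanlog = log(20) + log(6) * active,
                      sdlog = 0.8),
    mut_log2fc = rnorm(length(g), mean = -effect * bound, sd = sd_log2fc),
    stringsAsFactors = FALSE)
}
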