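# End-to-end pipeline over a simulated world: replicate peak calls,
# consensus, domain segmentation, classification, knockdown
# quantification, repeat enrichment, annotation and expression linkage.

#' Run the full analysis pipeline on a simulated world
#'
#' Builds the world, simulates input, IP replicates, HP1a, knockdown and
#' control samples, calls fixed-width peaks per replicate, selects the
#' 2-of-n consensus, segments HP1a domains, classifies consensus peaks by
#' cofactor combination / HP1a adjacency / motif content, quantifies
#' knockdown fold changes with the low-count filter and a rank-sum test
#' between gypsy-like and border peaks, computes repeat enrichment and the
#' gypsy 5' coverage ratio, annotates peaks to landmarks, and compares
#' expression of class-1- and class-2-bound genes. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param n_replicates Number of IP replicates (default 3).
#' @param expression_effect Mean mutant downregulation (log2) of
#'   border-bound genes (default 1).
#' @param knockdown_mode `"direct"` scales all site classes (factor
#'   knockdown); `"cofactor"` scales only gypsy-like sites (CP190-type
#'   knockdown).
#' @param peak_params,domain_params Parameter objects.
#' @param sequence Whether to generate sequence and run the motif scan.
#' @return A list with the world, peak calls, consensus, domains,
#'   classification, knockdown table and test, repeat table, annotation,
#'   fractions and expression comparisons.
#' @export
run_pipeline <- function(spec = simulation_spec(), n_replicates = 3,
                         expression_effect = 1,
                         knockdown_mode = c("direct", "cofactor"),
                         peak_params = peak_call_params(
                           fragment_length = spec$fragment_length),
                         domain_params = domain_call_params(),
                         sequence = TRUE) {
  knockdown_mode <- match.arg(knockdown_mode)
  world <- build_world(spec, sequence = sequence)
  genome <- world$genome

  input <- simulate_tags(world, "input")
  reps <- lapply(seq_len(n_replicates), function(i)
    simulate_tags(world, "ip", sample_id = paste0("ip_rep", i)))
  hp1a <- simulate_tags(world, "hp1a")
  ctrl <- simulate_tags(world, "ip", sample_id = "ip_ctrl")
  kd_overrides <- if (knockdown_mode == "cofactor")
    list(knockdown_classes = "gypsy_like") else list()
  kd <- simulate_tags(world, "ip_knockdown", overrides = kd_overrides)

  peak_calls <- lapply(reps, call_fixed_width_peaks, input = input,
                       genome = genome, params = peak_params)
  consensus <- consensus_peaks(peak_calls, min_support = 2,
                               peak_width = peak_params$peak_width)
  domains <- call_domains(hp1a, input, genome, domain_params,
                          fragment_length = spec$fragment_length)

  cls <- classify_peaks(consensus, world$cofactor_refs, domains,
                        genome_sequence = world$sequence,
                        pwm = if (sequence) spec$motif else NULL)

  kd_table <- knockdown_foldchange(ctrl, kd, consensus,
                                   extend_to = spec$fragment_length,
                                   classes = cls$peaks$gypsy_like)
  kd_test <- NULL
  gl <- kd_table$class == "TRUE"
  if (any(gl) && any(!gl))
    kd_test <- ranksum_test(kd_table$fold_change[gl],
                            kd_table$fold_change[!gl])

  rc <- simulate_repeat_counts(world)
  repeat_table <- repeat_enrichment(rc$counts, rc$ip_library,
                                    rc$input_library)
  gypsy_cov <- if ("gypsy" %in% names(rc$coverage))
    consensus_coverage(rc$coverage$gypsy$ip, rc$ip_library) else NULL

  ann <- annotate_peaks(consensus, world$genes)
  fractions <- annotation_fractions(ann, cls$peaks$hp1a_class)

  expr <- simulate_expression(world, effect = expression_effect)
  at_tss <- ann$category == "promoter_tss" & !is.na(ann$nearest_gene)
  bound <- split(ann$nearest_gene[at_tss],
                 cls$peaks$hp1a_class[at_tss])
  bound <- lapply(bound, unique)
  names(bound) <- paste0(names(bound), "_bound")
  expr_cmp <- list()
  if (all(lengths(bound) > 0)) {
    expr_cmp$levels <- compare_expression(bound, expr, mode = "levels")
    expr_cmp$mutant <- compare_expression(bound, expr,
                                          mode = "mutant_log2fc")
  }

  list(world = world, input = input, replicates = reps,
       peak_calls = peak_calls, consensus = consensus, domains = domains,
       classification = cls, kd_table = kd_table, kd_test = kd_test,
       repeat_table = repeat_table, gypsy_coverage = gypsy_cov,
       annotation = ann, fractions = fractions, expression = expr,
       expression_comparison = expr_cmp)
}

#' Write the pipeline's tabular outputs to a directory
#'
#' Emits plain-text BED and TSV files for every major result so that two
#' runs can be compared byte for byte.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_bed(res$consensus, p("consensus_peaks.bed"))
  write_bed(res$domains, p("hp1a_domains.bed"))
  for (i in seq_along(res$peak_calls))
    write_bed(res$peak_calls[[i]], p(sprintf("peaks_rep%d.bed", i)))
  write_tsv(res$classification$peaks, p("classification.tsv"))
  write_tsv(res$classification$combination_table,
            p("combination_table.tsv"))
  write_tsv(res$kd_table, p("knockdown_foldchange.tsv"))
  write_tsv(res$repeat_table, p("repeat_enrichment.tsv"))
  write_tsv(res$annotation, p("annotation.tsv"))
  write_tsv(res$fractions, p("annotation_fractions.tsv"))
  write_tsv(res$expression, p("expression.tsv"))
  if (length(res$expression_comparison)) {
    write_tsv(res$expression_comparison$levels, p("expression_levels.tsv"))
    write_tsv(res$expression_comparison$mutant, p("expression_mutant.tsv"))
  }
  sites <- res$world$sites
  write_tsv(data.frame(chrom = as.character(seqnames(sites)),
                       start = start(sites) - 1L, end = end(sites),
                       site_id = sites$site_id,
                       site_class = sites$site_class,
                       cofactors = sites$cofactors,
                       stringsAsFactors = FALSE),
            p("truth_sites.tsv"))
  write_bed(res$world$domains, p("truth_domains.bed"))
  write_genes(res$world$genes, p("genes.tsv"))
  for (nm in names(res$world$cofactor_refs)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    write_bed(res$world$cofactor_refs[[nm]],
              p(sprintf("ref_%s.bed", safe)))
  }
  invisible(dir)
}
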