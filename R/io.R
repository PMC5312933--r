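# Readers/writers for the plain-text formats the pipeline consumes. BED is
# parsed by rtracklayer; a light pre-scan supplies line-numbered messages
# for malformed input and enforces start < end before coordinates enter the
# 1-based GRanges world.

.scan_bed <- function(path, min_fields = 3L, need_strand = FALSE) {
  stop_if(!file.exists(path), "file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) return(invisible(0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  stop_if(length(bad) > 0, "malformed BED line ", bad[1], ": expected >= ",
          min_fields, " tab-separated fields, found ", nf[bad[1]])
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  stop_if(length(bad) > 0, "malformed BED line ", bad[1],
          ": non-numeric coordinates")
  bad <- which(s >= e)
  stop_if(length(bad) > 0, "invalid interval at BED line ", bad[1],
          ": start >= end")
  if (need_strand) {
    st <- vapply(fields, function(f) if (length(f) >= 6) f[6] else "",
                 FUN.VALUE = "")
    bad <- which(!st %in% c("+", "-"))
    stop_if(length(bad) > 0, "BED line ", bad[1],
            ": tag files require strand + or - in column 6")
  }
  invisible(length(lines))
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of `GRanges` on read; [write_bed()] inverts the conversion, so
#' BED round trips are bit-identical.
#'
#' @param path Path to a 3+ column BED file.
#' @param genome Optional `Seqinfo`; when given, chromosome names and bounds
#'   are validated against it.
#' @return A `GRanges` in file order (with `name`/`score` columns when
#'   present in the file).
#' @export
read_bed <- function(path, genome = NULL) {
  .scan_bed(path, 3L)
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) gr <- validate_chroms(gr, genome)
  gr
}

#' Write genomic intervals to a BED file
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Read aligned tags from a BED-like file
#'
#' Each line is one aligned read; the strand column (6) is required. Reads
#' are reduced to their strand-aware 5' position: the interval start for
#' `+` tags and the last covered base for `-` tags.
#'
#' @param path Path to a 6-column BED file of aligned reads.
#' @param sample_id Sample name; defaults to the file name without extension.
#' @param genome Optional `Seqinfo` for validation.
#' @return A [TagSet] with `library_size` equal to the number of lines.
#' @export
read_tags <- function(path, sample_id = NULL, genome = NULL) {
  .scan_bed(path, 6L, need_strand = TRUE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path, format = "BED")
  gr <- resize(gr, width = 1L, fix = "start")
  mcols(gr) <- NULL
  ts <- TagSet(gr, sample_id)
  if (!is.null(genome)) ts <- validate_chroms(ts, genome)
  ts
}

#' Write a TagSet to a BED file of 5' positions
#'
#' The inverse of [read_tags()] at the TagSet level: each tag becomes a
#' 1 bp stranded BED interval, so `read_tags(write_tags(x))` reproduces `x`.
#'
#' @param tags A [TagSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  stopifnot(is(tags, "TagSet"))
  gr <- tags$tags
  mcols(gr)$name <- rep(".", length(gr))
  mcols(gr)$score <- rep(0L, length(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts either GFF3 (`gene` features; 1-based inclusive coordinates as
#' per the format) or a tab-separated table with a header and columns
#' `gene_id`, `chrom`, `start`, `end`, `strand` (1-based inclusive; the
#' TSS is derived as `start` for `+` genes and `end` for `-` genes). A
#' 4-column variant `gene_id`, `chrom`, `strand`, `tss` is also accepted
#' (genes become 1 bp spans at the TSS).
#'
#' @param path Path to a GFF3 or TSV file.
#' @param genome Optional `Seqinfo` for validation.
#' @return A `GRanges` with mcols `gene_id` and `tss` (1-based position).
#' @export
read_genes <- function(path, genome = NULL) {
  stop_if(!file.exists(path), "file does not exist: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF")
    gr <- gr[gr$type == "gene"]
    gid <- gr$ID %||% gr$gene_id
    gr2 <- granges(gr)
    mcols(gr2)$gene_id <- as.character(gid)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (all(c("start", "end") %in% names(tab))) {
      gr2 <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                     strand = tab$strand)
    } else {
      stop_if(!"tss" %in% names(tab),
              "gene TSV needs either start/end or tss columns")
      gr2 <- GRanges(tab$chrom, IRanges(tab$tss, width = 1L),
                     strand = tab$strand)
    }
    mcols(gr2)$gene_id <- as.character(tab$gene_id)
    extra <- setdiff(names(tab), c("gene_id", "chrom", "start", "end",
                                   "strand", "tss"))
    for (cn in extra) mcols(gr2)[[cn]] <- tab[[cn]]
  }
  mcols(gr2)$tss <- ifelse(as.character(strand(gr2)) == "+",
                           start(gr2), end(gr2))
  if (!is.null(genome)) gr2 <- validate_chroms(gr2, genome)
  gr2
}

#' Write gene annotations as TSV
#' @param genes `GRanges` with `gene_id` mcol (as from [read_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   strand = as.character(strand(genes)),
                   stringsAsFactors = FALSE)
  extra <- setdiff(names(mcols(genes)), c("gene_id", "tss"))
  for (cn in extra) df[[cn]] <- mcols(genes)[[cn]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as a plain TSV file
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
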