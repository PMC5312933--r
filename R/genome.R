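#' Describe a (toy) genome as a Seqinfo object
#'
#' A genome is a set of uniquely named chromosomes with positive lengths,
#' represented with the standard Bioconductor [GenomeInfoDb::Seqinfo]
#' container so it can be attached to any `GRanges`.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return A `Seqinfo` object.
#' @export
#' @examples
#' bc_genome(c("chr2L", "chr4"), c(1e6, 4e5))
bc_genome <- function(chrom, length) {
  stop_if(anyDuplicated(chrom) > 0, "chromosome names must be unique")
  stop_if(any(length <= 0), "chromosome lengths must be > 0")
  stop_if(base::length(chrom) != base::length(length),
          "chrom and length differ in length")
  Seqinfo(seqnames = as.character(chrom), seqlengths = as.integer(length))
}

#' Total genome size in bp
#' @param genome A `Seqinfo` object.
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(seqlengths(genome)))
}

#' Validate chromosome names of a GRanges against a genome
#'
#' Chromosome matching is exact string equality; names absent from the
#' genome raise an error rather than being silently dropped. An exclusion
#' list supports deliberately ignored chromosomes (e.g. an assembly's
#' unplaced scaffolds).
#'
#' @param x A `GRanges` (or TagSet).
#' @param genome A `Seqinfo`.
#' @param exclude Character vector of chromosome names to drop silently.
#' @return `x` with `exclude` chromosomes removed and seqinfo set.
#' @export
validate_chroms <- function(x, genome, exclude = character()) {
  if (is(x, "TagSet")) {
    x$tags <- validate_chroms(x$tags, genome, exclude)
    x$library_size <- base::length(x$tags)
    return(x)
  }
  x <- x[!(as.character(seqnames(x)) %in% exclude)]
  bad <- setdiff(unique(as.character(seqnames(x))), seqlevels(genome))
  stop_if(base::length(bad) > 0,
          "chromosome name(s) absent from genome: ",
          paste(bad, collapse = ", "))
  oob <- end(x) > seqlengths(genome)[as.character(seqnames(x))] | start(x) < 1
  stop_if(any(oob), sum(oob), " interval(s) out of chromosome bounds")
  GenomeInfoDb::seqlevels(x) <- seqlevels(genome)
  seqinfo(x) <- genome
  x
}
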