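#' Construct a TagSet
#'
#' A TagSet is a sample's aligned sequencing tags, each reduced to its
#' strand-aware 5' position (a width-1 stranded `GRanges`), plus the sample
#' id and the library size. Fragment extension is applied only inside
#' counting and profiling operations, matching single-end sequencing of
#' chromatin sheared to a fixed average fragment size.
#'
#' @param tags Width-1 `GRanges` with strand `+` or `-`.
#' @param sample_id Character scalar naming the sample.
#' @return An object of class `TagSet`: a list with elements `sample_id`,
#'   `tags` and `library_size` (always equal to `length(tags)`).
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr2L", IRanges::IRanges(c(10, 50), width = 1),
#'                              strand = c("+", "-"))
#' TagSet(gr, "ip")
TagSet <- function(tags, sample_id) {
  stopifnot(is(tags, "GRanges"), is.character(sample_id),
            length(sample_id) == 1L)
  stop_if(length(tags) > 0 && any(width(tags) != 1L),
          "tags must be width-1 positions")
  stop_if(length(tags) > 0 && any(!as.character(strand(tags)) %in% c("+", "-")),
          "every tag needs strand + or -")
  structure(list(sample_id = sample_id, tags = tags,
                 library_size = length(tags)),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat("TagSet '", x$sample_id, "': ", x$library_size, " tags on ",
      length(unique(as.character(seqnames(x$tags)))), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' @export
length.TagSet <- function(x) x$library_size

#' Strand-aware fragment intervals for a TagSet
#'
#' Extends each 5' tag position to its presumed fragment of length
#' `extend_to` in the tag's strand direction, trimmed to chromosome bounds
#' when the TagSet carries seqlengths.
#'
#' @param tags A [TagSet].
#' @param extend_to Fragment length in bp.
#' @return A `GRanges` of fragments.
#' @export
tag_fragments <- function(tags, extend_to = 200L) {
  stopifnot(is(tags, "TagSet"), extend_to >= 1)
  fr <- resize(tags$tags, width = as.integer(extend_to), fix = "start")
  if (!all(is.na(seqlengths(fr)))) fr <- trim(fr)
  fr
}
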