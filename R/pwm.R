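#' Construct a position weight matrix
#'
#' A PWM is a 4 x L matrix of per-position base probabilities (rows A, C,
#' G, T) with a background distribution. A pseudocount is applied so that
#' every entry is strictly positive, then columns are renormalized to sum
#' to 1.
#'
#' @param mat 4 x L numeric matrix; rows in order A, C, G, T (rownames are
#'   set if missing).
#' @param background Length-4 probability vector over A, C, G, T.
#' @param motif_id Character identifier.
#' @param pseudocount Probability mass added to each entry before
#'   renormalization (default 1e-3).
#' @return An object of class `PWM`.
#' @export
#' @examples
#' pwm(matrix(c(.97, .01, .01, .01), 4, 3), motif_id = "polyA")
pwm <- function(mat, background = rep(0.25, 4), motif_id = "motif",
                pseudocount = 1e-3) {
  stopifnot(is.matrix(mat), nrow(mat) == 4, all(mat >= 0),
            length(background) == 4, all(background > 0))
  mat <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  stop_if(any(abs(colSums(mat) - 1) > 1e-9), "PWM columns must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = mat, background = background),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM '", x$motif_id, "', ", ncol(x$matrix), " positions, consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' @param consensus Character string over A/C/G/T.
#' @param p Probability of the consensus base at each position.
#' @param motif_id Identifier (defaults to the consensus string).
#' @return A [pwm()] object.
#' @export
consensus_pwm <- function(consensus, p = 0.97, motif_id = consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")), p > 0.25, p < 1)
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- p
  pwm(m, motif_id = motif_id, pseudocount = 0)
}

#' Consensus string of a PWM
#' @param x A `PWM`.
#' @return Character string of per-position most probable bases.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Log2-odds scoring matrix of a PWM
#' @param x A `PWM`.
#' @return 4 x L numeric matrix of `log2(p / background)` scores.
#' @export
pwm_log_odds <- function(x) {
  log2(x$matrix / x$background)
}

#' Maximum attainable log2-odds score of a PWM
#' @param x A `PWM`.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(x) {
  sum(apply(pwm_log_odds(x), 2, max))
}

#' Read a PWM from a plain-text 4-row matrix file
#'
#' Format: an optional `#`-prefixed id line, then four lines `A p1 p2 ...`,
#' `C ...`, `G ...`, `T ...` of per-position probabilities, and an optional
#' `background pA pC pG pT` line.
#'
#' @param path Path to the matrix file.
#' @return A `PWM`.
#' @export
read_pwm <- function(path) {
  stop_if(!file.exists(path), "file does not exist: ", path)
  lines <- readLines(path)
  id <- "motif"
  if (length(lines) && grepl("^#", lines[1])) {
    id <- sub("^#\\s*", "", lines[1])
    lines <- lines[-1]
  }
  fields <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  lab <- toupper(vapply(fields, `[`, "", 1L))
  rows <- match(c("A", "C", "G", "T"), lab)
  stop_if(any(is.na(rows)), "PWM file needs rows labelled A, C, G, T")
  m <- t(vapply(fields[rows],
                function(f) as.numeric(f[-1]),
                numeric(length(fields[[rows[1]]]) - 1)))
  bg <- rep(0.25, 4)
  bi <- match("BACKGROUND", lab)
  if (!is.na(bi)) bg <- as.numeric(fields[[bi]][-1])
  pwm(m, background = bg, motif_id = id, pseudocount = 0)
}

#' Write a PWM to a plain-text matrix file
#' @param x A `PWM`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", x$motif_id), con)
  for (b in rownames(x$matrix)) {
    writeLines(paste(b, paste(format(x$matrix[b, ], digits = 10),
                              collapse = " ")), con)
  }
  writeLines(paste("background",
                   paste(format(x$background, digits = 10), collapse = " ")),
             con)
  invisible(path)
}
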