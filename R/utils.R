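`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed and a label
#'
#' A single pipeline seed fans out to per-sample child seeds by stable
#' hashing of the sample label, so that adding a sample to a simulation
#' never perturbs the tags drawn for existing samples.
#'
#' @param seed Integer master seed.
#' @param id Character label (e.g. a sample id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "ip") != child_seed(1, "input")
child_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.numeric(seed), length(id) == 1L,
            is.character(id))
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 1000003
  as.integer(((abs(seed) %% 65011) + 1) * 32713 + h * 611 + 17) %% 2147483646L
}

#' Largest-remainder apportionment of a total over fractions
#'
#' Deterministically rounds `n * fractions` to integers summing to `n`:
#' floors first, then assigns the remaining units in order of decreasing
#' fractional remainder (ties broken by position).
#'
#' @param fractions Non-negative numeric vector summing to 1.
#' @param n Total count to apportion.
#' @return Integer vector, same names as `fractions`, summing to `n`.
#' @export
#' @examples
#' largest_remainder(c(a = 0.6, b = 0.4), 50)
largest_remainder <- function(fractions, n) {
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-8, n >= 0)
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(fractions))
}

# interval centre in the 0-based half-open convention used for reported
# coordinates; for a 1-based closed GRanges [s, e] this is (s - 1 + e) / 2
interval_center0 <- function(gr) {
  (start(gr) - 1 + end(gr)) / 2
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
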