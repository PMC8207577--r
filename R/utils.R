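#' Round half away from zero
#'
#' Deterministic rounding used when converting regression products to integer
#' point scores: exact halves move away from zero (1.5 -> 2, -1.5 -> -2),
#' unlike base [round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Largest-remainder apportionment
#'
#' Distributes `n` units over categories proportionally to `weights`, using
#' the largest-remainder (Hamilton) method so the counts always sum exactly
#' to `n`. Ties in remainders are broken by category order for determinism.
#'
#' @param n total count to distribute (non-negative integer).
#' @param weights non-negative weights; need not sum to one.
#' @return integer vector of counts, same length as `weights`, summing to `n`.
#' @examples
#' largest_remainder(10, c(0.55, 0.45))  # 6 4
#' @export
largest_remainder <- function(n, weights) {
  stopifnot(length(n) == 1L, n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  short <- as.integer(round(n - sum(base)))
  counts <- base
  if (short > 0L) {
    rem <- quota - base
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# md5 of the canonical JSON rendering of an object; used to stamp reports
# with the identity of the built-in tables they relied on.
object_checksum <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  if (is.object(x)) x <- unclass(x)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              na = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# Draw per-replicate RNG seeds from a master seed so each replicate is an
# independent, individually reproducible substream. Kept below 2^31.
spawn_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, k)
}
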