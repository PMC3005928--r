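#' Capped infix (semi-global) edit distance
#'
#' Minimum unit-cost Levenshtein distance between `probe` and any substring
#' of `gene`: gaps before and after the matched substring of `gene` are
#' free. This is the specificity measure used throughout probe design -- a
#' small distance to a non-target gene signals likely cross-hybridization.
#' The search is capped: when the true minimum exceeds `cap` the exact value
#' is not computed and the result is flagged, which keeps screening fast
#' when only "is the distance above the threshold?" matters.
#'
#' `N` never matches any base (including another `N`); a candidate window
#' containing `N` therefore has a conservative, inflated distance.
#'
#' @param probe Character scalar, the short query (length >= 1).
#' @param gene Character scalar, the text searched (may be empty: the
#'   distance is then `nchar(probe)`, the all-deletion alignment).
#' @param cap Integer >= 0. Distances above `cap` are reported as exceeded.
#' @return A list with elements `distance` (integer, `NA` when the cap was
#'   exceeded), `end_position` (0-based half-open end offset of the best
#'   match in `gene`; smallest end on ties; `NA` when the cap was exceeded)
#'   and `cap_exceeded` (logical).
#' @examples
#' infix_edit_distance("ACGT", "TTACGTTT", cap = 10)$distance # 0
#' infix_edit_distance("ACGT", "CCCC", cap = 1)$cap_exceeded  # TRUE
#' @seealso [brute_force_infix_distance()] for the uncapped full-matrix
#'   reference, [qgram_lower_bound()] for the prefilter bound.
#' @export
infix_edit_distance <- function(probe, gene, cap = nchar(probe)) {
  stopifnot(is.character(probe), length(probe) == 1L, nchar(probe) >= 1L,
            is.character(gene), length(gene) == 1L,
            is.numeric(cap), length(cap) == 1L, cap >= 0)
  res <- .infix_edit_cpp(probe, gene, as.integer(cap))
  if (res[1L] < 0L) {
    list(distance = NA_integer_, end_position = NA_integer_,
         cap_exceeded = TRUE)
  } else {
    list(distance = res[1L], end_position = res[2L], cap_exceeded = FALSE)
  }
}

#' Uncapped infix edit distance by full dynamic programming
#'
#' Reference implementation: fills the whole (probe+1) x (gene+1) matrix with
#' a zero first row and returns the minimum of the last row. Independent of
#' the capped banded routine; used as ground truth in the test suite and for
#' post-hoc verification of designed probes. Row updates are vectorised over
#' the gene; the left-to-right dependency is resolved with the cumulative-
#' minimum identity D[j] = j + min_{k<=j}(M[k] - k) for unit gap costs.
#'
#' @inheritParams infix_edit_distance
#' @return Integer distance (no cap).
#' @export
brute_force_infix_distance <- function(probe, gene) {
  stopifnot(is.character(probe), length(probe) == 1L, nchar(probe) >= 1L,
            is.character(gene), length(gene) == 1L)
  p <- strsplit(probe, "", fixed = TRUE)[[1L]]
  g <- strsplit(gene, "", fixed = TRUE)[[1L]]
  m <- length(p)
  n <- length(g)
  if (n == 0L) return(m)
  prev <- integer(n + 1L)
  idx <- 0L:n
  for (i in seq_len(m)) {
    cost <- as.integer(g != p[i] | g == "N" | p[i] == "N")
    cand <- c(i, pmin(prev[-1L] + 1L, prev[-(n + 1L)] + cost))
    prev <- idx + cummin(cand - idx)
  }
  min(prev)
}

#' q-gram lower bound on the infix edit distance
#'
#' Every edit operation destroys at most `q` of the probe's overlapping
#' q-grams, so if `missing` probe q-grams are absent from the gene, any
#' alignment needs at least `ceiling(missing / q)` edits. The bound is cheap
#' and is used only to skip transcripts whose bound already exceeds the
#' screening cap; correctness of the pipeline never depends on `q`.
#'
#' @inheritParams infix_edit_distance
#' @param q Integer q-gram length, `1 <= q <= nchar(probe)`.
#' @return Integer lower bound, always `<= brute_force_infix_distance(probe,
#'   gene)`.
#' @export
qgram_lower_bound <- function(probe, gene, q) {
  stopifnot(q >= 1L, q <= nchar(probe))
  .qgram_bound(.qgrams(probe, q), .qgram_set(gene, q), q)
}

# overlapping q-grams of a string, one per start position (may repeat)
.qgrams <- function(x, q) {
  np <- nchar(x) - q + 1L
  if (np < 1L) return(character())
  substring(x, seq_len(np), seq_len(np) + q - 1L)
}

.qgram_set <- function(x, q) unique(.qgrams(x, q))

.qgram_bound <- function(probe_qgrams, gene_set, q) {
  missing <- sum(!(probe_qgrams %in% gene_set))
  as.integer(ceiling(missing / q))
}
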