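#' Random DNA sequences
#'
#' Uniform i.i.d. bases; a convenience generator for synthetic transcript
#' sets. Uses the current RNG state.
#'
#' @param n Number of sequences.
#' @param length Sequence length(s) in bp (recycled).
#' @param ids Sequence ids (default `g0001`, ...).
#' @param species Species label.
#' @return A [Biostrings::DNAStringSet].
#' @export
random_transcripts <- function(n, length = 500L,
                               ids = sprintf("g%04d", seq_len(n)),
                               species = "synthetic") {
  length <- rep_len(as.integer(length), n)
  seqs <- vapply(length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L))
  transcript_set(seqs, ids = ids, species = species)
}

#' Deterministic toy dataset for examples and smoke tests
#'
#' Five reference-species and three query-species genes constructed to exercise every
#' probe-design removal path: an ordinary accepted gene, a too-short gene,
#' an identical duplicated pair (removed as non-specific), and a gene whose
#' 3'-most window is planted verbatim in a query-species transcript so the
#' cross-species filter removes it.
#'
#' @param seed Integer seed.
#' @return List with `species_a` and `species_b` transcript sets.
#' @export
toy_dataset <- function(seed = 42L) {
  set.seed(seed)
  rnd <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = "")
  dup <- rnd(300L)
  conflict <- rnd(300L)
  a <- c(refA = rnd(300L), refShort = rnd(40L), refDup1 = dup, refDup2 = dup,
         refConflict = conflict)
  # query gene 1 carries the 3'-most valid window of refConflict (start 200)
  planted <- substr(conflict, 201L, 260L)
  b <- c(qryCarrier = paste0(planted, rnd(240L)), qryB = rnd(300L),
         qryC = rnd(300L))
  list(species_a = transcript_set(a, species = "species_a"),
       species_b = transcript_set(b, species = "species_b"))
}
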