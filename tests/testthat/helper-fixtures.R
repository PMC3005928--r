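# shared generators for the test suite; everything is built in code

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random (probe, gene) pair for edit-distance property tests
rand_pair <- function(max_probe = 20L, max_gene = 100L, with_n = FALSE) {
  ab <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  list(probe = rand_dna(sample.int(max_probe, 1L), ab),
       gene = rand_dna(sample.int(max_gene + 1L, 1L) - 1L, ab))
}

# write a FASTA file from a named character vector, return its path
write_fasta_tmp <- function(seqs, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  path
}

# random valid probe-table rows for round-trip tests
rand_probe_rows <- function(n) {
  starts <- sample.int(500L, n, replace = TRUE) - 1L
  seqs <- vapply(rep(60L, n), rand_dna, character(1L))
  gene <- sprintf("g%03d", sample.int(200L, n, replace = TRUE))
  dist <- sample(c(NA_integer_, 0:30), n, replace = TRUE)
  data.frame(probe_id = sprintf("%s_%d_%d", gene, starts, seq_len(n)),
             gene_id = gene, start = starts, length = 60L, sequence = seqs,
             min_cross_distance = dist,
             nearest_nontarget = ifelse(is.na(dist), NA_character_,
                                        sprintf("g%03d", sample.int(200L, n,
                                                                    replace = TRUE))),
             dist_to_3prime = sample.int(400L, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

# plant `k` substitutions into a sequence at distinct positions
plant_substitutions <- function(seq, k) {
  pos <- sample.int(nchar(seq), k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
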