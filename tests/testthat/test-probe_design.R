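test_that("candidate extraction tiles 60-mers every 50 bp", {
  set.seed(21)
  cfg <- design_config()
  tx <- rand_dna(160L)
  cands <- extract_candidates(tx, "g1", cfg)
  expect_equal(cands$start, c(0L, 50L, 100L))
  expect_equal(cands$sequence, substring(tx, cands$start + 1L,
                                         cands$start + 60L))
  expect_equal(cands$dist_to_3prime, 160L - (cands$start + 60L))

  expect_equal(nrow(extract_candidates(rand_dna(59L), "g2", cfg)), 0L)

  one <- extract_candidates(rand_dna(60L), "g3", cfg)
  expect_equal(one$start, 0L)
  expect_equal(one$dist_to_3prime, 0L)
})

test_that("windows containing N are discarded at extraction", {
  set.seed(22)
  tx <- paste0(rand_dna(55L), "N", rand_dna(104L))  # N at position 56
  cands <- extract_candidates(tx, "g1", design_config())
  expect_equal(cands$start, c(100L))  # windows at 0 and 50 overlap the N
})

test_that("cross-gene screening finds the nearest non-target", {
  set.seed(23)
  cfg <- design_config(check_reverse_complement = FALSE)
  self <- rand_dna(120L)
  cand <- substr(self, 1L, 60L)
  near <- paste0(rand_dna(20L), plant_substitutions(cand, 2L), rand_dna(20L))
  far <- paste0(rand_dna(10L), plant_substitutions(cand, 5L), rand_dna(10L))
  tx <- transcript_set(c(self = self, near = near, far = far))
  # verify the construction with the independent oracle
  expect_equal(brute_force_infix_distance(cand, near), 2L)
  expect_equal(brute_force_infix_distance(cand, far), 5L)

  r <- min_cross_distance(cand, tx, exclude_gene = "self", config = cfg)
  expect_equal(r$distance, 2L)
  expect_equal(r$nearest, "near")

  # identical window in another gene
  twin <- transcript_set(c(self = self,
                           twin = paste0(rand_dna(5L), cand, rand_dna(5L))))
  r <- min_cross_distance(cand, twin, exclude_gene = "self", config = cfg)
  expect_equal(r$distance, 0L)
  expect_equal(r$nearest, "twin")

  # everything beyond the cap
  r <- min_cross_distance("ACGT", transcript_set(c(self = "ACGTACGT",
                                                   x = "GGGGGGGG")),
                          exclude_gene = "self",
                          config = design_config(probe_length = 4L,
                                                 distance_threshold = 1L,
                                                 cap = 2L, qgram_q = 2L))
  expect_true(r$cap_exceeded)
  expect_true(is.na(r$nearest))

  # empty set after exclusion reports maximal specificity
  r <- min_cross_distance(cand, transcript_set(c(self = self)),
                          exclude_gene = "self", config = cfg)
  expect_true(r$cap_exceeded)
})

test_that("the reverse complement is screened when configured", {
  set.seed(24)
  self <- rand_dna(120L)
  cand <- substr(self, 1L, 60L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cand)))
  other <- paste0(rand_dna(15L), rc, rand_dna(15L))
  tx <- transcript_set(c(self = self, other = other))
  r <- min_cross_distance(cand, tx, "self",
                          design_config(check_reverse_complement = TRUE))
  expect_equal(r$distance, 0L)
  r <- min_cross_distance(cand, tx, "self",
                          design_config(check_reverse_complement = FALSE))
  expect_true(r$cap_exceeded)
})

test_that("probe selection applies strict thresholds and the 3'-most rule", {
  cfg <- design_config()
  base <- data.frame(gene_id = "g", start = c(0L, 50L),
                     sequence = c(strrep("A", 60L), strrep("C", 60L)),
                     dist_to_3prime = c(140L, 90L),
                     min_cross_distance = c(20L, 20L),
                     nearest_nontarget = "other", stringsAsFactors = FALSE)
  sel <- select_probe_for_gene(base, cfg)
  expect_equal(sel$probe$start, 50L)           # 3'-most passing candidate
  expect_equal(sel$probe$probe_id, "g_50")

  # margin is strict: 15 <= 20 fails, 21 > 20 passes
  short3 <- base[1L, ]; short3$dist_to_3prime <- 15L
  expect_equal(select_probe_for_gene(short3, cfg)$reason,
               "no_specific_candidate")
  edge <- base[1L, ]; edge$dist_to_3prime <- 21L
  expect_equal(select_probe_for_gene(edge, cfg)$probe$start, 0L)

  # distance threshold is strict: exactly 11 fails, 12 passes
  d11 <- base[1L, ]; d11$min_cross_distance <- 11L
  expect_equal(select_probe_for_gene(d11, cfg)$reason,
               "no_specific_candidate")
  d12 <- base[1L, ]; d12$min_cross_distance <- 12L
  expect_false(is.null(select_probe_for_gene(d12, cfg)$probe))

  # capped-out distance counts as maximally specific
  dna <- base[1L, ]; dna$min_cross_distance <- NA_integer_
  expect_false(is.null(select_probe_for_gene(dna, cfg)$probe))

  expect_equal(select_probe_for_gene(base[0L, ], cfg)$reason, "too_short")
})

test_that("cross-species filter drops near-identical probes, keeps distant", {
  set.seed(25)
  cfg <- design_config(check_reverse_complement = FALSE)
  probe_seq <- rand_dna(60L)
  probes <- data.frame(probe_id = "g_0", gene_id = "g", start = 0L,
                       length = 60L, sequence = probe_seq,
                       min_cross_distance = NA_integer_,
                       nearest_nontarget = NA_character_,
                       dist_to_3prime = 100L, stringsAsFactors = FALSE)

  # identical window in the other species: removed
  other <- transcript_set(c(sq1 = paste0(rand_dna(30L), probe_seq)))
  res <- cross_species_filter(probes, other, cfg)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$removed$nearest_cross_species_gene, "sq1")

  # constructed target at oracle distance 12 (> 11): kept
  repeat {
    t12 <- paste0(rand_dna(20L), plant_substitutions(probe_seq, 12L),
                  rand_dna(20L))
    if (brute_force_infix_distance(probe_seq, t12) == 12L) break
  }
  res <- cross_species_filter(probes, transcript_set(c(sq = t12)), cfg)
  expect_equal(nrow(res$kept), 1L)

  # empty other species: no-op
  res <- cross_species_filter(probes, Biostrings::DNAStringSet(), cfg)
  expect_equal(nrow(res$kept), 1L)
})

test_that("exact-match counting sees both strands", {
  set.seed(26)
  probe <- rand_dna(30L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  tx <- transcript_set(c(src = paste0(rand_dna(10L), probe, rand_dna(10L)),
                         fwd = paste0(probe, rand_dna(20L)),
                         rev = paste0(rand_dna(20L), rc),
                         none = rand_dna(50L)))
  expect_equal(single_gene_check(probe, tx), 3L)
  expect_equal(single_gene_check(probe, tx, check_reverse_complement = FALSE),
               2L)
  expect_equal(single_gene_check(probe, tx["src"]), 1L)
})

test_that("the toy two-species design matches its hand trace", {
  toy <- toy_dataset(42L)
  rep <- design_array(toy$species_a, toy$species_b)

  expect_equal(rep$a$probes$gene_id, "refA")
  expect_equal(rep$a$probes$start, 200L)  # 3'-most window with margin > 20
  removed <- setNames(rep$a$removed$reason, rep$a$removed$gene_id)
  expect_equal(removed[["refShort"]], "too_short")
  expect_equal(removed[["refDup1"]], "no_specific_candidate")
  expect_equal(removed[["refDup2"]], "no_specific_candidate")
  expect_equal(removed[["refConflict"]], "cross_species_conflict")
  expect_equal(rep$a$removed$detail[rep$a$removed$gene_id == "refConflict"],
               "qryCarrier")
  expect_equal(nrow(rep$b$probes), 3L)

  # accounting identity per species
  for (sp in list(rep$a, rep$b)) {
    expect_equal(sp$counts[["input_genes"]],
                 nrow(sp$probes) + nrow(sp$removed))
    expect_equal(anyDuplicated(c(sp$probes$gene_id, sp$removed$gene_id)), 0L)
  }
})

test_that("identical duplicated genes are removed, design is deterministic", {
  set.seed(27)
  g <- rand_dna(200L)
  tx <- transcript_set(c(d1 = g, d2 = g, solo = rand_dna(200L)))
  rep <- design_array(tx)
  expect_setequal(rep$a$removed$gene_id, c("d1", "d2"))
  expect_true(all(rep$a$removed$reason == "no_specific_candidate"))
  expect_equal(rep$a$probes$gene_id, "solo")

  toy <- toy_dataset(42L)
  r1 <- design_array(toy$species_a, toy$species_b)
  r2 <- design_array(toy$species_a, toy$species_b)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_probe_table(r1$a$probes, p1)
  write_probe_table(r2$a$probes, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical tables
})

test_that("accepted probes satisfy every design invariant post hoc", {
  set.seed(28)
  tx <- random_transcripts(12L, sample(180:400, 12L, replace = TRUE))
  cfg <- design_config()
  rep <- design_array(tx)
  probes <- rep$a$probes
  expect_gt(nrow(probes), 0L)
  expect_equal(anyDuplicated(probes$gene_id), 0L)     # one probe per gene
  chars <- setNames(as.character(tx), names(tx))
  rcs <- setNames(as.character(Biostrings::reverseComplement(tx)), names(tx))
  for (i in seq_len(nrow(probes))) {
    expect_equal(nchar(probes$sequence[i]), cfg$probe_length)
    expect_gt(probes$dist_to_3prime[i], cfg$three_prime_margin)
    src <- chars[[probes$gene_id[i]]]
    expect_equal(substr(src, probes$start[i] + 1L,
                        probes$start[i] + cfg$probe_length),
                 probes$sequence[i])
    others <- setdiff(names(chars), probes$gene_id[i])
    d <- min(vapply(others, function(g) {
      min(brute_force_infix_distance(probes$sequence[i], chars[[g]]),
          brute_force_infix_distance(probes$sequence[i], rcs[[g]]))
    }, integer(1L)))
    expect_gt(d, cfg$distance_threshold)
    expect_equal(single_gene_check(probes$sequence[i], tx), 1L)
  }
})
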