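rec <- function(intensity, probe_id = sprintf("p%02d", seq_along(intensity)),
                sample_id = "head") {
  data.frame(probe_id = probe_id, sample_id = sample_id,
             intensity = intensity, detected = NA, stringsAsFactors = FALSE)
}

test_that("detection is a strict background + k*sd rule", {
  cfg <- call_config(detection_k = 2.6)
  r <- detect_expressed(rec(c(100, 100 + 2.6 * 10, 100 + 10 * 10, 99)),
                        background_mean = 100, background_sd = 10, cfg)
  expect_identical(r$detected, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("homolog candidacy is strictly above 1,000", {
  r <- call_homologs(rec(c(1001, 1000, 999, 50000)))
  expect_identical(r$is_homolog_candidate, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("known/new classification partitions the candidates exactly", {
  known <- data.frame(gene_id_species_A = sprintf("h%03d", 1:27),
                      gene_id_species_B = sprintf("s%03d", 1:27),
                      stringsAsFactors = FALSE)
  head_cand <- sprintf("h%03d", 1:94)   # 27 known among 94 candidates
  cls <- classify_known_new(head_cand, known)
  expect_equal(cls$n_known, 27L)
  expect_equal(cls$n_new, 67L)

  known25 <- known[1:25, ]
  body_cand <- sprintf("h%03d", 1:76)
  cls <- classify_known_new(body_cand, known25)
  expect_equal(cls$n_known, 25L)
  expect_equal(cls$n_new, 51L)

  expect_equal(cls$n_known + cls$n_new, length(body_cand))
  expect_length(intersect(cls$known, cls$new), 0L)

  cls <- classify_known_new(head_cand, NULL)
  expect_equal(cls$n_new, 94L)
})

test_that("detection percentages round to the printed integers", {
  expect_equal(detection_percentage(5435, 7987), 68)
  expect_equal(detection_percentage(5431, 7987), 68)
  expect_equal(detection_percentage(0, 100), 0)
  expect_equal(detection_percentage(100, 100), 100)
})

test_that("fold changes use the floored max/min ratio with direction", {
  cfg <- call_config(fold_change_min = 2, min_intensity_for_fc = 0)
  h <- rec(c(5000, 30000, 1200), sample_id = "head")
  b <- rec(c(5000, 3000, 12000), sample_id = "body")
  de <- differential_expression(h, b, cfg)
  # equal intensities -> fold change 1, excluded at min 2
  expect_false("p01" %in% de$probe_id)
  expect_equal(de$fold_change[de$probe_id == "p02"], 10)
  expect_equal(de$regulation[de$probe_id == "p02"], "up")
  expect_equal(de$fold_change[de$probe_id == "p03"], 10)
  expect_equal(de$regulation[de$probe_id == "p03"], "down")
  expect_equal(de$probe_id, c("p02", "p03"))  # sorted by fold change, then id

  # flooring damps ratios of weak signals
  cfg50 <- call_config(fold_change_min = 2, min_intensity_for_fc = 50)
  de50 <- differential_expression(h, b, cfg50)
  expect_equal(de50$fold_change[de50$probe_id == "p02"],
               30050 / 3050)
})

test_that("the differential list requires candidacy in some sample", {
  cfg <- call_config(fold_change_min = 2, min_intensity_for_fc = 0)
  h <- rec(c(900, 2000))
  b <- rec(c(90, 200))
  de <- differential_expression(h, b, cfg)
  expect_equal(de$probe_id, "p02")  # p01 never exceeds 1,000 in any sample
})

test_that("swapping the samples flips regulation, preserves fold change", {
  set.seed(41)
  h <- rec(runif(30, 0, 5e4))
  b <- rec(runif(30, 0, 5e4), sample_id = "body")
  cfg <- call_config(fold_change_min = 2)
  d1 <- differential_expression(h, b, cfg)
  d2 <- differential_expression(b, h, cfg)
  expect_equal(d1$probe_id, d2$probe_id)
  expect_equal(d1$fold_change, d2$fold_change)
  flip <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(flip[d1$regulation]), d2$regulation)
})

test_that("unpaired probes are dropped with a warning", {
  h <- rec(c(2000, 3000), probe_id = c("a", "b"))
  b <- rec(2000, probe_id = "a", sample_id = "body")
  expect_warning(de <- differential_expression(h, b, call_config()),
                 "one sample only")
  expect_false("b" %in% de$probe_id)
})

test_that("candidates are a subset of detected probes", {
  set.seed(42)
  cfg <- call_config()
  r <- rec(runif(200, 0, 3000))
  r <- detect_expressed(r, background_mean = 50, background_sd = 20, cfg)
  r <- call_homologs(r, cfg)
  expect_true(all(r$detected[r$is_homolog_candidate]))
})

test_that("venn regions agree with brute-force membership enumeration", {
  expect_equal(sum(venn_summary(c("a"), c("b"), c("c"))$count), 3L)
  v <- venn_summary(c("x", "a"), c("x", "b"), c("x", "c"))
  expect_equal(v$count[v$region == "A&B&C"], 1L)

  set.seed(43)
  for (i in 1:20) {
    ids <- sprintf("g%02d", 1:30)
    sets <- lapply(1:3, function(k) sample(ids, sample(0:30, 1L)))
    v <- venn_summary(sets[[1L]], sets[[2L]], sets[[3L]])
    # brute force: classify every id by its membership triple
    uni <- unique(unlist(sets))
    expect_equal(attr(v, "union_size"), length(uni))
    expect_equal(sum(v$count), length(uni))
    for (id in uni) {
      inset <- vapply(sets, function(s) id %in% s, logical(1L))
      region <- paste(c("A", "B", "C")[inset], collapse = "&")
      expect_gte(v$count[v$region == region], 1L)
    }
    counted <- vapply(v$region, function(rg) {
      members <- strsplit(rg, "&", fixed = TRUE)[[1L]]
      sum(vapply(uni, function(id) {
        inset <- c("A", "B", "C")[vapply(sets, function(s) id %in% s,
                                         logical(1L))]
        setequal(inset, members)
      }, logical(1L)))
    }, numeric(1L))
    expect_equal(unname(counted), v$count)
  }
})

test_that("species-B calls map into species-A space for the venn", {
  hom <- data.frame(gene_id_species_A = c("h1", "h2", "h3"),
                    gene_id_species_B = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  vs <- build_venn_sets(calls_a = c("h1", "h9"), calls_b = c("s2"),
                        homology_table = hom)
  expect_equal(vs$b_called_mapped, "h2")
  expect_setequal(vs$conserved, c("h1", "h2", "h3"))
})
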