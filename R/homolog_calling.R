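#' Detection calls from background statistics
#'
#' A probe is called detected in a sample when its intensity strictly
#' exceeds `background_mean + detection_k * background_sd`. This documented
#' rule stands in for the scanner vendor's proprietary "significant
#' expression" flag and is not claimed to reproduce it.
#'
#' @param records Intensity data frame (`probe_id`, `sample_id`,
#'   `intensity`, ...).
#' @param background_mean,background_sd Background statistics (>= 0).
#' @param config A [call_config()] supplying `detection_k`.
#' @return `records` with the `detected` column (re)set.
#' @export
detect_expressed <- function(records, background_mean, background_sd,
                             config = call_config()) {
  stopifnot(background_mean >= 0, background_sd >= 0)
  records$detected <- records$intensity >
    background_mean + config$detection_k * background_sd
  records
}

#' Call homolog candidates at the high-expression threshold
#'
#' Cross-hybridization to non-target genes dramatically reduces intensity,
#' so probes whose signal is high must be seeing a genuine homologous
#' target: records whose intensity strictly exceeds the homolog intensity
#' threshold (default 1,000 on the linear scale, about 10 bits of the
#' 20-bit range) are flagged as homolog candidates.
#'
#' @param records Intensity data frame (detection already applied).
#' @param config A [call_config()].
#' @param probes Optional probe table used to attach `gene_id`.
#' @return `records` with `is_homolog_candidate` (and `gene_id` when
#'   `probes` is given).
#' @export
call_homologs <- function(records, config = call_config(), probes = NULL) {
  records$is_homolog_candidate <-
    records$intensity > config$homolog_intensity_threshold
  if (!is.null(probes)) {
    records$gene_id <- probes$gene_id[match(records$probe_id,
                                            probes$probe_id)]
  }
  records
}

#' Split homolog candidates into known and newly identified
#'
#' @param candidates Character vector of candidate gene ids (species A).
#' @param known_table Data frame with column `gene_id_species_A` (as read by
#'   [read_known_homologs()]), or `NULL`/empty for no prior knowledge.
#' @return List with `n_known`, `n_new`, and the `known` / `new` id vectors
#'   (a disjoint, exhaustive partition of `candidates`).
#' @export
classify_known_new <- function(candidates, known_table = NULL) {
  candidates <- unique(candidates)
  known_ids <- if (is.null(known_table) || nrow(known_table) == 0L) {
    character()
  } else {
    known_table$gene_id_species_A
  }
  is_known <- candidates %in% known_ids
  list(n_known = sum(is_known), n_new = sum(!is_known),
       known = candidates[is_known], new = candidates[!is_known])
}

#' Detection percentage
#'
#' @param n_detected,n_total Counts (`n_total > 0`).
#' @return `100 * n_detected / n_total`, rounded to the nearest integer.
#' @export
detection_percentage <- function(n_detected, n_total) {
  stopifnot(n_total > 0)
  round(100 * n_detected / n_total)
}

#' Two-sample fold-change list
#'
#' Pairs head and body records by probe id, floors both intensities by
#' `min_intensity_for_fc` (guarding against near-zero denominators), and
#' reports `fold_change = max(h', b') / min(h', b')` with `regulation =
#' "up"` when head is higher and `"down"` when body is higher. The list is
#' restricted to probes that are a homolog candidate in at least one sample
#' and whose fold change reaches `fold_change_min`, sorted by descending
#' fold change. Probes present in only one sample are dropped with a
#' warning. Swapping the samples flips every regulation flag and preserves
#' every fold change.
#'
#' @param head_records,body_records Intensity data frames for the two
#'   samples.
#' @param config A [call_config()].
#' @param probes Optional probe table to attach `gene_id`.
#' @param annotations Optional annotation data frame (`gene_id`,
#'   `annotation`).
#' @return Data frame `probe_id`, `gene_id` (if available), `fold_change`,
#'   `regulation`, `annotation`, `intensity_head`, `intensity_body`.
#' @export
differential_expression <- function(head_records, body_records,
                                    config = call_config(), probes = NULL,
                                    annotations = NULL) {
  h <- head_records[, c("probe_id", "intensity")]
  b <- body_records[, c("probe_id", "intensity")]
  only <- c(setdiff(h$probe_id, b$probe_id), setdiff(b$probe_id, h$probe_id))
  if (length(only) > 0L) {
    warning(length(only), " probe(s) present in one sample only excluded: ",
            paste(utils::head(only, 3L), collapse = ", "),
            if (length(only) > 3L) ", ..." else "", call. = FALSE)
  }
  m <- merge(h, b, by = "probe_id", suffixes = c("_head", "_body"))
  floor_v <- config$min_intensity_for_fc
  hf <- m$intensity_head + floor_v
  bf <- m$intensity_body + floor_v
  fc <- pmax(hf, bf) / pmin(hf, bf)
  candidate <- pmax(m$intensity_head, m$intensity_body) >
    config$homolog_intensity_threshold
  keep <- candidate & fc >= config$fold_change_min
  out <- data.frame(probe_id = m$probe_id[keep],
                    fold_change = fc[keep],
                    regulation = ifelse(hf[keep] > bf[keep], "up", "down"),
                    intensity_head = m$intensity_head[keep],
                    intensity_body = m$intensity_body[keep],
                    stringsAsFactors = FALSE)
  out$regulation[hf[keep] == bf[keep]] <- "none"
  if (!is.null(probes)) {
    out$gene_id <- probes$gene_id[match(out$probe_id, probes$probe_id)]
  }
  if (!is.null(annotations) && !is.null(out$gene_id)) {
    out$annotation <- annotations$annotation[match(out$gene_id,
                                                   annotations$gene_id)]
  } else {
    out$annotation <- rep(NA_character_, nrow(out))
  }
  out[order(-out$fold_change, out$probe_id), , drop = FALSE]
}

#' Three-set Venn region counts
#'
#' Region counts for three gene-id sets (e.g. genes called highly expressed
#' by species-A probes, by species-B probes, and genes in a precomputed
#' sequence-homology list). The seven exclusive regions sum to the union
#' size.
#'
#' @param set_a,set_b,set_c Character vectors (duplicates ignored).
#' @param labels Length-3 labels used in the output.
#' @return Data frame with columns `region` (membership pattern like
#'   `"A&B"`) and `count`, plus an attribute `union_size`.
#' @export
venn_summary <- function(set_a, set_b, set_c,
                         labels = c("A", "B", "C")) {
  sets <- list(unique(set_a), unique(set_b), unique(set_c))
  all_ids <- unique(c(sets[[1L]], sets[[2L]], sets[[3L]]))
  member <- cbind(all_ids %in% sets[[1L]], all_ids %in% sets[[2L]],
                  all_ids %in% sets[[3L]])
  pattern <- apply(member, 1L, function(z) paste(labels[z], collapse = "&"))
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(labels, k, paste, collapse = "&")
  }))
  counts <- setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  out <- data.frame(region = combos, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(all_ids)
  out
}

#' Map species-B homolog calls into species-A gene space for a Venn
#'
#' Builds the three comparable gene sets: species-A genes called by A
#' probes; species-A genes whose known B partner was called by B probes; and
#' all species-A genes appearing in the sequence-homology table (the
#' "highly conserved" reference set).
#'
#' @param calls_a Character vector of called species-A gene ids.
#' @param calls_b Character vector of called species-B gene ids.
#' @param homology_table Data frame with `gene_id_species_A`,
#'   `gene_id_species_B`.
#' @return List of three character vectors `a_called`, `b_called_mapped`,
#'   `conserved`.
#' @export
build_venn_sets <- function(calls_a, calls_b, homology_table) {
  mapped <- homology_table$gene_id_species_A[
    homology_table$gene_id_species_B %in% calls_b]
  list(a_called = unique(calls_a), b_called_mapped = unique(mapped),
       conserved = unique(homology_table$gene_id_species_A))
}
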