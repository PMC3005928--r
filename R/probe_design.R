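#' Extract candidate probe windows from a transcript
#'
#' Tiles fixed-length windows over the transcript at regular intervals:
#' starts 0, `step`, `2*step`, ... while the window fits. Windows containing
#' `N` are discarded (their hybridization behaviour is undefined).
#' Coordinates are 0-based, half-open.
#'
#' @param sequence Transcript sequence (character scalar, normalised).
#' @param gene_id Source transcript id.
#' @param config A [design_config()].
#' @return Data frame with columns `gene_id`, `start`, `sequence`,
#'   `dist_to_3prime` (bp from the window's last base to the transcript's
#'   last base), ordered by ascending `start`. Empty for transcripts shorter
#'   than the probe length.
#' @export
extract_candidates <- function(sequence, gene_id, config = design_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  pl <- config$probe_length
  if (len < pl) {
    return(data.frame(gene_id = character(), start = integer(),
                      sequence = character(), dist_to_3prime = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, len - pl, by = config$step)
  windows <- substring(sequence, starts + 1L, starts + pl)
  keep <- !grepl("N", windows, fixed = TRUE)
  data.frame(gene_id = gene_id, start = starts[keep],
             sequence = windows[keep],
             dist_to_3prime = len - (starts[keep] + pl),
             stringsAsFactors = FALSE)[order(starts[keep]), , drop = FALSE]
}

# Precomputed screening context for a transcript set: sequences, reverse
# complements and q-gram sets, so repeated candidate screens share the work.
.screen_context <- function(transcripts, config) {
  tx <- .tx_chars(transcripts)
  tx <- tx[order(names(tx))]          # lexicographic id order => argmin ties
  ctx <- list(ids = names(tx), fwd = unname(tx), q = config$qgram_q,
              rc = NULL, fwd_q = NULL, rc_q = NULL,
              both = config$check_reverse_complement)
  ctx$fwd_q <- lapply(ctx$fwd, .qgram_set, q = ctx$q)
  if (ctx$both) {
    ctx$rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx$fwd)))
    ctx$rc_q <- lapply(ctx$rc, .qgram_set, q = ctx$q)
  }
  ctx
}

#' Minimum cross-gene edit distance of a candidate probe
#'
#' Screens a candidate against every transcript except its own source gene:
#' the minimum capped infix edit distance over all non-target transcripts
#' (both strands when `check_reverse_complement`), with the q-gram lower
#' bound used only to skip transcripts whose bound already exceeds the cap.
#' Ties on the nearest non-target are broken by the lexicographically
#' smallest gene id.
#'
#' @param sequence Candidate probe sequence.
#' @param transcripts Transcript set ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param exclude_gene Gene id excluded from the screen (its own source);
#'   `NULL` to screen against every transcript (cross-species use).
#' @param config A [design_config()]; `config$cap` caps the search.
#' @return List with `distance` (integer, `NA` when every non-target is
#'   beyond the cap), `nearest` (gene id of the argmin, `NA` when beyond the
#'   cap or the set is empty after exclusion) and `cap_exceeded` (logical).
#' @export
min_cross_distance <- function(sequence, transcripts, exclude_gene = NULL,
                               config = design_config()) {
  ctx <- .screen_context(transcripts, config)
  .min_cross_distance_ctx(sequence, ctx, exclude_gene, config$cap)
}

.min_cross_distance_ctx <- function(sequence, ctx, exclude_gene, cap) {
  probe_q <- .qgrams(sequence, ctx$q)
  best <- NA_integer_
  nearest <- NA_character_
  cur_cap <- cap
  for (k in seq_along(ctx$ids)) {
    if (!is.null(exclude_gene) && ctx$ids[k] == exclude_gene) next
    d <- NA_integer_
    if (.qgram_bound(probe_q, ctx$fwd_q[[k]], ctx$q) <= cur_cap) {
      r <- .infix_edit_cpp(sequence, ctx$fwd[k], cur_cap)
      if (r[1L] >= 0L) d <- r[1L]
    }
    if (ctx$both && (is.na(d) || d > 0L) &&
        .qgram_bound(probe_q, ctx$rc_q[[k]], ctx$q) <= cur_cap) {
      r <- .infix_edit_cpp(sequence, ctx$rc[k], cur_cap)
      if (r[1L] >= 0L && (is.na(d) || r[1L] < d)) d <- r[1L]
    }
    if (!is.na(d) && (is.na(best) || d < best)) {
      best <- d
      nearest <- ctx$ids[k]
      if (best == 0L) break
      cur_cap <- best - 1L   # only strictly closer genes can matter now
    }
  }
  list(distance = best, nearest = nearest, cap_exceeded = is.na(best))
}

#' Select the accepted probe for one gene
#'
#' Keeps candidates whose minimum cross-gene distance is strictly greater
#' than the threshold (a capped-out screen counts as passing, since the cap
#' is at least threshold + 1) and whose last base is strictly more than the
#' 3' margin from the transcript end; of the keepers, the 3'-most (largest
#' start) wins. Candidate starts within a gene are distinct, so the winner
#' is unique.
#'
#' @param candidates Data frame as from [extract_candidates()] with added
#'   columns `min_cross_distance` (integer, `NA` = cap exceeded) and
#'   `nearest_nontarget`.
#' @param config A [design_config()].
#' @return List with either `probe` (single-row probe-table data frame) or
#'   `reason` (`"too_short"` when there were no candidates,
#'   `"no_specific_candidate"` when none passed; such genes are the
#'   duplicated / multi-copy genes the screen removes).
#' @export
select_probe_for_gene <- function(candidates, config = design_config()) {
  if (nrow(candidates) == 0L) return(list(reason = "too_short"))
  pass <- (is.na(candidates$min_cross_distance) |
             candidates$min_cross_distance > config$distance_threshold) &
    candidates$dist_to_3prime > config$three_prime_margin
  if (!any(pass)) return(list(reason = "no_specific_candidate"))
  keep <- candidates[pass, , drop = FALSE]
  w <- keep[which.max(keep$start), , drop = FALSE]
  list(probe = data.frame(
    probe_id = paste0(w$gene_id, "_", w$start),
    gene_id = w$gene_id, start = w$start,
    length = config$probe_length, sequence = w$sequence,
    min_cross_distance = w$min_cross_distance,
    nearest_nontarget = w$nearest_nontarget,
    dist_to_3prime = w$dist_to_3prime, stringsAsFactors = FALSE))
}

#' Count transcripts containing an exact probe match
#'
#' Exact substring search over a transcript set, on the forward strand and
#' (optionally) the reverse complement. Each transcript counts at most once.
#' The design pipeline keeps a probe only when the count within its own
#' species is exactly 1 (its source gene).
#'
#' @param sequence Probe sequence.
#' @param transcripts Transcript set.
#' @param check_reverse_complement Also search the reverse complement.
#' @return Integer count of transcripts with an exact match.
#' @export
single_gene_check <- function(sequence, transcripts,
                              check_reverse_complement = TRUE) {
  tx <- Biostrings::DNAStringSet(.tx_chars(transcripts))
  hit <- Biostrings::vcountPattern(sequence, tx, fixed = TRUE) > 0L
  if (check_reverse_complement) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    hit <- hit | Biostrings::vcountPattern(rc, tx, fixed = TRUE) > 0L
  }
  sum(hit)
}

#' Remove probes too similar to the other species' transcripts
#'
#' A probe survives only when its minimum infix edit distance to every
#' transcript of the other species (both strands when configured) strictly
#' exceeds the design threshold, so near-identical probes cannot appear for
#' both species on the same array. Removed probes are returned with the
#' nearest cross-species gene.
#'
#' @param probes Probe-table data frame (already accepted within species).
#' @param other_species Transcript set of the other species (may be empty:
#'   the filter is then a no-op).
#' @param config A [design_config()].
#' @return List with `kept` (probe table) and `removed` (data frame
#'   `probe_id`, `gene_id`, `nearest_cross_species_gene`, `distance`).
#' @export
cross_species_filter <- function(probes, other_species,
                                 config = design_config()) {
  removed <- data.frame(probe_id = character(), gene_id = character(),
                        nearest_cross_species_gene = character(),
                        distance = integer(), stringsAsFactors = FALSE)
  if (length(other_species) == 0L || nrow(probes) == 0L) {
    return(list(kept = probes, removed = removed))
  }
  ctx <- .screen_context(other_species, config)
  drop <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    r <- .min_cross_distance_ctx(probes$sequence[i], ctx,
                                 exclude_gene = NULL, cap = config$cap)
    if (!r$cap_exceeded && r$distance <= config$distance_threshold) {
      drop[i] <- TRUE
      removed <- rbind(removed, data.frame(
        probe_id = probes$probe_id[i], gene_id = probes$gene_id[i],
        nearest_cross_species_gene = r$nearest, distance = r$distance,
        stringsAsFactors = FALSE))
    }
  }
  list(kept = probes[!drop, , drop = FALSE], removed = removed)
}

# full within-species design for one transcript set
.design_species <- function(transcripts, config) {
  tx <- .tx_chars(transcripts)
  ctx <- .screen_context(transcripts, config)
  probes <- list()
  removed <- list()
  for (gid in names(tx)) {
    cands <- extract_candidates(tx[[gid]], gid, config)
    if (nrow(cands) == 0L) {
      removed[[gid]] <- data.frame(gene_id = gid, reason = "too_short",
                                   detail = NA_character_,
                                   stringsAsFactors = FALSE)
      next
    }
    # evaluate candidates 3'-most first: the first one passing both the
    # margin and the distance screen is the selection (equivalent to
    # screening all candidates and then applying select_probe_for_gene)
    ord <- order(cands$start, decreasing = TRUE)
    sel <- NULL
    for (j in ord) {
      if (cands$dist_to_3prime[j] <= config$three_prime_margin) next
      scr <- .min_cross_distance_ctx(cands$sequence[j], ctx,
                                     exclude_gene = gid, cap = config$cap)
      if (scr$cap_exceeded || scr$distance > config$distance_threshold) {
        one <- cands[j, , drop = FALSE]
        one$min_cross_distance <- scr$distance
        one$nearest_nontarget <- scr$nearest
        sel <- select_probe_for_gene(one, config)$probe
        break
      }
    }
    if (is.null(sel)) {
      removed[[gid]] <- data.frame(gene_id = gid,
                                   reason = "no_specific_candidate",
                                   detail = NA_character_,
                                   stringsAsFactors = FALSE)
      next
    }
    n_exact <- single_gene_check(sel$sequence, tx,
                                 config$check_reverse_complement)
    if (n_exact != 1L) {
      removed[[gid]] <- data.frame(gene_id = gid, reason = "multi_copy_exact",
                                   detail = sprintf("exact matches: %d",
                                                    n_exact),
                                   stringsAsFactors = FALSE)
      next
    }
    probes[[gid]] <- sel
  }
  empty_removed <- data.frame(gene_id = character(), reason = character(),
                              detail = character(), stringsAsFactors = FALSE)
  list(probes = if (length(probes)) do.call(rbind, c(probes,
                                                     make.row.names = FALSE))
       else .empty_probe_table(),
       removed = if (length(removed)) do.call(rbind, c(removed,
                                                       make.row.names = FALSE))
       else empty_removed)
}

.empty_probe_table <- function() {
  data.frame(probe_id = character(), gene_id = character(),
             start = integer(), length = integer(), sequence = character(),
             min_cross_distance = integer(), nearest_nontarget = character(),
             dist_to_3prime = integer(), stringsAsFactors = FALSE)
}

#' Design a two-species homology-search array
#'
#' Runs the full procedure for each species: tile candidates, screen each
#' against all other genes of its own species, keep the 3'-most specific
#' candidate per gene, require the probe sequence to occur in exactly one
#' gene of its species, then remove probes within the distance threshold of
#' any transcript of the other species. Every input gene is accounted for:
#' it contributes exactly one accepted probe or appears in `removed` with a
#' reason (`too_short`, `no_specific_candidate`, `multi_copy_exact`,
#' `cross_species_conflict`).
#'
#' @param species_a,species_b Transcript sets; `species_b` may be empty
#'   (`NULL`), in which case the cross-species filter is a no-op.
#' @param config A [design_config()].
#' @return A list of class `design_report` with elements `a` and `b`, each a
#'   list of `probes` (probe table), `removed` (gene_id / reason / detail)
#'   and `counts` (named integer vector per stage).
#' @export
design_array <- function(species_a, species_b = NULL,
                         config = design_config()) {
  a <- .design_species(species_a, config)
  b <- if (is.null(species_b) || length(species_b) == 0L) {
    list(probes = .empty_probe_table(),
         removed = data.frame(gene_id = character(), reason = character(),
                              detail = character(), stringsAsFactors = FALSE))
  } else {
    .design_species(species_b, config)
  }
  xa <- cross_species_filter(a$probes, species_b, config)
  xb <- if (is.null(species_b) || length(species_b) == 0L) {
    list(kept = b$probes, removed = NULL)
  } else {
    cross_species_filter(b$probes, species_a, config)
  }
  finish <- function(within, crossed, n_input) {
    removed <- within$removed
    if (!is.null(crossed$removed) && nrow(crossed$removed) > 0L) {
      removed <- rbind(removed, data.frame(
        gene_id = crossed$removed$gene_id,
        reason = "cross_species_conflict",
        detail = crossed$removed$nearest_cross_species_gene,
        stringsAsFactors = FALSE))
    }
    counts <- c(input_genes = n_input,
                accepted = nrow(crossed$kept),
                too_short = sum(removed$reason == "too_short"),
                no_specific_candidate =
                  sum(removed$reason == "no_specific_candidate"),
                multi_copy_exact = sum(removed$reason == "multi_copy_exact"),
                cross_species_conflict =
                  sum(removed$reason == "cross_species_conflict"))
    list(probes = crossed$kept, removed = removed, counts = counts)
  }
  structure(list(
    a = finish(a, xa, length(.tx_chars(species_a))),
    b = finish(b, xb,
               if (is.null(species_b)) 0L else length(.tx_chars(species_b)))),
    class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  for (sp in c("a", "b")) {
    cat(sprintf("species %s: %d genes -> %d probes accepted\n", toupper(sp),
                x[[sp]]$counts[["input_genes"]],
                x[[sp]]$counts[["accepted"]]))
    rem <- x[[sp]]$counts[c("too_short", "no_specific_candidate",
                            "multi_copy_exact", "cross_species_conflict")]
    rem <- rem[rem > 0]
    if (length(rem)) {
      cat("  removed:", paste(sprintf("%s=%d", names(rem), rem),
                              collapse = ", "), "\n")
    }
  }
  invisible(x)
}
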