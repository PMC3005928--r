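#' Evolve a diverged ortholog of a sequence
#'
#' Per site, one of four mutually exclusive events: substitution to a
#' uniformly random different base (probability `substitution_rate`),
#' deletion of the site (`deletion_rate`), insertion of one uniformly random
#' base after the site (`insertion_rate`), or no change. A cheap stand-in
#' for hundreds of millions of years of divergence; no codon structure or
#' site heterogeneity. Uses the current RNG state -- seed beforehand (or via
#' [evolve_transcriptome()]) for reproducibility.
#'
#' @param sequence DNA character scalar.
#' @param config An [evolution_config()].
#' @return The diverged sequence (may be empty at extreme deletion rates).
#' @export
evolve_ortholog <- function(sequence, config = evolution_config()) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  if (n == 0L) return("")
  s <- config$substitution_rate
  d <- config$deletion_rate
  i <- config$insertion_rate
  u <- runif(n)
  sub <- u < s
  del <- !sub & u < s + d
  ins <- !sub & !del & u < s + d + i
  alphabet <- c("A", "C", "G", "T")
  if (any(sub)) {
    # uniformly random *different* base; N mutates to any of the four
    pick <- function(b) sample(setdiff(alphabet, b), 1L)
    bases[sub] <- vapply(bases[sub], pick, character(1L))
  }
  out <- bases
  out[del] <- ""
  if (any(ins)) {
    out[ins] <- paste0(out[ins], sample(alphabet, sum(ins), replace = TRUE))
  }
  paste(out, collapse = "")
}

#' Evolve a whole transcript set
#'
#' Applies [evolve_ortholog()] to every transcript, seeding the evolution
#' RNG stream from `config$rng_seed` so the diverged set is reproducible.
#' Gene ids are preserved (the ortholog of gene `g` is named `g`), which
#' keeps the truth mapping trivial in simulations.
#'
#' @param transcripts Transcript set.
#' @param config An [evolution_config()].
#' @param species Species label for the evolved set.
#' @return A [Biostrings::DNAStringSet] of diverged orthologs.
#' @export
evolve_transcriptome <- function(transcripts, config = evolution_config(),
                                 species = "evolved") {
  tx <- .tx_chars(transcripts)
  set.seed(config$rng_seed)
  out <- vapply(tx, evolve_ortholog, character(1L), config = config)
  transcript_set(out, ids = names(tx), species = species)
}

# deterministic part of the signal model
.expected_signal <- function(expression_scalar, distance, model) {
  if (is.na(distance)) 0 else
    expression_scalar * model$amplitude * exp(-model$decay_k * distance)
}

# mean-1 lognormal noise factor with coefficient of variation cv
.lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate one probe x sample intensity
#'
#' The probe's best expressed target determines the signal: `d` is the
#' minimum infix edit distance from the probe to any transcript in the pool
#' (capped at `model$distance_cap`; beyond it the probe sees background
#' only). Expected signal is `expression_scalar * amplitude * exp(-decay_k *
#' d)` plus Gaussian additive background; the observed intensity multiplies
#' in mean-1 lognormal noise and is clipped to `[0, 2^20]`. Uses the current
#' RNG state.
#'
#' @param probe_sequence Probe sequence.
#' @param target_pool Transcript set of expressed targets (may be empty:
#'   background-only signal).
#' @param expression_scalar Expression level of the best target (>= 0).
#' @param model A [signal_model()].
#' @return List with `intensity` (observed), `distance` (best target
#'   distance, `NA` when beyond the cap or the pool is empty) and `target`
#'   (id of the best target or `NA`).
#' @export
simulate_intensity <- function(probe_sequence, target_pool = NULL,
                               expression_scalar = 1,
                               model = signal_model()) {
  d <- NA_integer_
  target <- NA_character_
  if (!is.null(target_pool) && length(target_pool) > 0L) {
    cfg <- design_config(probe_length = nchar(probe_sequence),
                         distance_threshold = 0L,
                         cap = model$distance_cap,
                         qgram_q = min(11L, nchar(probe_sequence)),
                         check_reverse_complement = FALSE)
    r <- min_cross_distance(probe_sequence, target_pool,
                            exclude_gene = NULL, config = cfg)
    d <- r$distance
    target <- r$nearest
  }
  expected <- .expected_signal(expression_scalar, d, model) +
    max(0, rnorm(1L, model$background_mean, model$background_sd))
  obs <- expected * .lognormal_factor(1L, model$noise_cv)
  list(intensity = min(max(obs, 0), model$ceiling), distance = d,
       target = target)
}

#' Generate a full synthetic two-sample array experiment
#'
#' Evolves a diverged ortholog set from `species_a` (once per gene), applies
#' the per-gene, per-sample expression scalars of the experiment design, and
#' simulates intensities for every probe in both samples ("head" and
#' "body"). Three independent RNG streams -- evolution, expression and noise
#' -- are seeded from `master_seed` (as `master_seed + 1/2/3`, reduced mod
#' 2^31 - 1), so each stage is independently reproducible.
#'
#' For each probe and sample, the signal target is the expressed transcript
#' (scalar > 0 in that sample) at minimum infix edit distance from the
#' probe, within `model$distance_cap`; its expression scalar drives the
#' expected signal. Ties go to the lexicographically smallest gene id.
#'
#' @param species_a Transcript set probes were designed from.
#' @param probes_a Probe table for species A.
#' @param probes_b Optional probe table for species B (designed from a
#'   previously evolved set with the same seeds).
#' @param evolution An [evolution_config()] (its `rng_seed` is overridden by
#'   the derived stream seed).
#' @param design An [experiment_design()] over the gene ids of `species_a`,
#'   or `NULL` for all genes expressed at scalar 1.
#' @param model A [signal_model()].
#' @param species_b Optional pre-evolved ortholog set (skips evolution;
#'   must be named by the same gene ids).
#' @param master_seed Integer master seed.
#' @return List with `species_b` (diverged ortholog [Biostrings::DNAStringSet]),
#'   `intensities` (data frame `probe_id`, `sample_id`, `intensity`,
#'   `detected`), and `truth` (design truth table joined with each A probe's
#'   true distance to its own ortholog).
#' @export
generate_experiment <- function(species_a, probes_a, probes_b = NULL,
                                evolution = evolution_config(),
                                design = NULL, model = signal_model(),
                                species_b = NULL, master_seed = 1L) {
  tx_a <- .tx_chars(species_a)
  seeds <- (as.numeric(master_seed) + 1:3) %% (2^31 - 1)
  if (is.null(species_b)) {
    evolution$rng_seed <- as.integer(seeds[1L])
    species_b <- evolve_transcriptome(species_a, evolution,
                                      species = "species_b")
  }
  tx_b <- .tx_chars(species_b)
  if (is.null(design)) {
    design <- experiment_design(names(tx_a), expressed_fraction = 1,
                                n_differential = 0L,
                                rng_seed = as.integer(seeds[2L]))
  }
  truth <- design$truth
  probes <- rbind(probes_a[, .probe_table_cols],
                  if (!is.null(probes_b)) probes_b[, .probe_table_cols])

  # capped distances probe -> every ortholog, computed once (sample
  # independent); stored sparse as (probe, gene, distance) triples
  cfg <- design_config(probe_length = max(probes$length),
                       distance_threshold = 0L, cap = model$distance_cap,
                       qgram_q = 11L, check_reverse_complement = FALSE)
  ctx <- .screen_context(species_b, cfg)
  hits <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    probe_q <- .qgrams(probes$sequence[i], ctx$q)
    ds <- rep(NA_integer_, length(ctx$ids))
    for (k in seq_along(ctx$ids)) {
      if (.qgram_bound(probe_q, ctx$fwd_q[[k]], ctx$q) > cfg$cap) next
      r <- .infix_edit_cpp(probes$sequence[i], ctx$fwd[k], cfg$cap)
      if (r[1L] >= 0L) ds[k] <- r[1L]
    }
    hits[[i]] <- ds
  }

  scal <- list(head = setNames(truth$scalar_head, truth$gene_id),
               body = setNames(truth$scalar_body, truth$gene_id))
  set.seed(as.integer(seeds[3L]))
  rows <- vector("list", 2L * nrow(probes))
  ri <- 0L
  for (sample_id in c("head", "body")) {
    sc <- scal[[sample_id]][ctx$ids]
    sc[is.na(sc)] <- 0
    expressed <- sc > 0
    for (i in seq_len(nrow(probes))) {
      ds <- hits[[i]]
      cand <- which(expressed & !is.na(ds))
      if (length(cand) > 0L) {
        best <- cand[which.min(ds[cand])]  # first index = smallest id on tie
        expected <- .expected_signal(sc[best], ds[best], model)
      } else {
        expected <- 0
      }
      expected <- expected + max(0, rnorm(1L, model$background_mean,
                                          model$background_sd))
      obs <- expected * .lognormal_factor(1L, model$noise_cv)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(probe_id = probes$probe_id[i],
                               sample_id = sample_id,
                               intensity = min(max(obs, 0), model$ceiling),
                               stringsAsFactors = FALSE)
    }
  }
  intensities <- do.call(rbind, rows)
  intensities$detected <- intensities$intensity >
    model$background_mean + call_config()$detection_k * model$background_sd

  # true distance of each A probe to its own gene's ortholog
  own <- rep(NA_integer_, nrow(probes_a))
  for (i in seq_len(nrow(probes_a))) {
    k <- match(probes_a$gene_id[i], ctx$ids)
    if (!is.na(k)) own[i] <- hits[[i]][k]
  }
  truth <- merge(truth,
                 data.frame(gene_id = probes_a$gene_id,
                            probe_id = probes_a$probe_id,
                            true_distance = own, stringsAsFactors = FALSE),
                 by = "gene_id", all.x = TRUE, sort = TRUE)
  list(species_b = species_b, intensities = intensities, truth = truth)
}
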