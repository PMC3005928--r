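#' Probe-design configuration
#'
#' Defaults follow the array-design procedure: 60 bp probes (the vendor
#' oligo length) tiled every 50 bp, kept only when the minimum edit distance
#' to every non-target gene is strictly greater than 11 and the probe's last
#' base lies strictly more than 20 bp from the transcript's 3' end.
#'
#' @param probe_length Probe window length in bp.
#' @param step Tiling interval in bp between candidate starts.
#' @param distance_threshold Specificity threshold: a candidate survives only
#'   when its minimum cross-gene infix edit distance is strictly greater
#'   than this.
#' @param three_prime_margin A candidate's last base must be strictly more
#'   than this many bp from the transcript 3' end.
#' @param cap Early-exit cap for the screening distance; must be at least
#'   `distance_threshold + 1` so that "cap exceeded" always implies "passes
#'   the threshold".
#' @param qgram_q q-gram length for the prefilter lower bound.
#' @param check_reverse_complement Screen both strands (specificity and
#'   exact-match checks consider a transcript and its reverse complement).
#' @return A list of class `design_config`.
#' @export
design_config <- function(probe_length = 60L, step = 50L,
                          distance_threshold = 11L, three_prime_margin = 20L,
                          cap = distance_threshold + 1L, qgram_q = 11L,
                          check_reverse_complement = TRUE) {
  probe_length <- as.integer(probe_length)
  step <- as.integer(step)
  distance_threshold <- as.integer(distance_threshold)
  three_prime_margin <- as.integer(three_prime_margin)
  cap <- as.integer(cap)
  qgram_q <- as.integer(qgram_q)
  stopifnot(probe_length > 0L, step > 0L, distance_threshold >= 0L,
            three_prime_margin >= 0L, qgram_q >= 1L,
            qgram_q <= probe_length, is.logical(check_reverse_complement))
  if (cap < distance_threshold + 1L) {
    stop("cap must be >= distance_threshold + 1", call. = FALSE)
  }
  structure(list(probe_length = probe_length, step = step,
                 distance_threshold = distance_threshold,
                 three_prime_margin = three_prime_margin, cap = cap,
                 qgram_q = qgram_q,
                 check_reverse_complement = check_reverse_complement),
            class = "design_config")
}

#' Homolog-calling configuration
#'
#' @param homolog_intensity_threshold Linear intensity above which (strictly)
#'   a detected probe is called a homolog candidate. Default 1,000, about
#'   10 bits on the scanner's 20-bit range.
#' @param detection_k Number of background standard deviations above the
#'   background mean for the detection call.
#' @param fold_change_min Smallest fold change reported in the differential
#'   list.
#' @param min_intensity_for_fc Floor added to both intensities before the
#'   ratio, preventing blow-ups at near-zero signal; defaults to the signal
#'   model's background mean.
#' @return A list of class `call_config`.
#' @export
call_config <- function(homolog_intensity_threshold = 1000,
                        detection_k = 2.6, fold_change_min = 2,
                        min_intensity_for_fc = 50) {
  stopifnot(homolog_intensity_threshold > 0, detection_k >= 0,
            fold_change_min >= 1, min_intensity_for_fc >= 0)
  structure(list(homolog_intensity_threshold = homolog_intensity_threshold,
                 detection_k = detection_k,
                 fold_change_min = fold_change_min,
                 min_intensity_for_fc = min_intensity_for_fc),
            class = "call_config")
}

#' Hybridization signal model
#'
#' Expected linear signal for a probe whose best expressed target lies at
#' infix edit distance `d` is `scalar * amplitude * exp(-decay_k * d)` plus
#' Gaussian additive background; the observed value is the expected value
#' times a mean-1 lognormal noise factor, clipped to the scanner's 20-bit
#' ceiling. The exponential decay is a deliberate, documented stand-in for
#' hybridization thermodynamics; the default `decay_k` puts a target at
#' distance 11 below 5% of full signal, i.e. the specificity threshold is
#' strong enough to kill cross-hybridization in the simulation.
#'
#' @param amplitude Expected linear intensity at distance 0 and expression
#'   scalar 1. The default places the bulk of genuine homolog signal at
#'   10--15 bits of the 20-bit range: a strongly expressed, perfectly
#'   conserved target saturates, cross-hybridizing non-targets (distance
#'   above the design threshold) stay below the 1,000-intensity homolog
#'   cutoff, and hundred-fold expression changes remain measurable inside
#'   the dynamic range.
#' @param decay_k Per-edit exponential signal decay (>= 0).
#' @param background_mean,background_sd Additive Gaussian background
#'   (negative draws are clipped at 0).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise.
#' @param ceiling Saturation ceiling (2^20, the scanner dynamic range).
#' @param distance_cap Distances beyond this contribute background only
#'   (signal there is far below the background mean at the default decay).
#' @return A list of class `signal_model`.
#' @export
signal_model <- function(amplitude = 2e4, decay_k = 0.3,
                         background_mean = 50, background_sd = 20,
                         noise_cv = 0.2, ceiling = 2^20,
                         distance_cap = 25L) {
  stopifnot(amplitude > 0, decay_k >= 0, background_mean >= 0,
            background_sd >= 0, noise_cv >= 0, ceiling > 0, distance_cap >= 0)
  structure(list(amplitude = amplitude, decay_k = decay_k,
                 background_mean = background_mean,
                 background_sd = background_sd, noise_cv = noise_cv,
                 ceiling = ceiling, distance_cap = as.integer(distance_cap)),
            class = "signal_model")
}

#' Ortholog-evolution configuration
#'
#' Per-site mutually exclusive events: substitution to a uniformly random
#' different base, site deletion, or insertion of one random base after the
#' site. Rates must sum to less than 1. The defaults emulate a conserved
#' coding gene in a pair of anciently diverged species: divergence large
#' enough to be visible to a 60-mer (about 6 substitutions per probe window)
#' but small enough that homologous targets still hybridize.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-site event
#'   probabilities in `[0, 1]`.
#' @param rng_seed Integer seed for the evolution RNG stream.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(substitution_rate = 0.10,
                             insertion_rate = 0.01, deletion_rate = 0.01,
                             rng_seed = 1L) {
  stopifnot(substitution_rate >= 0, insertion_rate >= 0, deletion_rate >= 0,
            substitution_rate + insertion_rate + deletion_rate <= 1)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "evolution_config")
}

#' Two-sample experiment design
#'
#' Draws per-gene expression scalars for the two samples ("head" and
#' "body"). A gene is expressed in a sample with probability
#' `expressed_fraction`; expressed genes get a lognormal baseline scalar. A
#' designated subset is differentially expressed: its scalar in one sample
#' (alternating up-in-head / up-in-body) is multiplied by `fold_change`.
#' The returned truth table records the designated fold change exactly as
#' the ratio of the two scalars.
#'
#' @param gene_ids Character vector of gene ids.
#' @param expressed_fraction Probability a gene is expressed (applied to
#'   both samples jointly so an expressed gene has signal in both).
#' @param n_differential Number of designated differentially expressed
#'   genes (drawn from the expressed genes).
#' @param fold_change Target fold change for designated genes (>= 1).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline expression scalar.
#' @param rng_seed Integer seed for the expression RNG stream.
#' @return A list of class `experiment_design` with elements `truth` (data
#'   frame: `gene_id`, `scalar_head`, `scalar_body`, `true_fold_change`,
#'   `direction`, `is_differential`) and the call parameters.
#' @export
experiment_design <- function(gene_ids, expressed_fraction = 1,
                              n_differential = 0L, fold_change = 100,
                              baseline_meanlog = 0, baseline_sdlog = 1,
                              rng_seed = 2L) {
  stopifnot(length(gene_ids) >= 1L, expressed_fraction >= 0,
            expressed_fraction <= 1, fold_change >= 1,
            n_differential >= 0L)
  n <- length(gene_ids)
  set.seed(as.integer(rng_seed))
  expressed <- runif(n) < expressed_fraction
  base <- exp(rnorm(n, baseline_meanlog, baseline_sdlog)) * expressed
  head_s <- base
  body_s <- base
  de_idx <- integer()
  if (n_differential > 0L) {
    pool <- which(expressed)
    if (length(pool) < n_differential) {
      stop("fewer expressed genes than n_differential", call. = FALSE)
    }
    de_idx <- sort(sample(pool, n_differential))
    up_in_head <- rep_len(c(TRUE, FALSE), n_differential)
    head_s[de_idx[up_in_head]] <- head_s[de_idx[up_in_head]] * fold_change
    body_s[de_idx[!up_in_head]] <- body_s[de_idx[!up_in_head]] * fold_change
  }
  fc <- ifelse(pmin(head_s, body_s) > 0,
               pmax(head_s, body_s) / pmin(head_s, body_s),
               ifelse(pmax(head_s, body_s) > 0, Inf, 1))
  truth <- data.frame(
    gene_id = gene_ids,
    scalar_head = head_s,
    scalar_body = body_s,
    true_fold_change = fc,
    direction = ifelse(head_s > body_s, "up",
                       ifelse(body_s > head_s, "down", "none")),
    is_differential = seq_len(n) %in% de_idx,
    stringsAsFactors = FALSE)
  structure(list(truth = truth, expressed_fraction = expressed_fraction,
                 n_differential = as.integer(n_differential),
                 fold_change = fold_change, rng_seed = as.integer(rng_seed)),
            class = "experiment_design")
}

#' Load a key-value configuration file
#'
#' YAML key-value file whose keys match the arguments of [design_config()],
#' [call_config()], [signal_model()] and [evolution_config()]. Unknown keys
#' are an error; omitted keys take the documented defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list of values taking precedence over the file.
#' @return List with elements `design`, `call`, `signal`, `evolution` and
#'   `raw` (the merged flat key-value list).
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- unique(c(names(formals(design_config)),
                    names(formals(call_config)),
                    names(formals(signal_model)),
                    names(formals(evolution_config))))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pick <- function(fn) {
    args <- vals[intersect(names(vals), names(formals(fn)))]
    do.call(fn, args)
  }
  list(design = pick(design_config), call = pick(call_config),
       signal = pick(signal_model), evolution = pick(evolution_config),
       raw = vals)
}
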