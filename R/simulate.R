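# Synthetic two-compartment microarray data with planted 3'-terminal
# fragment secretion. The generator emulates the regime of the analyzed
# array data: transcript lengths lognormal in [400, 12000] nt centered
# near 2100 nt, several non-overlapping 60-mer probes per transcript,
# lognormal cellular intensities with multiplicative replicate noise and
# an additive array background, and a secretion process in which a
# 3'-terminal fragment of each "fragmented" transcript is exported with
# elevated efficiency while the remainder leaks weakly.

#' Simulation configuration
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param n_transcripts Number of transcripts.
#' @param length_log_mean,length_log_sd Lognormal law for transcript length
#'   (nt), truncated to `[length_min, length_max]`. Defaults center the
#'   median near 2100 nt.
#' @param length_min,length_max Truncation bounds (nt).
#' @param utr5_frac,utr3_frac Fractions of the transcript length given to
#'   the 5' and 3' UTRs; the CDS takes the rest.
#' @param probes_min,probes_max Per-transcript probe count range; the draw
#'   is capped at what fits without overlap, and a transcript too short for
#'   even `probes_min` probes raises a generation error.
#' @param probes_weights Sampling weights over `probes_min:probes_max`;
#'   `NULL` for uniform. The default `c(0.9, 0.1)` over 2:3 mirrors
#'   expression-array designs in which most transcripts carry two probes.
#' @param probe_width Probe footprint in nt (default 60).
#' @param n_exosome_samples,n_cell_samples Replicates per compartment.
#' @param frag_prob Probability a transcript is fragmented (3'-terminal
#'   fragment exported).
#' @param bias_beta 3'-bias strength, >= 0. The fragment breakpoint is
#'   Beta(1 + 12 b, 1 + 10.8 b) on relative coordinates: 0 gives uniform
#'   breakpoints (diffuse positional signal), larger values concentrate
#'   them just 3' of the midpoint, sharpening the planted 3'-terminal
#'   export signal.
#' @param secretion_gain Median exosome/cell gain applied to exported
#'   material (> 1).
#' @param gain_log_sd Per-transcript lognormal spread (log scale) of the
#'   secretion gain; models variable secretion efficiency.
#' @param leak Residual exosomal abundance of non-exported material,
#'   relative to its cellular level (in `[0, 1)`).
#' @param noise_sd Multiplicative lognormal replicate noise, sd on the
#'   natural-log scale.
#' @param intact_secreted_prob Among non-fragmented transcripts, the
#'   probability of intact (whole-transcript) secretion; the rest are not
#'   secreted.
#' @param baseline_log_mean,baseline_log_sd Lognormal law for the cellular
#'   baseline intensity per transcript (arbitrary linear units).
#' @param probe_eff_log_sd Lognormal spread of per-probe hybridization
#'   efficiency.
#' @param background_frac Additive array background for every measurement,
#'   as a fraction of the median baseline intensity; gives weakly expressed
#'   probes near-unit enrichment ratios, as on real arrays. Set 0 for a
#'   noise-floor-free idealization.
#' @param probe_ratio_sd Lognormal spread (log scale) of a probe-specific
#'   exosome/cell ratio bias: probe-level hybridization effects that do
#'   not cancel between compartments. Set 0 for perfectly paired channels.
#' @param normalize If `TRUE` (default), exosome intensities are rescaled
#'   so the median per-probe mean-intensity ratio is 1, as standard
#'   between-array normalization does on processed data.
#' @param utr3_only If `TRUE`, breakpoints are confined to the 3' UTR, so
#'   only UTR probes carry the positional secretion signal.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 2000L,
                       length_log_mean = log(2100),
                       length_log_sd = 0.55,
                       length_min = 400L,
                       length_max = 12000L,
                       utr5_frac = 0.10,
                       utr3_frac = 0.35,
                       probes_min = 2L,
                       probes_max = 3L,
                       probes_weights = c(0.9, 0.1),
                       probe_width = 60L,
                       n_exosome_samples = 3L,
                       n_cell_samples = 3L,
                       frag_prob = 0.7,
                       bias_beta = 5,
                       secretion_gain = 8,
                       gain_log_sd = 0.5,
                       leak = 0.25,
                       noise_sd = 0.2,
                       intact_secreted_prob = 0.35,
                       baseline_log_mean = log(200),
                       baseline_log_sd = 1.2,
                       probe_eff_log_sd = 0.4,
                       background_frac = 0.15,
                       probe_ratio_sd = 0.45,
                       normalize = TRUE,
                       utr3_only = FALSE) {
  cfg <- as.list(environment())
  check <- function(ok, what) if (!ok) config_error(paste0("sim_config: ", what))
  check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
        "seed must be a finite number")
  check(n_transcripts >= 1, "n_transcripts >= 1")
  check(length_min >= 100 && length_min < length_max,
        "100 <= length_min < length_max")
  check(utr5_frac > 0 && utr3_frac > 0 && utr5_frac + utr3_frac < 1,
        "utr5_frac, utr3_frac in (0,1) with sum < 1")
  check(probes_min >= 2 && probes_min <= probes_max,
        "2 <= probes_min <= probes_max")
  check(is.null(probes_weights) ||
          (length(probes_weights) == probes_max - probes_min + 1 &&
             all(probes_weights >= 0) && sum(probes_weights) > 0),
        "probes_weights must match the probe-count range")
  check(probe_width >= 1, "probe_width >= 1")
  check(n_exosome_samples >= 1 && n_cell_samples >= 1,
        "at least one sample per compartment")
  check(frag_prob >= 0 && frag_prob <= 1, "frag_prob in [0,1]")
  check(bias_beta >= 0, "bias_beta >= 0")
  check(secretion_gain > 1, "secretion_gain > 1")
  check(gain_log_sd >= 0, "gain_log_sd >= 0")
  check(leak >= 0 && leak < 1, "leak in [0,1)")
  check(noise_sd >= 0, "noise_sd >= 0")
  check(intact_secreted_prob >= 0 && intact_secreted_prob <= 1,
        "intact_secreted_prob in [0,1]")
  check(background_frac >= 0, "background_frac >= 0")
  check(probe_ratio_sd >= 0, "probe_ratio_sd >= 0")
  structure(cfg, class = "sim_config")
}

# run code under a derived seed without disturbing the caller's RNG state
with_sim_seed <- function(seed, offset, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% 2147483629L)
  force(code)
}

#' Simulate transcript models and probe placements
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (transcript model tibble) and
#'   `mappings` (annotated probe tibble).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 0L, {
    n <- config$n_transcripts
    len <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {  # rejection sampling for the truncation
      draw <- stats::rlnorm(length(todo), config$length_log_mean,
                            config$length_log_sd)
      ok <- draw >= config$length_min & draw <= config$length_max
      len[todo[ok]] <- round(draw[ok])
      todo <- todo[!ok]
    }
    ids <- sprintf("T%05d", seq_len(n))
    cds_start <- round(config$utr5_frac * len)
    cds_end <- len - round(config$utr3_frac * len)
    transcripts <- tibble::tibble(
      transcript_id = ids, length = len,
      cds_start = cds_start, cds_end = cds_end
    )
    transcripts <- validate_transcript_models(transcripts)

    w <- config$probe_width
    k_cap <- floor(len / (w + 1))
    short <- which(k_cap < config$probes_min)
    if (length(short) > 0) {
      abort_exofrag(paste0("transcript '", ids[short[1]], "' (", len[short[1]],
                           " nt) cannot fit ", config$probes_min,
                           " non-overlapping probes"),
                    "exofrag_generation_error")
    }
    k_range <- config$probes_min:config$probes_max
    k <- if (length(k_range) == 1) {
      rep(k_range, n)
    } else {
      sample(k_range, n, replace = TRUE, prob = config$probes_weights)
    }
    k <- pmin(k, k_cap)
    # stratified-uniform placement: probe i uniform within the i-th of k
    # equal strata, which scatters probes along the transcript without
    # overlap (coverage-style design)
    tx_idx <- rep(seq_len(n), k)
    probe_rank <- sequence(k)
    kk <- k[tx_idx]
    ll <- len[tx_idx]
    lo <- floor((probe_rank - 1) * ll / kk)
    hi <- floor(probe_rank * ll / kk) - w
    start <- lo + floor(stats::runif(length(probe_rank)) * (hi - lo + 1))
    probes <- tibble::tibble(
      probe_id = sprintf("%s_p%02d", ids[tx_idx], probe_rank),
      transcript_id = ids[tx_idx],
      start = start,
      end = start + w
    )
    list(transcripts = transcripts,
         mappings = annotate_probes(probes, transcripts))
  })
}

#' Simulate two-compartment expression with planted fragment secretion
#'
#' Cellular intensity of a probe is transcript baseline x probe efficiency
#' x replicate noise, plus additive background. Each transcript is
#' fragmented (probability `frag_prob`; a 3'-terminal fragment from a
#' Beta-distributed breakpoint is exported at the transcript's secretion
#' gain while the 5' remainder leaks), intact-secreted (gain applied to
#' the whole transcript) or not secreted (leak only).
#'
#' @param transcripts,mappings Output of [simulate_transcriptome()].
#' @param config The same [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (per-probe tibble: `transcript_id`, `probe_id`, `fragmented`,
#'   `breakpoint`, `secretion_gain_applied`, `in_fragment`).
#' @export
simulate_expression <- function(transcripts, mappings, config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 1L, {
    n_tx <- nrow(transcripts)
    tx_idx <- match(mappings$transcript_id, transcripts$transcript_id)

    status_u <- stats::runif(n_tx)
    fragmented <- status_u < config$frag_prob
    intact_secreted <- !fragmented &
      (status_u - config$frag_prob) / (1 - config$frag_prob + 1e-12) <
        config$intact_secreted_prob

    b <- config$bias_beta
    bp <- ifelse(fragmented,
                 stats::rbeta(n_tx, 1 + 12 * b, 1 + 10.8 * b), 0)
    if (config$utr3_only) {
      utr_start <- transcripts$cds_end / transcripts$length
      bp <- ifelse(fragmented, utr_start + bp * (1 - utr_start), 0)
    }
    gain_tx <- config$secretion_gain *
      stats::rlnorm(n_tx, 0, config$gain_log_sd)
    gain_applied <- ifelse(fragmented | intact_secreted, gain_tx, NA_real_)

    in_fragment <- ifelse(fragmented[tx_idx],
                          mappings$relative_location >= bp[tx_idx],
                          intact_secreted[tx_idx])
    probe_factor <- ifelse(in_fragment, gain_tx[tx_idx], config$leak)

    baseline <- stats::rlnorm(n_tx, config$baseline_log_mean,
                              config$baseline_log_sd)
    eff <- stats::rlnorm(nrow(mappings), 0, config$probe_eff_log_sd)
    signal_cell <- baseline[tx_idx] * eff
    bg <- config$background_frac * exp(config$baseline_log_mean)

    n_e <- config$n_exosome_samples
    n_c <- config$n_cell_samples
    n_p <- nrow(mappings)
    noise <- function(nc) matrix(stats::rlnorm(n_p * nc, 0, config$noise_sd),
                                 n_p, nc)
    # probe-specific exosome/cell ratio variability: hybridization biases
    # do not cancel exactly between compartments on real arrays
    ratio_noise <- stats::rlnorm(n_p, 0, config$probe_ratio_sd)
    exo <- signal_cell * probe_factor * ratio_noise * noise(n_e) +
      bg * noise(n_e)
    cel <- signal_cell * noise(n_c) + bg * noise(n_c)
    if (config$normalize) {
      # median-ratio normalization, as applied to processed two-compartment
      # array data: centres the per-probe mean-intensity ratio at 1
      med <- stats::median(rowMeans(exo) / rowMeans(cel))
      exo <- exo / med
    }
    values <- cbind(exo, cel)
    rownames(values) <- mappings$probe_id
    colnames(values) <- c(sprintf("exo%02d", seq_len(n_e)),
                          sprintf("cell%02d", seq_len(n_c)))
    groups <- stats::setNames(rep(c("exosome", "cell"), c(n_e, n_c)),
                              colnames(values))
    truth <- tibble::tibble(
      transcript_id = mappings$transcript_id,
      probe_id = mappings$probe_id,
      fragmented = fragmented[tx_idx],
      breakpoint = bp[tx_idx],
      secretion_gain_applied = gain_applied[tx_idx],
      in_fragment = in_fragment
    )
    list(matrix = expression_matrix(values, groups), truth = truth)
  })
}

#' One-call simulation of a complete dataset
#'
#' @param config A [sim_config()].
#' @return List with `transcripts`, `mappings`, `matrix`, `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  tr <- simulate_transcriptome(config)
  ex <- simulate_expression(tr$transcripts, tr$mappings, config)
  list(transcripts = tr$transcripts, mappings = tr$mappings,
       matrix = ex$matrix, truth = ex$truth, config = config)
}

#' Write a simulated dataset as the pipeline's input files
#'
#' Writes `transcripts.tsv`, `probes.tsv`, `expression.tsv`, `groups.tsv`
#' and `truth.tsv` in the formats the readers expect, so a generated
#' dataset round-trips through the file interface.
#'
#' @param sim Output of [simulate_dataset()].
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(sim, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    readr::write_tsv(df, file.path(directory, name), progress = FALSE)
  }
  wtsv(sim$transcripts, "transcripts.tsv")
  wtsv(sim$mappings[, c("probe_id", "transcript_id", "start", "end")],
       "probes.tsv")
  expr <- tibble::as_tibble(sim$matrix$values, rownames = "probe_id")
  wtsv(expr, "expression.tsv")
  wtsv(tibble::tibble(sample_id = names(sim$matrix$groups),
                      group = unname(sim$matrix$groups)), "groups.tsv")
  wtsv(sim$truth, "truth.tsv")
  invisible(directory)
}
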