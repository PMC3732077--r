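#' Run the full probe-wise fragment-secretion analysis
#'
#' Orchestrates the analysis in order: read and validate inputs, keep
#' transcripts with at least `min_probes` probes, compute per-probe ECER
#' and secretion calls, classify transcripts, sweep the cutoff grid for the
#' class-fraction curve and its trends, compute the positional statistics
#' (overall, region-stratified, representative pairs, design-bias control,
#' expression landscape) and the fragment-length bounds. All tables are
#' written to `out_dir` together with a JSON + text summary.
#'
#' @param transcripts_path,probes_path,expression_path,groups_path Input
#'   files in the formats of [read_transcript_models()],
#'   [read_probe_table()] and [read_expression_table()].
#' @param out_dir Output directory; created if needed. On any stage error
#'   the partially written outputs are removed.
#' @param cutoff ECER cutoff for the secretion call (default 3).
#' @param strong_cutoff "Strongly secreted" preset (default 10).
#' @param cutoff_grid Cutoff sweep (default `1:32`).
#' @param epsilon Cell-mean floor; `NULL` for [default_epsilon()].
#' @param min_probes Minimum probes per transcript (default 2).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with every computed object plus `summary`.
#' @export
run_pipeline <- function(transcripts_path, probes_path, expression_path,
                         groups_path, out_dir, cutoff = 3, strong_cutoff = 10,
                         cutoff_grid = 1:32, epsilon = NULL, min_probes = 2,
                         verbose = TRUE) {
  for (p in c(transcripts_path, probes_path, expression_path, groups_path)) {
    if (!file.exists(p)) config_error(paste0("input file not found: ", p))
  }
  if (cutoff <= 0) config_error("cutoff must be > 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (verbose) message("[exofrag] ", ...)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
  }

  tryCatch({
    say("reading inputs")
    transcripts <- read_transcript_models(transcripts_path)
    mappings <- read_probe_table(probes_path, transcripts)
    mat <- read_expression_table(expression_path, groups_path)

    say("filtering: >= ", min_probes, " probes per transcript")
    mappings <- filter_min_probes(mappings, min_probes)

    say("computing ECER at cutoff ", cutoff)
    records <- probe_secretion(mat, mappings, cutoff = cutoff,
                               epsilon = epsilon)
    emit(records, "ecer.tsv")

    say("classifying transcripts")
    cls <- classify_all(records, cutoff)
    emit(cls$classes, "classes.tsv")
    frag_pct <- fragmented_fraction(cls$counts)

    say("cutoff sweep over ", length(cutoff_grid), " cutoffs")
    curve <- suppressWarnings(class_fraction_curve(records, cutoff_grid))
    emit(curve, "curve.tsv")
    trend <- function(k) {
      tryCatch(curve_trend(curve, k),
               exofrag_insufficient_data_error = function(e) {
                 tibble::tibble(tau = NA_real_, p_value = NA_real_, n = 0L,
                                stratum = paste0("fraction(", k, ") vs cutoff"),
                                method = NA_character_)
               })
    }
    trends <- dplyr::bind_rows(lapply(setdiff(FRAG_CLASSES, "NOT_SECRETED"),
                                      trend))
    emit(trends, "curve_trends.tsv")

    say("positional statistics")
    overall <- location_secretion_correlation(records, mappings)
    strong <- location_secretion_correlation(records, mappings,
                                             strength = strong_cutoff)
    strata <- region_stratified_correlations(records, mappings,
                                             cutoffs = cutoff_grid,
                                             strength_threshold = strong_cutoff)
    emit(dplyr::bind_rows(overall, strong), "correlations.tsv")
    emit(strata, "correlations_stratified.tsv")
    pairs <- select_representative_pairs(records, mappings)
    emit(pairs, "pairs.tsv")
    bias <- probe_design_bias_check(records, mappings, split_cutoff = cutoff)
    emit(bias, "design_bias.tsv")
    landscape <- expression_location_landscape(records, mappings)
    emit(landscape, "landscape.tsv")

    say("fragment-length bounds")
    fraglen <- suppressWarnings(
      fragment_length_bounds(records, mappings, transcripts, cutoff = cutoff))
    emit(fraglen$bounds, "fraglen.tsv")

    summary <- list(
      n_transcripts = nrow(cls$classes),
      n_probes = nrow(records),
      cutoff = cutoff,
      class_counts = as.list(cls$counts),
      half_breakdown = as.data.frame(cls$half_breakdown),
      fragmented_fraction_pct = frag_pct,
      tau_location_all = overall$tau,
      p_location_all = overall$p_value,
      tau_location_strong = strong$tau,
      curve_trends = as.data.frame(trends[, c("stratum", "tau", "p_value")]),
      fraglen_n = fraglen$n_transcripts,
      fraglen_median = fraglen$median_length,
      fraglen_iqr = fraglen$iqr_length
    )
    json_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    written <- c(written, json_path)
    txt_path <- file.path(out_dir, "report.txt")
    writeLines(c(
      "exofrag pipeline report",
      sprintf("transcripts classified: %d (probes: %d, cutoff: %g)",
              summary$n_transcripts, summary$n_probes, cutoff),
      sprintf("class counts: %s",
              paste(names(cls$counts), cls$counts, sep = "=", collapse = ", ")),
      sprintf("fragmented fraction of secreted transcripts: %.1f%%", frag_pct),
      sprintf("location-vs-ECER tau: %.3f (p = %.3g, n = %d)",
              overall$tau, overall$p_value, overall$n),
      sprintf("fragment-length bound median: %s nt (IQR %s, n = %d)",
              format(fraglen$median_length), format(fraglen$iqr_length),
              fraglen$n_transcripts)
    ), txt_path)
    written <- c(written, txt_path)
    say("done: ", out_dir)

    invisible(list(transcripts = transcripts, mappings = mappings,
                   matrix = mat, records = records, classes = cls,
                   curve = curve, trends = trends, overall = overall,
                   strong = strong, strata = strata, pairs = pairs,
                   bias = bias, landscape = landscape, fraglen = fraglen,
                   summary = summary))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' qPCR relative abundance against a spike-in control
#'
#' Relative abundance of an amplicon from threshold cycles, assuming
#' amplification efficiency 2: `2^-(ct_gene - ct_spike)`.
#'
#' @param ct_gene,ct_spike Finite threshold cycle values (vectorized).
#' @return `2^-(ct_gene - ct_spike)`.
#' @export
qpcr_relative_abundance <- function(ct_gene, ct_spike) {
  if (!all(is.finite(ct_gene)) || !all(is.finite(ct_spike))) {
    validation_error("CT values must be finite")
  }
  2^(-(ct_gene - ct_spike))
}

#' qPCR 3'/5' amplicon ratio
#'
#' Quotient of the spike-normalized abundances of a 3' and a 5' amplicon
#' of the same transcript.
#'
#' @param ct_3p,ct_5p Threshold cycles of the 3' and 5' amplicons.
#' @param ct_spike Threshold cycle of the spike-in control.
#' @return Abundance ratio (3' over 5').
#' @export
qpcr_ratio_3p_5p <- function(ct_3p, ct_5p, ct_spike) {
  qpcr_relative_abundance(ct_3p, ct_spike) /
    qpcr_relative_abundance(ct_5p, ct_spike)
}
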