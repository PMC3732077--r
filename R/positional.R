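# All location-vs-secretion statistics. Records are probe secretion tables
# (probe_id, transcript_id, mean_exosome, ecer, ...), mappings carry
# relative_location and region; the two join on (probe_id, transcript_id).

join_positional <- function(records, mappings) {
  dplyr::inner_join(
    tibble::as_tibble(records),
    mappings[, c("probe_id", "transcript_id", "relative_location",
                 "binned_location", "region")],
    by = c("probe_id", "transcript_id")
  )
}

#' Mean exosomal expression over (location bin x ECER bin) cells
#'
#' Bins every probe record by its 0.02-step relative location (50 bins)
#' and by ECER, and reports the mean exosomal intensity and the record
#' count per occupied cell. Empty cells are absent from the table (missing,
#' not zero).
#'
#' @param records Probe secretion tibble.
#' @param mappings Annotated probe tibble.
#' @param ecer_edges Increasing bin edges for ECER; the default
#'   `c(0, 1, 2, 4, 8, 16, 32, Inf)` is log2-spaced with an open top bin.
#' @return Tibble: `location_bin` (left edge), `ecer_bin` (label),
#'   `mean_expression`, `count`.
#' @export
expression_location_landscape <- function(records, mappings,
                                          ecer_edges = c(0, 1, 2, 4, 8, 16, 32, Inf)) {
  if (any(diff(ecer_edges) <= 0)) config_error("ecer_edges must be increasing")
  joined <- join_positional(records, mappings)
  joined$location_bin <- bin_location(joined$relative_location)
  joined$ecer_bin <- cut(joined$ecer, breaks = ecer_edges, right = FALSE,
                         include.lowest = TRUE)
  joined |>
    dplyr::group_by(.data$location_bin, .data$ecer_bin) |>
    dplyr::summarise(mean_expression = mean(.data$mean_exosome),
                     count = dplyr::n(), .groups = "drop")
}

#' Representative max/min-ECER probe pair per transcript
#'
#' For each transcript (>= 2 probes) selects the probe with the highest
#' and the probe with the lowest ECER. The 3'/5' ratio is the exosomal
#' mean of the more 3'-located probe of the pair over that of the other
#' probe. ECER ties are broken toward the larger relative location, then
#' by probe id.
#'
#' @param records Probe secretion tibble.
#' @param mappings Annotated probe tibble.
#' @return Tibble: `transcript_id`, `hi_probe`, `lo_probe`, `hi_ecer`,
#'   `lo_ecer`, `ratio_3p_5p`, `hi_is_3prime`, `delta_location`.
#' @export
select_representative_pairs <- function(records, mappings) {
  joined <- join_positional(records, mappings)
  counts <- table(joined$transcript_id)
  if (any(counts < 2)) {
    insufficient_data_error(paste0(
      "transcript '", names(counts)[counts < 2][1],
      "' has fewer than 2 probes"))
  }
  joined |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_modify(function(df, key) representative_pair(df)) |>
    dplyr::ungroup()
}

# one transcript's pair; df holds ecer, relative_location, mean_exosome
representative_pair <- function(df) {
  ord_hi <- order(-df$ecer, -df$relative_location, df$probe_id)
  hi <- ord_hi[1]
  ord_lo <- order(df$ecer, -df$relative_location, df$probe_id)
  lo <- ord_lo[1]
  if (lo == hi) lo <- ord_lo[2]
  hi_is_3prime <- df$relative_location[hi] >= df$relative_location[lo]
  p3 <- if (hi_is_3prime) hi else lo
  p5 <- if (hi_is_3prime) lo else hi
  tibble::tibble(
    hi_probe = df$probe_id[hi],
    lo_probe = df$probe_id[lo],
    hi_ecer = df$ecer[hi],
    lo_ecer = df$ecer[lo],
    ratio_3p_5p = df$mean_exosome[p3] / df$mean_exosome[p5],
    hi_is_3prime = hi_is_3prime,
    delta_location = df$relative_location[hi] - df$relative_location[lo]
  )
}

#' Correlation between the pair 3'/5' ratio and its location offset
#'
#' Companion statistic to the per-probe correlation: over representative
#' pairs, Kendall tau-b between the location offset of the high-ECER probe
#' and the pair's 3'/5' expression ratio.
#'
#' @param pairs Tibble from [select_representative_pairs()].
#' @return One-row tibble from [kendall_tau_b()].
#' @export
pair_ratio_correlation <- function(pairs) {
  kendall_tau_b(pairs$delta_location, pairs$ratio_3p_5p,
                stratum = "pairs: delta_location vs 3'/5' ratio")
}

#' Correlation between probe location and secretion (ECER)
#'
#' The central positional statistic: Kendall tau-b between a probe's
#' relative location (0 = 5' end, 1 = 3' end) and its ECER, over all probe
#' records passing the stratum filter. Positive tau means probes closer to
#' the 3' end are more strongly secreted.
#'
#' @param records Probe secretion tibble.
#' @param mappings Annotated probe tibble.
#' @param region Optional: `"UTR"` (5' and 3' UTRs merged), `"UTR3"`,
#'   `"UTR5"` or `"CDS"`.
#' @param classes Optional classes tibble (from `classify_all()$classes`)
#'   when filtering by `klass`.
#' @param klass Optional fragmentation class label; keeps probes of
#'   transcripts in that class.
#' @param strength Optional threshold: keep transcripts whose probe ECER
#'   reaches it (`strength_rule = "max"`, default) or whose probes all
#'   reach it (`"all"`).
#' @param strength_rule `"max"` or `"all"`.
#' @param stratum Optional label for the result; autogenerated otherwise.
#' @return One-row tibble from [kendall_tau_b()].
#' @export
location_secretion_correlation <- function(records, mappings, region = NULL,
                                           classes = NULL, klass = NULL,
                                           strength = NULL,
                                           strength_rule = c("max", "all"),
                                           stratum = NULL) {
  strength_rule <- match.arg(strength_rule)
  joined <- join_positional(records, mappings)
  label <- character(0)
  if (!is.null(region)) {
    keep_regions <- switch(region,
      UTR = c("UTR5", "UTR3"),
      UTR3 = "UTR3", UTR5 = "UTR5", CDS = "CDS",
      config_error("region must be one of UTR, UTR3, UTR5, CDS"))
    joined <- joined[joined$region %in% keep_regions, ]
    label <- c(label, region)
  }
  if (!is.null(klass)) {
    if (is.null(classes)) {
      config_error("filtering by klass requires the classes table")
    }
    keep_tx <- classes$transcript_id[classes$klass == klass]
    joined <- joined[joined$transcript_id %in% keep_tx, ]
    label <- c(label, paste0("class=", klass))
  }
  if (!is.null(strength)) {
    agg <- tapply(joined$ecer, joined$transcript_id,
                  if (strength_rule == "max") max else min)
    keep_tx <- names(agg)[agg >= strength]
    joined <- joined[joined$transcript_id %in% keep_tx, ]
    label <- c(label, paste0("ECER>=", strength, " (", strength_rule, ")"))
  }
  if (is.null(stratum)) {
    stratum <- if (length(label) > 0) paste(label, collapse = ", ") else "all probes"
  }
  if (nrow(joined) < 3) {
    insufficient_data_error(paste0("fewer than 3 probe records in stratum '",
                                   stratum, "'"))
  }
  kendall_tau_b(joined$relative_location, joined$ecer, stratum = stratum)
}

#' Region-stratified location-secretion correlations across cutoffs
#'
#' For every cutoff, computes the location-vs-ECER correlation within the
#' four strata {UTR, CDS} x {MAJORITY-class transcripts at that cutoff,
#' strongly secreted transcripts}. Strata with fewer than 3 records are
#' recorded with missing statistics rather than dropped.
#'
#' @param records Probe secretion tibble.
#' @param mappings Annotated probe tibble.
#' @param cutoffs Cutoff grid for the class-based strata (default `1:32`).
#' @param strength_threshold ECER threshold for "strongly secreted"
#'   (default 10); `NULL` skips those strata.
#' @return Tibble: `cutoff`, `region`, `selection`, `tau`, `p_value`, `n`,
#'   `stratum`.
#' @export
region_stratified_correlations <- function(records, mappings, cutoffs = 1:32,
                                           strength_threshold = 10) {
  one <- function(cutoff, region, selection) {
    res <- tryCatch({
      if (selection == "MAJORITY") {
        cls <- classify_all(records, cutoff)$classes
        location_secretion_correlation(records, mappings, region = region,
                                       classes = cls, klass = "MAJORITY")
      } else {
        location_secretion_correlation(records, mappings, region = region,
                                       strength = strength_threshold)
      }
    }, exofrag_insufficient_data_error = function(e) NULL,
       exofrag_undefined_result_error = function(e) NULL)
    if (is.null(res)) {
      res <- tibble::tibble(tau = NA_real_, p_value = NA_real_, n = 0L,
                            stratum = NA_character_, method = NA_character_)
    }
    tibble::tibble(cutoff = cutoff, region = region, selection = selection,
                   tau = res$tau, p_value = res$p_value, n = res$n,
                   stratum = paste0(region, ", ", selection,
                                    ", cutoff=", cutoff))
  }
  selections <- "MAJORITY"
  if (!is.null(strength_threshold)) selections <- c(selections, "STRONG")
  grid <- expand.grid(cutoff = cutoffs, region = c("UTR", "CDS"),
                      selection = selections, stringsAsFactors = FALSE)
  # the STRONG stratum does not depend on the cutoff; emit it once
  grid <- grid[grid$selection == "MAJORITY" | grid$cutoff == cutoffs[1], ]
  dplyr::bind_rows(Map(one, grid$cutoff, grid$region, grid$selection))
}

#' Probe-design bias control
#'
#' If probe placement influenced hybridization intensity, expression would
#' correlate with location regardless of secretion. The control splits
#' probes at an ECER cutoff and reports the correlation between exosomal
#' mean expression and relative location within each side; both should be
#' near zero on unbiased designs.
#'
#' @param records Probe secretion tibble.
#' @param mappings Annotated probe tibble.
#' @param split_cutoff ECER value splitting the strata (default 3).
#' @return Two-row tibble (`stratum` = `"ECER < c"` / `"ECER >= c"`); a
#'   stratum with fewer than 3 records gets missing statistics.
#' @export
probe_design_bias_check <- function(records, mappings, split_cutoff = 3) {
  joined <- join_positional(records, mappings)
  one <- function(mask, label) {
    sub <- joined[mask, ]
    if (nrow(sub) < 3) {
      return(tibble::tibble(tau = NA_real_, p_value = NA_real_,
                            n = nrow(sub), stratum = label,
                            method = NA_character_))
    }
    kendall_tau_b(sub$mean_exosome, sub$relative_location, stratum = label)
  }
  out <- dplyr::bind_rows(
    one(joined$ecer < split_cutoff, paste0("ECER < ", split_cutoff)),
    one(joined$ecer >= split_cutoff, paste0("ECER >= ", split_cutoff))
  )
  if (all(is.na(out$tau))) {
    insufficient_data_error("both design-bias strata are empty")
  }
  out
}
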