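FRAG_CLASSES <- c("ALL_SECRETED", "HALF", "MAJORITY", "MINORITY", "NOT_SECRETED")

#' Fragmentation class of one transcript
#'
#' A transcript with some but not all probes called secreted is evidence of
#' fragment (partial) secretion. The five-way partition by the share of
#' secreted probes: all secreted, exactly half, more than half, less than
#' half (but more than none), none.
#'
#' @param n_secreted Number of secreted probes (vectorized).
#' @param n_probes Total probes on the transcript, `>= 2` (vectorized).
#' @return Character vector of class labels.
#' @export
classify_transcript <- function(n_secreted, n_probes) {
  if (any(n_probes < 2) || any(n_secreted < 0) || any(n_secreted > n_probes)) {
    validation_error("need 0 <= n_secreted <= n_probes and n_probes >= 2")
  }
  ifelse(n_secreted == n_probes, "ALL_SECRETED",
    ifelse(n_secreted == 0, "NOT_SECRETED",
      ifelse(2 * n_secreted == n_probes, "HALF",
        ifelse(2 * n_secreted > n_probes, "MAJORITY", "MINORITY"))))
}

#' Classify every transcript at an ECER cutoff
#'
#' Re-calls probe secretion at `cutoff` and tallies secreted probes per
#' transcript. Also reports the breakdown of the HALF class by its number
#' of secreted probes (1-vs-1, 2-vs-2, ...).
#'
#' @param records Probe secretion tibble ([probe_secretion()]); needs
#'   `probe_id`, `transcript_id`, `ecer`. Every transcript must carry at
#'   least 2 probes (apply [filter_min_probes()] upstream).
#' @param cutoff ECER cutoff (default 3).
#' @return List with `classes` (tibble: `transcript_id`, `n_probes`,
#'   `n_secreted`, `klass`, `cutoff`), `counts` (named integer vector over
#'   the five classes) and `half_breakdown` (tibble: `n_secreted`,
#'   `n_transcripts`).
#' @export
classify_all <- function(records, cutoff = 3) {
  rec <- call_secretion(records, cutoff)
  classes <- rec |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(n_probes = dplyr::n_distinct(.data$probe_id),
                     n_secreted = sum(.data$secreted), .groups = "drop")
  classes$klass <- classify_transcript(classes$n_secreted, classes$n_probes)
  classes$cutoff <- cutoff
  counts <- table(factor(classes$klass, levels = FRAG_CLASSES))
  counts <- stats::setNames(as.integer(counts), FRAG_CLASSES)
  half <- classes[classes$klass == "HALF", ]
  half_breakdown <- half |>
    dplyr::count(.data$n_secreted, name = "n_transcripts") |>
    dplyr::arrange(.data$n_secreted)
  list(classes = classes, counts = counts, half_breakdown = half_breakdown)
}

#' Percentage of secreted transcripts that are fragmented
#'
#' Share of the HALF, MAJORITY and MINORITY classes among transcripts with
#' at least one secreted probe; fully unsecreted transcripts are excluded
#' from the denominator.
#'
#' @param counts Named vector of per-class counts (names from
#'   `ALL_SECRETED`, `HALF`, `MAJORITY`, `MINORITY`, optionally
#'   `NOT_SECRETED`), or the list returned by [classify_all()].
#' @return Percentage in `[0, 100]`.
#' @export
fragmented_fraction <- function(counts) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  get0c <- function(k) if (k %in% names(counts)) as.numeric(counts[[k]]) else 0
  frag <- get0c("HALF") + get0c("MAJORITY") + get0c("MINORITY")
  secreted <- frag + get0c("ALL_SECRETED")
  if (secreted == 0) {
    undefined_result_error("no secreted transcripts: fragmented fraction undefined")
  }
  100 * frag / secreted
}

#' Class-fraction curve over a sweep of ECER cutoffs
#'
#' At each cutoff, probe secretion and transcript classes are recomputed
#' and the fraction of secreted transcripts (>= 1 secreted probe) in each
#' secreted class is recorded. Cutoffs where no transcript is secreted get
#' missing fractions (with one warning).
#'
#' @param records Probe secretion tibble (flags ignored; `ecer` is used).
#' @param cutoffs Strictly increasing positive cutoffs (default `1:32`).
#' @return Long tibble of class `class_fraction_curve`: `cutoff`, `klass`,
#'   `count`, `fraction` (fraction is `NA` for `NOT_SECRETED` and at empty
#'   cutoffs).
#' @export
class_fraction_curve <- function(records, cutoffs = 1:32) {
  if (length(cutoffs) < 1 || any(cutoffs <= 0) ||
      any(diff(cutoffs) <= 0)) {
    config_error("cutoffs must be strictly increasing and > 0")
  }
  secreted_classes <- setdiff(FRAG_CLASSES, "NOT_SECRETED")
  rows <- lapply(cutoffs, function(ct) {
    counts <- classify_all(records, ct)$counts
    n_secreted_tx <- sum(counts[secreted_classes])
    tibble::tibble(
      cutoff = ct,
      klass = FRAG_CLASSES,
      count = as.integer(counts[FRAG_CLASSES]),
      fraction = ifelse(FRAG_CLASSES == "NOT_SECRETED", NA_real_,
                        if (n_secreted_tx > 0) {
                          counts[FRAG_CLASSES] / n_secreted_tx
                        } else NA_real_)
    )
  })
  out <- dplyr::bind_rows(rows)
  empty <- unique(out$cutoff[is.na(out$fraction) & out$klass != "NOT_SECRETED"])
  if (length(empty) > 0) {
    warning("no secreted transcripts at cutoff(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("class_fraction_curve", class(out))
  out
}

#' Trend of one class's fraction across the cutoff sweep
#'
#' Kendall tau-b between the cutoff values and the selected class's
#' fraction of secreted transcripts. A positive tau says the class gains
#' share as the secretion call becomes more stringent.
#'
#' @param curve A [class_fraction_curve()].
#' @param klass One of `"ALL_SECRETED"`, `"HALF"`, `"MAJORITY"`,
#'   `"MINORITY"`.
#' @return One-row tibble from [kendall_tau_b()].
#' @export
curve_trend <- function(curve, klass) {
  klass <- match.arg(klass, setdiff(FRAG_CLASSES, "NOT_SECRETED"))
  pts <- curve[curve$klass == klass & !is.na(curve$fraction), ]
  if (nrow(pts) < 3) {
    insufficient_data_error("curve_trend needs >= 3 non-missing cutoff points")
  }
  kendall_tau_b(pts$cutoff, pts$fraction,
                stratum = paste0("fraction(", klass, ") vs cutoff"))
}

#' Upper bounds on secreted 3'-terminal fragment lengths
#'
#' With probes as the only landmarks, the length of a secreted 3'-terminal
#' fragment is bounded above by the distance from the transcript 3' end to
#' the 3'-most non-secreted probe in the 3' UTR (its interval end), or by
#' the full 3'-UTR length when every UTR probe is secreted. Only
#' transcripts whose 3' UTR carries at least `min_probes_per_utr` probes
#' and at least one secreted UTR probe are informative; a transcript whose
#' bound collapses to zero (non-secreted probe flush with the 3' end) is
#' dropped.
#'
#' @param records Probe secretion tibble (the `ecer` column is used; calls
#'   are re-made at `cutoff`).
#' @param mappings Annotated probe tibble.
#' @param transcripts Transcript models.
#' @param cutoff ECER cutoff for the secretion calls.
#' @param min_probes_per_utr Minimum probes in the 3' UTR (default 3).
#' @param max_utr_length Optional cap on 3'-UTR length (nt); transcripts
#'   with longer UTRs are excluded, mirroring a <= 1000 nt stratification.
#' @return List with `cutoff`, `n_transcripts`, `median_length`,
#'   `iqr_length` and `bounds` (tibble: `transcript_id`, `utr3_length`,
#'   `n_utr_probes`, `n_utr_secreted`, `bound`).
#' @export
fragment_length_bounds <- function(records, mappings, transcripts, cutoff = 3,
                                   min_probes_per_utr = 3,
                                   max_utr_length = NULL) {
  if (cutoff <= 0) config_error("cutoff must be > 0")
  rec <- call_secretion(records, cutoff)
  utr <- dplyr::inner_join(
    mappings[mappings$region == "UTR3",
             c("probe_id", "transcript_id", "end")],
    rec[, c("probe_id", "transcript_id", "secreted")],
    by = c("probe_id", "transcript_id")
  )
  tx <- transcripts[, c("transcript_id", "length", "cds_end")]
  utr <- dplyr::inner_join(utr, tx, by = "transcript_id")
  utr$utr3_length <- utr$length - utr$cds_end

  per_tx <- utr |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      utr3_length = .data$utr3_length[1],
      n_utr_probes = dplyr::n(),
      n_utr_secreted = sum(.data$secreted),
      max_unsecreted_end = if (any(!.data$secreted)) {
        max(.data$end[!.data$secreted])
      } else NA_real_,
      tx_length = .data$length[1],
      .groups = "drop"
    )
  keep <- per_tx$n_utr_probes >= min_probes_per_utr & per_tx$n_utr_secreted > 0
  if (!is.null(max_utr_length)) {
    keep <- keep & per_tx$utr3_length <= max_utr_length
  }
  per_tx <- per_tx[keep, ]
  per_tx$bound <- ifelse(is.na(per_tx$max_unsecreted_end),
                         per_tx$utr3_length,
                         per_tx$tx_length - per_tx$max_unsecreted_end)
  per_tx <- per_tx[per_tx$bound > 0, ]
  bounds <- per_tx[, c("transcript_id", "utr3_length", "n_utr_probes",
                       "n_utr_secreted", "bound")]
  if (nrow(bounds) == 0) {
    warning("no qualifying transcripts for fragment-length bounds",
            call. = FALSE)
    return(list(cutoff = cutoff, n_transcripts = 0L,
                median_length = NA_real_, iqr_length = NA_real_,
                bounds = bounds))
  }
  list(cutoff = cutoff,
       n_transcripts = nrow(bounds),
       median_length = stats::median(bounds$bound),
       iqr_length = stats::IQR(bounds$bound),
       bounds = bounds)
}
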