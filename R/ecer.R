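#' Per-probe group means
#'
#' Arithmetic mean of the linear-scale intensities over the samples of each
#' compartment, per probe.
#'
#' @param matrix An [expression_matrix()].
#' @return Tibble with `probe_id`, `mean_exosome`, `mean_cell`.
#' @export
group_means <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  exo <- matrix$values[, matrix$groups == "exosome", drop = FALSE]
  cel <- matrix$values[, matrix$groups == "cell", drop = FALSE]
  tibble::tibble(
    probe_id = rownames(matrix$values),
    mean_exosome = unname(rowMeans(exo)),
    mean_cell = unname(rowMeans(cel))
  )
}

#' Default floor for near-zero cell means
#'
#' Half the smallest strictly positive intensity in the matrix; keeps the
#' enrichment ratio finite without assuming a unit scale.
#'
#' @param matrix An [expression_matrix()].
#' @return A positive scalar.
#' @export
default_epsilon <- function(matrix) {
  pos <- matrix$values[matrix$values > 0]
  if (length(pos) == 0) {
    validation_error("expression matrix has no positive values")
  }
  min(pos) / 2
}

#' Exosome-to-cell enrichment ratio (ECER) per probe
#'
#' ECER is the mean exosomal intensity of a probe divided by its mean
#' cellular intensity; probes measuring exported transcript regions have
#' high ECER. Cell means below `epsilon` are floored at `epsilon` so the
#' ratio stays finite.
#'
#' @param means Tibble from [group_means()], optionally carrying a
#'   `transcript_id` column (preserved in the output).
#' @param epsilon Positive floor for the cell mean; see [default_epsilon()].
#' @return Tibble with the input columns plus `ecer`.
#' @export
compute_ecer <- function(means, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0) {
    config_error("epsilon must be a single finite value > 0")
  }
  out <- tibble::as_tibble(means)
  out$ecer <- out$mean_exosome / pmax(out$mean_cell, epsilon)
  out
}

#' Call probe secretion at an ECER cutoff
#'
#' A probe is called secreted when its ECER is at or above the cutoff
#' (boundary inclusive). The analysis default is 3; 10 is the preset for
#' "strongly secreted".
#'
#' @param records Tibble with an `ecer` column.
#' @param cutoff Positive ECER cutoff (default 3).
#' @return The records with `secreted` (logical) and `cutoff` columns set.
#' @export
call_secretion <- function(records, cutoff = 3) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    config_error("cutoff must be a single value > 0")
  }
  out <- tibble::as_tibble(records)
  out$secreted <- out$ecer >= cutoff
  out$cutoff <- cutoff
  out
}

#' Probe-level secretion table from an expression matrix
#'
#' Convenience composition: group means, ECER and the secretion call, with
#' probe-to-transcript joins carried along so every downstream analysis can
#' work from this one table.
#'
#' @param matrix An [expression_matrix()].
#' @param mappings Annotated probe tibble ([read_probe_table()]); rows for
#'   probes absent from the matrix are dropped. One probe mapped to several
#'   transcripts yields one record per transcript.
#' @param cutoff ECER cutoff for the secretion call (default 3).
#' @param epsilon Cell-mean floor; `NULL` (default) uses [default_epsilon()].
#' @return Tibble with `probe_id`, `transcript_id`, `mean_exosome`,
#'   `mean_cell`, `ecer`, `secreted`, `cutoff`.
#' @export
probe_secretion <- function(matrix, mappings, cutoff = 3, epsilon = NULL) {
  if (is.null(epsilon)) epsilon <- default_epsilon(matrix)
  means <- group_means(matrix)
  joined <- dplyr::inner_join(
    mappings[, c("probe_id", "transcript_id")], means, by = "probe_id"
  )
  call_secretion(compute_ecer(joined, epsilon), cutoff)
}
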