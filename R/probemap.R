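#' Read a transcript model table
#'
#' Transcript models live in transcript coordinates (0-based, half-open):
#' the 5' UTR is `[0, cds_start)`, the CDS `[cds_start, cds_end)` and the
#' 3' UTR `[cds_end, length)`.
#'
#' @param path Path to a tab-separated file with columns `transcript_id`,
#'   `length`, `cds_start`, `cds_end`. A header row is required; lines
#'   starting with `#` are ignored.
#' @return A tibble with one row per transcript, in file order.
#' @export
read_transcript_models <- function(path) {
  tab <- read_tsv_checked(path, c("transcript_id", "length", "cds_start", "cds_end"))
  validate_transcript_models(tab)
}

#' Validate an in-memory transcript model table
#'
#' @param transcripts A data frame with columns `transcript_id`, `length`,
#'   `cds_start`, `cds_end`.
#' @return The validated table as a tibble.
#' @export
validate_transcript_models <- function(transcripts) {
  tab <- tibble::as_tibble(transcripts)
  need <- c("transcript_id", "length", "cds_start", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    format_error(paste0("transcript table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(tab) == 0) return(tab[, need])
  tab$transcript_id <- as.character(tab$transcript_id)
  for (col in c("length", "cds_start", "cds_end")) {
    if (!is.numeric(tab[[col]])) {
      format_error(paste0("transcript column '", col, "' is not numeric"))
    }
  }
  dup <- tab$transcript_id[duplicated(tab$transcript_id)]
  if (length(dup) > 0) {
    validation_error(paste0("duplicated transcript_id: ", dup[1]))
  }
  bad <- function(cond, rule) {
    idx <- which(cond)
    if (length(idx) > 0) {
      validation_error(paste0("transcript '", tab$transcript_id[idx[1]],
                              "' violates: ", rule))
    }
  }
  bad(tab$length < 100, "length >= 100")
  bad(tab$cds_start < 0, "cds_start >= 0")
  bad(tab$cds_start >= tab$cds_end, "cds_start < cds_end")
  bad(tab$cds_end > tab$length, "cds_end <= length")
  tab[, need]
}

#' Read a probe-to-transcript mapping table and annotate positions
#'
#' Each row places one probe on one transcript (0-based half-open interval
#' in transcript coordinates). The relative location is the probe midpoint
#' divided by the transcript length, so 0 is the 5' end and 1 the 3' end;
#' `binned_location` snaps it down to the 0.02 grid used for positional
#' summaries (a midpoint exactly at the 3' end falls in the last bin, 0.98).
#'
#' @param path Path to a tab-separated file with columns `probe_id`,
#'   `transcript_id`, `start`, `end`.
#' @param transcripts Transcript models from [read_transcript_models()].
#' @return A tibble with columns `probe_id`, `transcript_id`, `start`,
#'   `end`, `relative_location`, `binned_location`, `region`.
#' @export
read_probe_table <- function(path, transcripts) {
  tab <- read_tsv_checked(path, c("probe_id", "transcript_id", "start", "end"))
  annotate_probes(tab, transcripts)
}

#' Annotate probe mappings with relative location and region
#'
#' @param probes Data frame with columns `probe_id`, `transcript_id`,
#'   `start`, `end`.
#' @param transcripts Validated transcript models.
#' @return Annotated probe tibble (see [read_probe_table()]).
#' @export
annotate_probes <- function(probes, transcripts) {
  tab <- tibble::as_tibble(probes)
  need <- c("probe_id", "transcript_id", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    format_error(paste0("probe table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  out_cols <- c(need, "relative_location", "binned_location", "region")
  if (nrow(tab) == 0) {
    tab$relative_location <- numeric(0)
    tab$binned_location <- numeric(0)
    tab$region <- character(0)
    return(tab[, out_cols])
  }
  tab$probe_id <- as.character(tab$probe_id)
  tab$transcript_id <- as.character(tab$transcript_id)

  key <- paste(tab$probe_id, tab$transcript_id)
  if (anyDuplicated(key)) {
    validation_error(paste0("duplicated (probe_id, transcript_id) pair: ",
                            key[duplicated(key)][1]))
  }
  idx <- match(tab$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    validation_error(paste0("probe references unknown transcript_id '",
                            tab$transcript_id[which(is.na(idx))[1]], "'"))
  }
  len <- transcripts$length[idx]
  if (any(tab$start < 0) || any(tab$start >= tab$end)) {
    bad <- which(tab$start < 0 | tab$start >= tab$end)[1]
    validation_error(paste0("probe '", tab$probe_id[bad],
                            "': requires 0 <= start < end"))
  }
  if (any(tab$end > len)) {
    bad <- which(tab$end > len)[1]
    validation_error(paste0("probe '", tab$probe_id[bad],
                            "' extends past the end of transcript '",
                            tab$transcript_id[bad], "'"))
  }
  midpoint <- (tab$start + tab$end) / 2
  tab$relative_location <- midpoint / len
  tab$binned_location <- bin_location(tab$relative_location)
  tab$region <- region_of(midpoint, transcripts$cds_start[idx],
                          transcripts$cds_end[idx])
  tab[, out_cols]
}

#' Snap relative locations to the 0.02 positional grid
#'
#' @param relative_location Numeric vector in `[0, 1]`.
#' @return Left edge of the containing 0.02 bin; 1.0 maps to 0.98.
#' @export
bin_location <- function(relative_location) {
  pmin(floor(relative_location / 0.02) * 0.02, 0.98)
}

# Region of a transcript position; boundaries belong to the downstream
# (3'-ward) region, consistent with half-open intervals.
region_of <- function(pos, cds_start, cds_end) {
  ifelse(pos < cds_start, "UTR5", ifelse(pos < cds_end, "CDS", "UTR3"))
}

#' Region containing one probe's midpoint
#'
#' @param probe One-row data frame with `start`, `end` (transcript
#'   coordinates, 0-based half-open).
#' @param transcript One-row data frame with `cds_start`, `cds_end`, `length`.
#' @return `"UTR5"`, `"CDS"` or `"UTR3"`. A midpoint exactly on a boundary
#'   belongs to the downstream region.
#' @export
assign_region <- function(probe, transcript) {
  mid <- (probe$start + probe$end) / 2
  if (probe$start < 0 || probe$end > transcript$length) {
    validation_error("probe interval outside transcript bounds")
  }
  region_of(mid, transcript$cds_start, transcript$cds_end)
}

#' Keep only transcripts covered by at least k probes
#'
#' Transcript-level classification needs several independent measurements
#' along each transcript; the analysis uses transcripts with two or more
#' probes.
#'
#' @param mappings Annotated probe tibble.
#' @param k Minimum number of distinct probes per transcript (default 2).
#' @return The filtered probe tibble.
#' @export
filter_min_probes <- function(mappings, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    config_error("k must be a single integer >= 1")
  }
  n_by_tx <- tapply(mappings$probe_id, mappings$transcript_id,
                    function(p) length(unique(p)))
  keep <- names(n_by_tx)[n_by_tx >= k]
  mappings[mappings$transcript_id %in% keep, , drop = FALSE]
}

#' Read a probe-by-sample expression table with group labels
#'
#' @param path Tab-separated expression file: first column `probe_id`,
#'   one numeric column per sample (linear-scale intensities, >= 0).
#' @param groups Either a path to a two-column tab-separated file
#'   (`sample_id`, `group`) or a named character vector mapping sample id
#'   to `"exosome"` / `"cell"`.
#' @return An `expression_matrix` object: list with `values` (numeric
#'   matrix, probes x samples, rownames = probe ids) and `groups` (named
#'   character vector).
#' @export
read_expression_table <- function(path, groups) {
  tab <- read_tsv_checked(path, "probe_id")
  if (is.character(groups) && length(groups) == 1 && is.null(names(groups))) {
    gt <- read_tsv_checked(groups, c("sample_id", "group"))
    groups <- stats::setNames(as.character(gt$group), as.character(gt$sample_id))
  }
  sample_ids <- setdiff(names(tab), "probe_id")
  vals <- as.matrix(tab[, sample_ids, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
    where <- if (nrow(bad) > 0) {
      paste0(" (probe '", tab$probe_id[bad[1, 1]], "', sample '",
             sample_ids[bad[1, 2]], "')")
    } else ""
    validation_error(paste0("expression values must be numeric and finite", where))
  }
  rownames(vals) <- as.character(tab$probe_id)
  expression_matrix(vals, groups[sample_ids])
}

#' Construct and validate an expression matrix
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Named character vector over the sample ids, values in
#'   `{"exosome", "cell"}`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    validation_error("expression matrix needs unique probe_id rownames")
  }
  if (anyNA(groups)) {
    missing_samples <- colnames(values)[is.na(groups[colnames(values)])]
    config_error(paste0("no group label for sample(s): ",
                        paste(missing_samples, collapse = ", ")))
  }
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values)) {
      config_error("groups must be named by sample id or match column count")
    }
    names(groups) <- colnames(values)
  }
  if (!setequal(names(groups), colnames(values)) ||
      anyNA(match(colnames(values), names(groups)))) {
    config_error("group labels do not cover the sample columns")
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("exosome", "cell"))) {
    config_error("groups must be 'exosome' or 'cell'")
  }
  if (sum(groups == "exosome") < 1 || sum(groups == "cell") < 1) {
    validation_error("need at least one exosome and one cell sample")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    validation_error("expression values must be finite and >= 0")
  }
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples (", sum(x$groups == "exosome"), " exosome, ",
      sum(x$groups == "cell"), " cell)\n", sep = "")
  invisible(x)
}

#' Write probe intervals as BED-like text (transcript space)
#'
#' @param mappings Annotated probe tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(mappings, path) {
  bed <- data.frame(chrom = mappings$transcript_id,
                    chromStart = mappings$start,
                    chromEnd = mappings$end,
                    name = mappings$probe_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared TSV reader: header required, '#' comments skipped, listed columns
# must be present.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    config_error(paste0("file not found: ", path))
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    format_error(paste0(basename(path), " is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  tab
}
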