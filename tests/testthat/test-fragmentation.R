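test_that("transcript classification matches the stated class definitions", {
  expect_equal(classify_transcript(1, 2), "HALF")
  expect_equal(classify_transcript(2, 3), "MAJORITY")
  expect_equal(classify_transcript(1, 3), "MINORITY")
  expect_equal(classify_transcript(0, 5), "NOT_SECRETED")
  expect_equal(classify_transcript(5, 5), "ALL_SECRETED")
  expect_error(classify_transcript(3, 2), class = "exofrag_validation_error")
  expect_error(classify_transcript(-1, 4), class = "exofrag_validation_error")
})

test_that("classification agrees with direct majority comparison, exhaustively", {
  for (np in 2:8) {
    for (ns in 0:np) {
      expected <- if (ns == np) "ALL_SECRETED"
      else if (ns == 0) "NOT_SECRETED"
      else if (ns / np == 0.5) "HALF"
      else if (ns / np > 0.5) "MAJORITY"
      else "MINORITY"
      expect_equal(classify_transcript(ns, np), expected,
                   info = sprintf("ns=%d np=%d", ns, np))
    }
  }
})

test_that("classify_all tallies per-transcript classes and the HALF breakdown", {
  rec <- tibble::tibble(
    probe_id = c("a1", "a2", "b1", "b2", "c1", "c2", "c3", "d1", "d2", "d3", "d4"),
    transcript_id = rep(c("A", "B", "C", "D"), c(2, 2, 3, 4)),
    ecer = c(5, 4, 5, 1, 0.5, 0.2, 1, 8, 9, 1, 0.5)
  )
  out <- classify_all(rec, cutoff = 3)
  expect_equal(unname(out$counts),
               c(1L, 2L, 0L, 0L, 1L))  # ALL, HALF, MAJ, MIN, NOT
  expect_equal(sum(out$counts), 4L)
  expect_equal(out$half_breakdown$n_secreted, c(1, 2))
  expect_equal(out$half_breakdown$n_transcripts, c(1, 1))
  # everything below the cutoff
  out2 <- classify_all(rec, cutoff = 100)
  expect_equal(unname(out2$counts["NOT_SECRETED"]), 4L)
})

test_that("fragmented fraction reproduces the published worked example", {
  counts <- c(ALL_SECRETED = 511, HALF = 687, MAJORITY = 279, MINORITY = 145)
  expect_equal(round(fragmented_fraction(counts), 1), 68.5)
  expect_equal(fragmented_fraction(c(ALL_SECRETED = 10)), 0)
  expect_equal(fragmented_fraction(c(ALL_SECRETED = 0, HALF = 5)), 100)
  expect_error(fragmented_fraction(c(NOT_SECRETED = 7)),
               class = "exofrag_undefined_result_error")
  # invariant to scaling the counts
  expect_equal(fragmented_fraction(counts * 13), fragmented_fraction(counts))
})

test_that("class-fraction curves partition secreted transcripts", {
  run <- recovery_run(1)
  curve <- run$curve
  for (ct in c(1, 3, 10, 25)) {
    fr <- curve$fraction[curve$cutoff == ct & curve$klass != "NOT_SECRETED"]
    if (all(is.na(fr))) next
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  n_sec <- tapply(curve$count[curve$klass != "NOT_SECRETED"],
                  curve$cutoff[curve$klass != "NOT_SECRETED"], sum)
  expect_true(all(diff(n_sec) <= 0))  # non-increasing in cutoff
})

test_that("a single-cutoff curve degenerates to classify_all", {
  rec <- recovery_run(1)$rec
  curve <- class_fraction_curve(rec, 3)
  counts <- classify_all(rec, 3)$counts
  expect_equal(stats::setNames(curve$count, curve$klass), counts)
  # a cutoff beyond the maximum ECER yields missing fractions
  expect_warning(far <- class_fraction_curve(rec, max(rec$ecer) + 1),
                 "no secreted")
  expect_true(all(is.na(far$fraction)))
})

test_that("curve trends recover the sign of monotone fraction series", {
  mk <- function(fr) tibble::tibble(cutoff = seq_along(fr), klass = "HALF",
                                    count = 1L, fraction = fr)
  expect_equal(curve_trend(mk(seq(0.1, 0.9, length.out = 10)), "HALF")$tau, 1)
  expect_equal(curve_trend(mk(seq(0.9, 0.1, length.out = 10)), "HALF")$tau, -1)
  expect_error(curve_trend(mk(c(0.1, 0.2)), "HALF"),
               class = "exofrag_insufficient_data_error")
})

test_that("fragment-length bounds follow probe landmarks and UTR borders", {
  tx <- tibble::tibble(transcript_id = "T", length = 2000L,
                       cds_start = 100L, cds_end = 1400L)
  mp <- annotate_probes(tibble::tibble(
    probe_id = c("u1", "u2", "u3", "cds"),
    transcript_id = "T",
    start = c(1440L, 1640L, 1840L, 500L),
    end = c(1500L, 1700L, 1900L, 560L)), tx)
  rec <- tibble::tibble(probe_id = c("u1", "u2", "u3", "cds"),
                        transcript_id = "T",
                        ecer = c(1, 5, 9, 1))
  # u1 not secreted at cutoff 3: bound = 2000 - 1500
  fl3 <- fragment_length_bounds(rec, mp, tx, cutoff = 3)
  expect_equal(fl3$bounds$bound, 500)
  expect_equal(fl3$n_transcripts, 1L)
  # raising the cutoff drops u2: bound shrinks to 2000 - 1700
  fl7 <- fragment_length_bounds(rec, mp, tx, cutoff = 7)
  expect_equal(fl7$bounds$bound, 300)
  # all three UTR probes secreted: bound = full 3' UTR length
  rec_all <- rec
  rec_all$ecer <- c(5, 5, 9, 1)
  expect_equal(fragment_length_bounds(rec_all, mp, tx, 3)$bounds$bound, 600)
  # no secreted UTR probe -> excluded -> empty summary with warning
  rec_none <- rec
  rec_none$ecer <- c(1, 1, 1, 9)
  expect_warning(fl0 <- fragment_length_bounds(rec_none, mp, tx, 3),
                 "no qualifying")
  expect_equal(fl0$n_transcripts, 0L)
  # UTR-length cap excludes this 600 nt UTR
  expect_warning(
    flcap <- fragment_length_bounds(rec, mp, tx, 3, max_utr_length = 500),
    "no qualifying")
  expect_equal(flcap$n_transcripts, 0L)
})

test_that("per-transcript bounds never exceed the UTR and shrink with cutoff", {
  sim <- simulate_dataset(sim_config(seed = 77, n_transcripts = 250,
                                     probes_min = 8L, probes_max = 12L,
                                     probes_weights = NULL,
                                     length_min = 1200L))
  rec <- probe_secretion(sim$matrix, sim$mappings, cutoff = 2)
  prev <- NULL
  for (ct in c(2, 3, 5, 8)) {
    fl <- suppressWarnings(
      fragment_length_bounds(rec, sim$mappings, sim$transcripts, ct))
    expect_true(all(fl$bounds$bound > 0))
    expect_true(all(fl$bounds$bound <= fl$bounds$utr3_length))
    if (!is.null(prev)) {
      shared <- intersect(prev$transcript_id, fl$bounds$transcript_id)
      m <- match(shared, prev$transcript_id)
      m2 <- match(shared, fl$bounds$transcript_id)
      expect_true(all(fl$bounds$bound[m2] <= prev$bound[m] + 1e-9))
    }
    prev <- fl$bounds
  }
})

test_that("HALF is empty when every transcript has an odd probe count", {
  sim <- simulate_dataset(sim_config(seed = 5, n_transcripts = 150,
                                     probes_min = 3L, probes_max = 3L,
                                     probes_weights = NULL))
  rec <- probe_secretion(sim$matrix, sim$mappings, cutoff = 3)
  out <- classify_all(rec, 3)
  expect_equal(unname(out$counts["HALF"]), 0L)
})
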