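test_that("the landscape bins probes by location and ECER", {
  tx <- tibble::tibble(transcript_id = "T", length = 1000L,
                       cds_start = 100L, cds_end = 800L)
  mp <- annotate_probes(tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    transcript_id = "T",
    start = c(470L, 480L, 100L), end = c(530L, 540L, 160L)), tx)
  rec <- tibble::tibble(probe_id = c("p1", "p2", "p3"), transcript_id = "T",
                        mean_exosome = c(10, 20, 7), ecer = c(3, 3.5, 0.4))
  ls <- expression_location_landscape(rec, mp)
  expect_equal(sum(ls$count), 3)
  # p1 and p2 share the (0.50, [2,4)) cell; the cell holds their mean
  shared <- ls[ls$location_bin == 0.50 & ls$count == 2, ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$mean_expression, 15)
  # singleton cell keeps its own expression
  expect_equal(ls$mean_expression[ls$count == 1], 7)
})

test_that("landscape cell counts total the probe records on simulated data", {
  run <- recovery_run(1)
  ls <- expression_location_landscape(run$rec, run$sim$mappings)
  expect_equal(sum(ls$count), nrow(run$rec))
  expect_true(all(ls$location_bin >= 0 & ls$location_bin <= 0.98))
})

test_that("3'-proximal cells of the landscape are enriched under planted bias", {
  run <- recovery_run(1)
  joined <- dplyr::inner_join(run$rec, run$sim$mappings,
                              by = c("probe_id", "transcript_id"))
  strong <- joined[joined$ecer >= 3, ]
  expect_gt(mean(strong$relative_location > 0.5),
            mean(strong$relative_location <= 0.5))
})

test_that("representative pairs select extreme-ECER probes deterministically", {
  tx <- tibble::tibble(transcript_id = "T", length = 1000L,
                       cds_start = 100L, cds_end = 800L)
  mp <- annotate_probes(tibble::tibble(
    probe_id = c("pA", "pB", "pC"), transcript_id = "T",
    start = c(100L, 500L, 850L), end = c(160L, 560L, 910L)), tx)
  rec <- tibble::tibble(probe_id = c("pA", "pB", "pC"), transcript_id = "T",
                        mean_exosome = c(10, 12, 30), ecer = c(1, 4, 8))
  pr <- select_representative_pairs(rec, mp)
  expect_equal(pr$hi_probe, "pC")
  expect_equal(pr$lo_probe, "pA")
  expect_true(pr$hi_is_3prime)
  expect_equal(pr$ratio_3p_5p, 3)  # exo(pC)/exo(pA)
  expect_gt(pr$delta_location, 0)
  # permuting the input rows yields the identical pair
  pr2 <- select_representative_pairs(rec[c(3, 1, 2), ], mp)
  expect_equal(pr2, pr)
  # equal ECER everywhere: the more 3'-located probe wins the hi slot
  rec_tied <- rec
  rec_tied$ecer <- c(2, 2, 2)
  pr3 <- select_representative_pairs(rec_tied, mp)
  expect_equal(pr3$hi_probe, "pC")
  expect_error(select_representative_pairs(rec[1, ], mp),
               class = "exofrag_insufficient_data_error")
})

test_that("pair ratio correlation runs on simulated pairs", {
  run <- recovery_run(1)
  pairs <- select_representative_pairs(run$rec, run$sim$mappings)
  expect_equal(nrow(pairs), dplyr::n_distinct(run$rec$transcript_id))
  r <- pair_ratio_correlation(pairs)
  expect_gt(r$tau, 0)  # 3'-ward offset of the hi probe raises the ratio
})

test_that("location-secretion correlation is 1 for monotone data", {
  tx <- tibble::tibble(transcript_id = "T", length = 1000L,
                       cds_start = 100L, cds_end = 800L)
  starts <- seq(0L, 900L, by = 100L)
  mp <- annotate_probes(tibble::tibble(
    probe_id = sprintf("p%02d", seq_along(starts)),
    transcript_id = "T", start = starts, end = starts + 60L), tx)
  rec <- tibble::tibble(probe_id = mp$probe_id, transcript_id = "T",
                        mean_exosome = 1, ecer = seq_along(starts))
  expect_equal(location_secretion_correlation(rec, mp)$tau, 1)
})

test_that("stratum filters restrict the correlation records", {
  run <- recovery_run(1)
  rec <- run$rec
  mp <- run$sim$mappings
  all_r <- location_secretion_correlation(rec, mp)
  utr <- location_secretion_correlation(rec, mp, region = "UTR")
  cds <- location_secretion_correlation(rec, mp, region = "CDS")
  expect_equal(utr$n + cds$n, all_r$n)  # UTR (5'+3') and CDS partition
  utr3 <- location_secretion_correlation(rec, mp, region = "UTR3")
  utr5 <- location_secretion_correlation(rec, mp, region = "UTR5")
  expect_equal(utr3$n + utr5$n, utr$n)
  strong <- location_secretion_correlation(rec, mp, strength = 10)
  expect_lt(strong$n, all_r$n)
  cls <- run$classes$classes
  maj <- location_secretion_correlation(rec, mp, classes = cls,
                                        klass = "MAJORITY")
  keep <- cls$transcript_id[cls$klass == "MAJORITY"]
  expect_equal(maj$n, sum(rec$transcript_id %in% keep))
  expect_error(location_secretion_correlation(rec, mp, klass = "MAJORITY"),
               class = "exofrag_config_error")
  expect_error(location_secretion_correlation(rec[0, ], mp),
               class = "exofrag_insufficient_data_error")
})

test_that("region-stratified tables label empty strata as missing", {
  tx <- tibble::tibble(transcript_id = "T", length = 1000L,
                       cds_start = 100L, cds_end = 800L)
  starts <- seq(810L, 930L, by = 40L)
  mp <- annotate_probes(tibble::tibble(   # all probes in the 3' UTR
    probe_id = sprintf("p%d", seq_along(starts)),
    transcript_id = "T", start = starts, end = starts + 30L), tx)
  rec <- tibble::tibble(probe_id = mp$probe_id, transcript_id = "T",
                        mean_exosome = 1, ecer = c(12, 5, 2, 14))
  out <- region_stratified_correlations(rec, mp, cutoffs = 3,
                                        strength_threshold = 10)
  cds_rows <- out[out$region == "CDS", ]
  expect_true(all(is.na(cds_rows$tau)))
  expect_true(all(cds_rows$n == 0))
  expect_equal(sort(unique(out$selection)), c("MAJORITY", "STRONG"))
})

test_that("the probe-design bias control is near zero without planted bias", {
  sim <- simulate_dataset(sim_config(seed = 9, n_transcripts = 950,
                                     bias_beta = 0, frag_prob = 0,
                                     intact_secreted_prob = 0,
                                     background_frac = 0))
  rec <- probe_secretion(sim$matrix, sim$mappings, cutoff = 3)
  out <- probe_design_bias_check(rec, sim$mappings, split_cutoff = 3)
  expect_equal(nrow(out), 2)
  low <- out[grepl("<", out$stratum), ]
  expect_gt(low$n, 1000)
  expect_lt(abs(low$tau), 0.05)
})

test_that("the bias control detects deliberately planted design bias", {
  sim <- simulate_dataset(sim_config(seed = 10, n_transcripts = 500,
                                     bias_beta = 0, frag_prob = 0,
                                     intact_secreted_prob = 0,
                                     background_frac = 0))
  rec <- probe_secretion(sim$matrix, sim$mappings, cutoff = 3)
  # overwrite expression with a location-proportional artefact
  rec$mean_exosome <- sim$mappings$relative_location[
    match(paste(rec$probe_id, rec$transcript_id),
          paste(sim$mappings$probe_id, sim$mappings$transcript_id))] + 0.01
  out <- probe_design_bias_check(rec, sim$mappings, split_cutoff = 3)
  low <- out[grepl("<", out$stratum), ]
  expect_gt(low$tau, 0.9)
})

test_that("an empty stratum in the bias control is reported, not fatal", {
  tx <- tibble::tibble(transcript_id = "T", length = 1000L,
                       cds_start = 100L, cds_end = 800L)
  starts <- seq(0L, 900L, by = 300L)
  mp <- annotate_probes(tibble::tibble(
    probe_id = sprintf("p%d", seq_along(starts)),
    transcript_id = "T", start = starts, end = starts + 60L), tx)
  rec <- tibble::tibble(probe_id = mp$probe_id, transcript_id = "T",
                        mean_exosome = c(4, 2, 8, 1), ecer = c(5, 6, 7, 8))
  out <- probe_design_bias_check(rec, mp, split_cutoff = 3)
  expect_true(is.na(out$tau[grepl("<", out$stratum)]))
  expect_false(is.na(out$tau[grepl(">=", out$stratum)]))
})
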