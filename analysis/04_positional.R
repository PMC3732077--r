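#!/usr/bin/env Rscript
# Positional statistics: does secretion favour probes near the 3' end?
# Per-probe location-vs-ECER correlation (overall, strongly secreted,
# UTR/CDS strata), representative max/min-ECER probe pairs with 3'/5'
# expression ratios, the (location x ECER) expression landscape, and the
# probe-design bias control.

library(exofrag)

fx <- "results/fixtures"
tx <- read_transcript_models(file.path(fx, "transcripts.tsv"))
mp <- filter_min_probes(read_probe_table(file.path(fx, "probes.tsv"), tx), 2)
rec <- readr::read_tsv("results/ecer.tsv", show_col_types = FALSE)

overall <- location_secretion_correlation(rec, mp)
strong <- location_secretion_correlation(rec, mp, strength = 10)
utr <- location_secretion_correlation(rec, mp, region = "UTR")
cds <- location_secretion_correlation(rec, mp, region = "CDS")
correlations <- dplyr::bind_rows(overall, strong, utr, cds)
readr::write_tsv(correlations, "results/correlations.tsv")
for (i in seq_len(nrow(correlations))) {
  message(sprintf("%-22s tau = %+.3f (p = %.3g, n = %d probes)",
                  correlations$stratum[i], correlations$tau[i],
                  correlations$p_value[i], correlations$n[i]))
}

strata <- region_stratified_correlations(rec, mp, cutoffs = c(1, 2, 3, 5, 10),
                                         strength_threshold = 10)
readr::write_tsv(strata, "results/correlations_stratified.tsv")

pairs <- select_representative_pairs(rec, mp)
readr::write_tsv(pairs, "results/pairs.tsv")
message(sprintf("representative pairs: %d; hi-ECER probe is 3' of lo in %.0f%%",
                nrow(pairs), 100 * mean(pairs$hi_is_3prime)))
message(sprintf("pair ratio correlation: tau = %+.3f",
                pair_ratio_correlation(pairs)$tau))

landscape <- expression_location_landscape(rec, mp)
readr::write_tsv(landscape, "results/landscape.tsv")

bias <- probe_design_bias_check(rec, mp, split_cutoff = 3)
readr::write_tsv(bias, "results/design_bias.tsv")
message(sprintf("design-bias control: tau = %+.3f (%s), %+.3f (%s)",
                bias$tau[1], bias$stratum[1], bias$tau[2], bias$stratum[2]))
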