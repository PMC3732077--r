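#!/usr/bin/env Rscript
# Generate the study dataset: a two-compartment (exosome vs cell) probe-level
# expression matrix over ~2000 transcripts with planted 3'-terminal fragment
# secretion, written as the TSV bundle every later step reads.

library(exofrag)

out <- "results/fixtures"
cfg <- sim_config(seed = 1, n_transcripts = 2000)
sim <- simulate_dataset(cfg)
write_fixture_bundle(sim, out)

frag <- unique(sim$truth[, c("transcript_id", "fragmented")])
message(sprintf("simulated %d transcripts (%d probes), %.0f%% fragmented",
                nrow(sim$transcripts), nrow(sim$mappings),
                100 * mean(frag$fragmented)))
message(sprintf("median transcript length: %d nt (range %d-%d)",
                median(sim$transcripts$length), min(sim$transcripts$length),
                max(sim$transcripts$length)))
message("wrote ", out, "/{transcripts,probes,expression,groups,truth}.tsv")
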