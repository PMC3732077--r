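# exofrag

Probe-wise analysis of two-compartment expression microarray data to detect
secretion of 3'-end mRNA fragments in exosomes.

Exosomes released by cultured cells carry mRNA, and array probes
interrogate different regions of each transcript. If a transcript is
exported intact, all of its probes should be enriched in the exosomal
fraction together; if only a 3'-terminal fragment is exported, its 3'
probes are enriched while the 5' probes stay at cellular levels. `exofrag`
turns that observation into a pipeline:

* **ECER** — per-probe exosome-to-cell enrichment ratio,
  `ECER_i = mean_exo_i / max(mean_cell_i, eps)`, with a probe called
  *secreted* when `ECER_i >= c` (default cutoff `c = 3`, "strong" preset
  `c = 10`).
* **Fragmentation classes** — each transcript with >= 2 probes is
  classified by its secreted-probe count `s` of `k`: `ALL_SECRETED`
  (`s = k`), `HALF` (`2s = k`), `MAJORITY` (`2s > k, s < k`), `MINORITY`
  (`0 < 2s < k`), `NOT_SECRETED` (`s = 0`); the *fragmented fraction* is
  the share of the middle three among transcripts with any secreted probe.
* **Cutoff sweep** — classes recomputed over cutoffs 1..32, with Kendall
  tau-b trends of each class fraction.
* **Positional statistics** — Kendall tau-b between a probe's relative
  location (0 = 5' end, 1 = 3' end) and its ECER, overall and stratified
  by UTR/CDS, transcript class, or secretion strength; representative
  max/min-ECER probe pairs with 3'/5' expression ratios; a
  (location x ECER) expression landscape at 0.02 location steps; and a
  probe-design bias control. The tau-b engine uses exact permutation
  p-values for n <= 8 (ties included) and the tie-adjusted normal
  approximation otherwise.
* **Fragment-length upper bounds** — distance from the transcript 3' end
  to the 3'-most non-secreted probe in the 3' UTR (or the UTR border),
  summarized by median/IQR over transcripts with >= 3 UTR probes.
* **Synthetic data** — a generator that plants tunable 3'-terminal
  fragment secretion (`sim_config()` / `simulate_dataset()`), so every
  stage is testable against ground truth without external downloads.

## Worked example

The `analysis/` scripts form the full study over one simulated dataset;
running them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
simulated 2000 transcripts (4215 probes), 69% fragmented
median transcript length: 2060 nt (range 402-11901)

$ Rscript analysis/02_enrichment_classes.R
class counts at ECER >= 3:
  ALL_SECRETED    192
  HALF           1135
  MAJORITY         37
  MINORITY        107
  NOT_SECRETED    529
fragmented fraction of secreted transcripts: 86.9%

$ Rscript analysis/03_cutoff_sweep.R
fraction(ALL_SECRETED) vs cutoff   tau = -0.786 (p = 2.5e-10, 32 cutoffs)
fraction(HALF) vs cutoff           tau = +0.944 (p = 3.2e-14, 32 cutoffs)

$ Rscript analysis/04_positional.R
all probes             tau = +0.337 (p = 4.34e-236, n = 4215 probes)
ECER>=10 (max)         tau = +0.445 (p = 1.7e-173, n = 1775 probes)
design-bias control: tau = +0.010 (ECER < 3), -0.018 (ECER >= 3)
```

Reading: most planted-fragmented transcripts land in the partial-secretion
classes (86.9% of secreted transcripts are fragmented); as the secretion
call gets stricter the intact class shrinks while the half-secreted class
grows (tau = -0.79 / +0.94); probes closer to the 3' end are more strongly
secreted (tau = +0.34 overall, +0.45 among strongly secreted transcripts)
while raw expression is location-independent (the bias control sits at
~0). `analysis/05_fragment_lengths.R` and `analysis/06_recovery_benchmark.R`
add the fragment-length bounds and the ground-truth recovery rates
(mean sensitivity 0.914, specificity 0.977 over ten simulations).

The same computations are available programmatically:

```r
library(exofrag)
sim <- simulate_dataset(sim_config(seed = 1, n_transcripts = 2000))
rec <- probe_secretion(sim$matrix, sim$mappings, cutoff = 3)
cls <- classify_all(rec, 3)
fragmented_fraction(cls$counts)
location_secretion_correlation(rec, sim$mappings, strength = 10)
```

`run_pipeline()` performs the whole sequence from TSV inputs
(`transcripts.tsv`, `probes.tsv`, `expression.tsv`, `groups.tsv`) and
writes every table plus a JSON/text report.

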