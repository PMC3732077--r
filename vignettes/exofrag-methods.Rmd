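---
title: "Probe-wise detection of 3'-end mRNA fragments in exosomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-wise detection of 3'-end mRNA fragments in exosomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

Exosomes carry mRNA, but an expression microarray hybridized against
exosomal RNA cannot tell whether a signal comes from an intact message or
from a fragment. When an array design places several independent 60-mer
probes along each transcript, the *pattern* of probe signals becomes
informative: if a transcript is exported whole, all of its probes should be
enriched in the exosome fraction together; if only a 3'-terminal fragment
is exported, the 3' probes will be enriched while the 5' probes stay at
cellular levels. `exofrag` implements this probe-wise analysis for
two-compartment (exosome vs cell) intensity data.

## Per-probe enrichment

For probe $i$, with mean linear-scale intensity $\bar e_i$ over exosome
replicates and $\bar c_i$ over cell replicates, the exosome-to-cell
enrichment ratio is

$$\mathrm{ECER}_i = \frac{\bar e_i}{\max(\bar c_i, \varepsilon)},$$

where $\varepsilon$ is a floor against vanishing cell means (default: half
the smallest positive intensity in the matrix, so no unit scale is
assumed). A probe is *secreted* when $\mathrm{ECER}_i \ge c$; the default
cutoff is $c = 3$, with $c = 10$ as the preset for strongly secreted
material. Means are taken on linear intensities: processed two-channel
array signals are conventionally linear, and a log transform would turn
the ratio into a difference. Both boundaries are inclusive.

## Transcript classes

Each transcript with at least two probes (the minimum-probe filter is part
of the pipeline) is classified by its count of secreted probes $s$ out of
$k$:

* `ALL_SECRETED` — $s = k$: consistent with intact export;
* `HALF` — $2s = k$, $0 < s < k$;
* `MAJORITY` — $2s > k$, $s < k$;
* `MINORITY` — $0 < 2s < k$;
* `NOT_SECRETED` — $s = 0$.

The *fragmented fraction* is the share of `HALF`, `MAJORITY` and
`MINORITY` among transcripts with at least one secreted probe. Fed with
the published class counts (511, 687, 279, 145) it returns 68.5%.

Sweeping the cutoff over $1..32$ and recomputing classes at each value
produces the class-fraction curve; Kendall's $\tau_b$ between the cutoff
and a class's fraction summarizes its trend. Fractions are recomputed per
cutoff (not accumulated over bins), which we read as the construction
behind the published curves; the trend statistics are insensitive to that
distinction as long as one construction is used consistently.

## Positional statistics

Probe position is summarized by the midpoint of its interval divided by
the transcript length (0 = 5' end, 1 = 3' end), binned at 0.02 for the
expression landscape. A midpoint on a region boundary belongs to the
downstream region; all coordinates are 0-based half-open. The central
statistic is Kendall's $\tau_b$ between relative location and ECER over
probe records, optionally restricted by region (UTR = 5' and 3' UTRs
merged, with a `UTR3`-only option), by transcript class (`MAJORITY` =
"most fragments secreted"), or by transcript strength (maximum probe ECER
$\ge$ 10 by default; an all-probes variant is available). Per-transcript
representative pairs (highest- and lowest-ECER probe, ECER ties broken
toward the 3' end and then by probe id) and their 3'/5' exosomal
expression ratio are emitted alongside, since the published analysis
describes both constructions without fully resolving which fed the
headline correlation; the per-probe form uses all the data and is our
primary statistic.

The probe-design bias control correlates exosomal expression (not
enrichment) with location on both sides of the cutoff; a near-zero result
says probe placement does not itself predict signal strength, so a
location–ECER correlation cannot be a design artefact.

## The Kendall engine

$\tau_b$ is computed from concordant/discordant pair counts with the
standard tie corrections. Two-sided p-values come from full enumeration of
all $n!$ pairings when $n \le 8$ — exact under ties as well, where the
classical exact distribution does not apply — and otherwise from the
normal approximation with tie-adjusted variance

$$\mathrm{var}(S) = \tfrac{v_0 - v_t - v_u}{18} + v_1 + v_2$$

(the usual $v$ terms over tie-group sizes). Both regimes agree with
`stats::cor.test` where the latter is applicable, and the enumeration is
checked in the test suite against an independent brute-force oracle.

One caveat stated here because it matters for interpretation: the
analytic p-value treats probe records as exchangeable. Probes of the same
transcript share its secretion state and baseline, so record-level
p-values on real (or realistically simulated) data are approximate —
calibrated testing of the engine therefore uses a null simulation with
per-probe-independent noise (see below). This caveat applies equally to
any probe-level correlation analysis of this design.

## Fragment-length upper bounds

With probes as the only landmarks, the length of a secreted 3'-terminal
fragment is bounded by the distance from the transcript 3' end to the
3'-most *non-secreted* probe in the 3' UTR (its interval end), or by the
full 3'-UTR length when every UTR probe is secreted. Only transcripts with
at least 3 probes in the 3' UTR and at least one secreted UTR probe are
informative, optionally restricted to UTRs up to 1000 nt; the summary is
the median and IQR of the per-transcript bounds. The UTR border (rather
than the gene border) is the default limit — the alternative would count
CDS sequence into a "UTR fragment". Bounds are non-increasing in the
cutoff because secretion calls are.

# The synthetic-data generator

No public accession is attached to the original arrays, so the package
ships a generator that emulates the analyzed regime and plants a known
fragmentation signal; every pipeline stage is tested against that ground
truth.

**Transcripts.** Lengths are lognormal (median ≈ 2100 nt), truncated to
[400, 12000] nt. The 5' UTR takes 10% and the 3' UTR 35% of the length —
typical human mRNA proportions.

**Probes.** Probe counts per transcript default to 2 or 3, weighted 9:1
toward 2: expression arrays are dominated by transcripts with two usable
probes, which is also visible in the published HALF-class breakdown (656
of 687 transcripts split 1-vs-1). Placement is stratified-uniform — probe
$i$ uniform within the $i$-th of $k$ equal strata — which scatters probes
along the transcript without overlap, as coverage-oriented designs do.
Denser designs (e.g. 8–12 probes) are a configuration away and are used
for the fragment-length analysis, which needs 3 probes inside a UTR.

**Expression.** Cellular intensity of a probe is transcript baseline
(lognormal, log-sd 1.2) × probe efficiency (log-sd 0.4) × replicate noise
(log-sd 0.2), plus an additive array background (15% of the median
baseline) that gives weakly expressed probes near-unit ratios, as on real
arrays. Each transcript is *fragmented* (probability 0.7), *intact-secreted*
(35% of the remainder) or *not secreted*. Fragmented transcripts draw a
breakpoint $b$ and export $[b, 1]$ at the transcript's secretion gain
(median 8, log-sd 0.5 across transcripts); everything else reaches the
exosome sample only at the leak level (0.25). A per-probe ratio bias
(log-sd 0.45) models hybridization effects that do not cancel between
compartments, and the exosome block is median-ratio normalized, emulating
the normalization any processed two-compartment dataset has been through.

**Breakpoint law.** $b \sim \mathrm{Beta}(1 + 12\beta,\, 1 + 10.8\beta)$
with $\beta$ the 3'-bias strength: $\beta = 0$ gives uniform breakpoints
(a diffuse positional signal), and growing $\beta$ concentrates breakpoints
just 3' of the midpoint, sharpening the planted contrast between 5' and 3'
probes. We deliberately did not push the breakpoint mass toward the far 3'
end: fragments much shorter than the inter-probe spacing would carry no
probe at all and be invisible to *any* probe-level method, which would make
ground-truth recovery meaningless rather than hard. The planted fragment is
therefore "the 3'-terminal roughly-half" of the transcript, matching the
dominant 1-of-2-probes pattern the analysis classifies. A `utr3_only`
switch confines breakpoints to the 3' UTR, so only UTR probes carry the
signal — the configuration behind the region-stratified checks.

**Determinism.** All randomness flows from the single config seed through
derived sub-seeds; the caller's RNG state is saved and restored. Identical
config gives byte-identical fixture files.

## What the generator does and does not emulate

It reproduces: probe-sparse transcripts, intensity scales and
multiplicative noise of processed arrays, a background floor, variable
per-transcript secretion efficiency, normalization centering typical
ratios at 1, and 3'-terminal fragment export with tunable positional
sharpness. It does not simulate sequences or motifs, cross-hybridization,
within-lab batch structure, partial intact/fragment co-export of the same
transcript, or fragments shorter than the probe spacing. Passing tests on
this generator therefore certify the pipeline's statistical machinery and
its sign-level conclusions, not quantitative agreement with any particular
real dataset — the published dataset-dependent values (class counts, exact
$\tau$ magnitudes, fragment-length medians) require the original arrays.

## Calibration and reference problem sizes

The packaged checks run at sizes chosen to keep the full suite in a few
minutes on one core while leaving estimates stable:

* recovery benchmark: 10 simulations × 1500 transcripts under the
  reference configuration (frag_prob 0.7, bias 5, gain 8, noise 0.2);
  class-based recovery of planted fragmented transcripts reaches mean
  sensitivity ≈ 0.91 and specificity ≈ 0.98 at cutoff 3, and the
  location–ECER correlation is positive with vanishing p in every run.
* cutoff-sweep trends: on the same runs, the HALF fraction trends upward
  (median $\tau \approx +0.8$; the high-cutoff tail of a single run is
  noisy, so the suite asserts the median across runs) and the intact
  fraction downward ($\tau < 0$ in every run).
* null calibration: 200 simulations × ~2000 probes with the planted
  signal off *and* per-probe-independent noise (no secretion, no shared
  background), giving |τ| ≤ 0.05 and p-values uniform by the
  Kolmogorov–Smirnov criterion at the 1% level. The exchangeable null is
  the right target for certifying the engine; with transcript-level
  clustering left on, record-level p-values are over-dispersed (see the
  caveat above).

## Numerical and degenerate-input conventions

Division safety: the $\varepsilon$ floor (configurable) keeps ECER finite;
"retained in the cell" is implemented as *not secreted* (the inclusive
complement), which makes the five classes exhaustive — the reciprocal
reading (cell-enriched, ECER ≤ 1/c) is not used. Cutoffs where no
transcript is secreted yield missing curve fractions with a warning, and
strata with fewer than 3 records are reported as missing rather than
fatal. All-tied correlation inputs raise a typed error instead of
returning NaN. Classification requires $k \ge 2$; single-probe transcripts
must be filtered upstream and the readers enforce interval and uniqueness
invariants with errors naming the offending record.

# Known limitations

* Sensitivity of fragment detection is bounded by probe geometry: a
  breakpoint outside a transcript's probe span is undetectable from that
  transcript, so recovery rates depend on probe density more than on
  noise.
* The fragment-length bounds are upper bounds under the stated landmark
  rule; with 2–3 probes per transcript almost no transcript qualifies,
  and with denser designs the bounds hug the UTR length whenever
  breakpoints sit 5' of the UTR.
* Record-level correlation p-values assume exchangeability (above).
* The ΔCT helper assumes amplification efficiency 2.0 per cycle.
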