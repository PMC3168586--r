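---
title: "Methods: hotspot-targeted aCGH CNV calling and rare-CNV burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot-targeted aCGH CNV calling and rare-CNV burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The measurement and its model

Array CGH measures, at each oligonucleotide probe, the log2 ratio of test
to reference DNA abundance. On a two-copy autosome the expectation is 0; a
heterozygous deletion shifts it toward log2(1/2) = −1 and a single-copy
duplication toward log2(3/2) ≈ +0.585 — note the asymmetry: duplications
are intrinsically harder to see. A hotspot-targeted design spends most of
its probes inside rearrangement hotspots (regions flanked by highly
identical segmental duplications) at a median spacing of 2.6 kbp, and
covers the remaining genomic backbone at 36 kbp.

The calling model treats each chromosome of each sample as a sequence of
probe z-scores emitted by a three-state hidden Markov chain:

* **Normalization.** z-scores use chromosome-specific means and standard
  deviations (sample sd, n − 1). This is deliberately local: it removes any
  whole-sample baseline (dye/reference effects) exactly and makes states
  comparable across chromosomes. The cost is a mild attenuation when a CNV
  occupies a large fraction of one chromosome, since the event itself
  inflates that chromosome's sd; for hotspot-scale events (≪ chromosome
  length) the effect is negligible. Chromosomes with fewer than two probes
  or zero variance are rejected rather than silently passed through.
* **Emissions.** Gaussian in z units: means −2.5 / 0 / +2.0 for
  decreased / normal / increased, unit sds. With probe noise of sd 0.2–0.4
  on the log2 scale, a heterozygous deletion lands near z = −2.5 to −5 and
  a duplication around +1.5 to +3, so the defaults sit where the signal
  does while unit sds keep single noisy probes cheap to explain as normal.
* **Transitions.** Homogeneous: self-transition 0.999, the remaining mass
  split evenly. We keep the chain blind to genomic distance on purpose —
  all distance handling lives in the explicit merge rules below, so those
  rules (not an opaque transition kernel) determine how gaps are treated.
  One consequence worth knowing: at stay-probability 0.999 a state switch
  costs about 7.6 log units, so once a segment is entered, up to two
  adjacent near-zero probes are absorbed into it rather than triggering a
  return to normal (three or more flip it back). The bridging rule below
  has the same flavour, so decoded segments and bridged segments compose
  coherently.
* **Decoding.** Viterbi (single best path), matching the one-state-per-
  probe reading of the output; posterior marginals are not computed. All
  arithmetic is in log space; there is no underflow for any finite z. Exact
  score ties are broken toward normal, then decreased, so degenerate inputs
  decode deterministically.

## From state paths to variants

Two rules turn per-probe states into calls, applied per chromosome:

1. **Segment rule (50 kbp).** Consecutive probes of the same non-normal
   state belong to one segment while the start-to-start gap between
   neighbours is below 50 kbp; a gap of 50 kbp or more splits the run. We
   measure start-to-start; an alternative reading ("when merged") would
   re-check a fused segment's internal gaps after fusion, but since fusion
   never changes inter-probe gaps the two readings coincide for this rule.
2. **Bridging rule (≤ 5 probes, ≤ 10 kbp).** Two same-state segments
   separated by an intervening sequence of at most 5 probes spanning at
   most 10 kbp (bases strictly between the first segment's end and the
   second's start) are called as a single variant, with the intervening
   probes counted into the probe support and the mean z recomputed over
   every covered probe — the intervening sequence is part of the variant,
   not an annotation. The rule is applied until a fixed point, so the
   output is idempotent under re-application. Only genomically adjacent
   segments bridge: an opposite-state segment between two candidates blocks
   the bridge.

A call records sample, interval (1-based inclusive, matching how published
coordinates are printed; all BED I/O converts to 0-based half-open), state,
probe count, mean z and size. Sex chromosomes are excluded by default
because a single male reference makes chrX/chrY ratios track the sample's
sex rather than copy number; `include_sex_chroms = TRUE` overrides.

## Filtering and burden

Post-call thresholds default to size > 50 kbp, ≥ 5 probes and
|mean z| ≥ 1.5. The size cutoffs ("> 50 kbp", "> 500 kbp" for large calls)
are strict inequalities as conventionally printed; the probe and z minima
are field conventions — published pipelines filter on "size, z-scores, and
probe counts" without printing values, so ours are explicit, conservative
defaults exposed in `filter_policy()`.

Rarity is assessed against one or more control catalogs (interval, carrier
count, cohort size). A call's frequency in a catalog is the summed carrier
count of records matching at ≥ 50% reciprocal overlap divided by the cohort
size, capped at 1; a call is rare only if that frequency is below 1% in
*every* catalog. The multi-catalog conjunction mirrors the common practice
of reporting counts against both a large external reference set and the
platform-matched control cohort.

The burden statistic is Fisher's exact test on the 2×2 carrier table
(carrier = sample with ≥ 1 call > 500 kbp; each sample counts once, and
samples with no calls must be on the roster so they count as
non-carriers). The test is computed in-package by enumerating the
hypergeometric support with log-gamma point masses (stable to cohort sizes
of order 10^5). Sidedness matters: for the table 6/113 vs 6/306 the
one-sided (cases-enriched) p is 0.0727 and the two-sided p (sum of point
probabilities ≤ the observed one, the standard Fisher convention) is
0.0944. A printed "P = 0.072" for this table can only be the one-sided
value, so both are always reported and the `tidy()` method labels the
alternative explicitly. Tables with a zero margin are flagged degenerate
with p = 1. Percentages in cohort summary tables are rounded half-up to
one decimal and rendered without the decimal when integral ("0 (0%)",
"6 (20%)", "30 (100%)"), reproducing the usual clinical-table style.

## The simulator: what it emulates and what it does not

`generate_design()` places non-overlapping hotspot regions (default 1.2
Mbp each — the value implied by a ~135,000-probe budget split between 107
hotspots at 2.6 kbp and a genome-scale backbone at 36 kbp) uniformly at
random, then tiles probes with log-normal inter-probe gaps whose *median*
equals the stated spacing (sdlog 0.25, floored at the 50-bp probe length).
Log-normal jitter was chosen over an exponential because an exponential
with the right median has a mean 1.44× larger, which would under-tile the
array by ~30%; the log-normal keeps both the median spacing and the probe
budget (counts land within a few percent of length/spacing) while still
producing occasional > 50 kbp backbone gaps that exercise the segment
rule.

The default genome is deliberately reduced — three chromosomes of 30 Mbp,
18 hotspots, ≈ 10,000 probes — so that cohort-scale tests run in seconds;
full-scale designs are reachable through `array_design_spec()` arguments.
The noise model is a per-sample Gaussian baseline offset (sd 0.05) plus
independent per-probe Gaussian noise (sd 0.2, a typical aCGH magnitude;
the platform's true noise is not published, so this is a configurable
convention). `simulate_cohort()` assigns each candidate event to each
sample by an independent Bernoulli draw at its carrier frequency and
returns the exact truth. `simulate_recovery_benchmark()` packages the
package's standard detection benchmark: 20 samples, each with one embedded
deletion and one duplication of 15–30 probes placed inside hotspots, probe
noise sd 0.18 so that both event kinds sit at a signal-to-noise ratio
(|log2 shift| / sd) of at least 3 — 5.6 for deletions, 3.25 for
duplications.

Not modelled: GC/dye waves, probe-specific affinity, mosaicism, homozygous
deletions, sex chromosomes, and breakpoints extending into segmental
duplications beyond probe coverage (calls report the probe-supported span
only — which is also why a recurrent event's published "1.35 Mbp" label
can exceed the span its probes support). Passing the recovery benchmark
therefore demonstrates the calling and merging logic under idealized
noise, not performance on wave-affected production arrays; on real data
the z-emission means and the post-call z threshold are the knobs to
revisit first.

## Numerical and testing choices

* Every generator is a pure function of (spec, seed); RNG state is
  restored after use, so simulations do not perturb the caller's stream.
* Viterbi correctness is checked against exhaustive maximization over all
  3^n paths for n ≤ 8 across 200 random parameter draws, and the exact
  test against direct hypergeometric-support enumeration (and
  `stats::fisher.test`) on hundreds of random tables with N ≤ 60; the
  bridging rule is checked for idempotence on 1,000 random segmentations.
  These sizes keep the full suite and the acceptance script to a few
  minutes on one CPU while exercising every code path.
* Counts of ~350 or ~1,000 CNVs per real cohort are properties of
  full-scale arrays and cohorts and are not reproduced at the reduced
  problem sizes; the recovery benchmark (sensitivity ≥ 0.95, ≤ 0.5 false
  calls per sample at 50% reciprocal overlap) is the desk-scale stand-in.

## Known limitations

Fixed HMM parameters (no per-sample Baum–Welch refit); no posterior
confidence per call; no joint multi-sample calling; rarity matching is
interval-overlap only, ignoring event type frequency differences between
catalogs built on different platforms; and the burden test treats carriers
as exchangeable, with no covariates — use a regression framework if
ancestry or batch structure matters.
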