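# cnvburden

Rare copy-number variants (CNVs) — deletions and duplications relative to
the two-copy reference state — concentrate in genomic "hotspots" flanked by
segmental duplications, and an excess burden of large rare CNVs has been
reported across a range of neuropsychiatric phenotypes. `cnvburden` is a
tidyverse-style R package for the analysis that underlies such studies when
the assay is hotspot-targeted array comparative genomic hybridization
(aCGH): it takes per-probe log2 intensity ratios, calls CNVs, filters them
to rare events against control catalogs, and tests whether cases carry more
large CNVs than controls. It is aimed at statistical geneticists who want
each stage of that pipeline as an inspectable, testable function rather
than a vendor black box.

## The method

Given a probe design (positions plus hotspot/backbone class) and one log2
ratio per probe per sample:

1. **Normalization.** Within each (sample, chromosome), log2 ratios are
   standardized to z-scores, `z = (x − mean) / sd` (sample sd), which
   removes whole-sample baseline offsets exactly and puts all chromosomes
   on one scale.
2. **Segmentation.** A three-state hidden Markov model (states *decreased*,
   *normal*, *increased*; Gaussian emissions in z units with means −2.5 /
   0 / +2; shared self-transition probability 0.999) is decoded by Viterbi
   per chromosome.
3. **Merging.** Consecutive same-state probes form a segment while their
   start-to-start gap stays below 50 kbp; two same-state segments separated
   by ≤ 5 intervening probes spanning ≤ 10 kbp are then fused into a single
   variant together with the intervening probes.
4. **Filtering.** Calls are retained above size (> 50 kbp), probe-count
   (≥ 5) and |mean z| (≥ 1.5) thresholds, and kept as *rare* only when
   their carrier frequency is below 1% in every supplied control catalog
   (events matched at 50% reciprocal overlap).
5. **Burden.** Carriers of large calls (> 500 kbp) are counted per cohort
   and compared by Fisher's exact test — computed in-package over the full
   hypergeometric support with log-gamma arithmetic, reporting both the
   one-sided (cases enriched) and two-sided p-values and the sample odds
   ratio.

Because raw microarray data for such studies are rarely deposited, the
package ships a seeded simulator: hotspot-targeted designs (median probe
spacing 2.6 kbp inside hotspot regions, 36 kbp in the backbone), cohorts
with embedded deletions (log2 shift −1) and duplications (+0.585) at
configurable sizes and carrier frequencies, and recovery scoring of calls
against the simulated truth.

## Worked example

```r
library(cnvburden)

design <- generate_design(array_design_spec(), seed = 11)  # ~9,900 probes
hs <- hotspot_regions(design)
events <- cnv_spec(
  chrom = hs$chrom[c(2, 9)],
  start = hs$start[c(2, 9)] + 20000,
  end   = hs$start[c(2, 9)] + c(80000, 120000),
  kind  = c("deletion", "duplication"),
  carrier_frequency = c(0.3, 0.2))
sim   <- simulate_cohort(design, events, events[0, ],
                         n_cases = 6, n_controls = 6, seed = 12)
calls <- call_cnvs(sim$profiles, design)
calls
#> # A tibble: 4 × 8
#>   sample_id chrom    start      end state     n_probes mean_z size_bp
#> 1 case_002  chr1  14536342 14595589 decreased       23  -4.09   59248
#> 2 case_004  chr2  13943807 14041244 increased       38   2.65   97438
#> 3 case_005  chr1  14536342 14593301 decreased       22  -4.60   56960
#> 4 case_006  chr1  14536342 14593301 decreased       22  -4.53   56960
```

Four samples drew an embedded event and all four are recovered: deletions
appear as *decreased* calls with strongly negative mean z, the duplication
as an attenuated *increased* call. `score_recovery()` confirms this against
the truth:

```r
score_recovery(calls, sim$truth, n_samples = 12)
#> CNV recovery: 4/4 truth events matched (sensitivity 1.000), 0.00 false calls/sample
```

The burden stage reproduces the canonical large-CNV comparison of 6
carriers among 113 cases versus 6 among 306 controls:

```r
fisher_exact(burden_table(6, 107, 6, 300))
#> Carrier burden (Fisher's exact test)
#>   cases:    6/113 carriers
#>   controls: 6/306 carriers
#>   odds ratio = 2.8
#>   p (one-sided, cases enriched) = 0.07273
#>   p (two-sided) = 0.09442
```

The one-sided test is what a printed "P = 0.072" for this table
corresponds to; the two-sided value is 0.094. `tidy()` and `glance()`
methods return these as tibbles, and `run_end_to_end(run_config(...))`
drives the whole simulate → call → filter → burden workflow to disk with
provenance headers and byte-reproducible output.

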