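---
title: "Quantifying replication-transcription conflicts from differential ChIP-Seq, qPCR and 2D gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication-transcription conflicts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliconflict)
```

## The problem

On a circular bacterial chromosome, replication starts at a single origin
(*oriC*) and proceeds bidirectionally to the terminus. Every transcribed
gene is therefore either *co-directional* (RNA polymerase moves with the
fork; leading-strand genes) or *head-on* (against the fork; lagging-strand
genes). Encounters between the replisome and transcription complexes slow
or stall the fork, head-on encounters far more severely, and accessory
helicases exist to clear these conflicts. Replisome occupancy measured by
ChIP of the replicative helicase is a sensitive proxy for fork dwell time:
where the fork stalls, replicative-helicase ChIP signal accumulates.

`repliconflict` implements the downstream arithmetic of such experiments:
subtraction-based normalization of ChIP-Seq coverage, between-condition
differential signal, per-region quantification, an origin-aware two-zone
background model with fold-over-background peak calling, orientation
classification on the two replichores, the ChIP-qPCR double-ratio
enrichment statistic, and 2D-gel Y-arc profiling. A seeded generative
model produces every input, so each stage is testable without sequencing
data.

## Geometry

`circular_genome(L, ori, ter)` fixes the coordinate system: 0-based,
half-open intervals, everything reduced modulo `L`. The *right* replichore
is the arc from ori toward ter in increasing coordinate; `ter` defaults to
the antipode of `ori`, which is approximately true for most bacterial
chromosomes and exact for the synthetic work here. `distance_from_ori()`
is the fork travel distance, the natural covariate for everything
replication-coupled (copy number, background zones).

Orientation is classified from the replichore containing the region
midpoint: a `+`-strand gene on the right replichore is co-directional, and
so on. Genes spanning ori or ter have no single fork direction; they are
reported `ambiguous` by default, with `force_midpoint = TRUE` available to
classify them by midpoint anyway. Published analyses rarely state how such
genes were treated, so both behaviors are exposed rather than guessed.

```{r}
g <- circular_genome(4215606)    # a 4.2-Mb Firmicute-like chromosome
ann <- synthetic_annotation(g, n_genes = 12, seed = 1)
table(classify_orientation(ann, g))
```

## The generative model

`simulation_scenario()` fixes the study conditions. Its defaults are the
conditions the pipeline is designed for, not tuning knobs:

* **Copy-number gradient** `R^(1 - d/d_max)` with `R = 2`: the standard
  marker-frequency form for exponentially growing cells with about one
  overlapping round of replication; ori-proximal DNA is about twice as
  abundant as terminus DNA. The data this emulates only warrant
  "slightly higher" ori-proximal background, so a single-parameter
  exponential law is the most defensible choice.
* **Stalling enrichment** `e(x) = 1 + s_g · m · w(x)` inside listed genes.
  The shape weight `w` is `uniform` (mean 1) or `three_prime_ramp`, a
  linear 0 to 2 ramp from the transcription start to the 3' end (mean
  exactly 1). The ramp is the default expectation for head-on genes, where
  the replisome penetrates from the 3' side and signal piles up there;
  no shape has been established for co-directional genes, so they default
  to uniform.
* **Condition multiplier** `m = 3` under helicase depletion: depletion
  roughly triples replicative-helicase dwell at a strong head-on reporter.
  Because no per-gene depletion response is established, the multiplier is
  a single scenario-level factor and several presets are plausible; 3 is
  the package default.
* **Fragment lengths** lognormal with mean 250 bp, sd 100 bp —
  sonication-like; fragment midpoints are drawn from the product of
  baseline and enrichment, and intervals wrap the circle.
* **Depth** 750,000 fragments per sample, a typical per-sample bacterial
  ChIP-Seq run. Mock IPs see configured sticky intervals but never the
  specific stalling signal; IPs see both.

What the generator does *not* emulate: PCR duplicates, mappability and GC
bias, paired-end insert inference, and real transcription-unit structure
(operons, promoters, terminators). Passing tests therefore demonstrate
that the arithmetic is correct and well-calibrated under this statistical
structure, not that any particular biological dataset would reproduce.

```{r}
sc <- simulation_scenario(g, ann, n_fragments = 50000)
round(copy_number_baseline(c(0, 1053901, 2107803), sc), 3)  # ori, mid, ter
```

## Normalization and differential signal

The analysis is subtraction-based throughout, mirroring the established
workflow for replisome ChIP: IP minus input per base (`normalize_chip()`),
optionally minus the input-normalized mock IP (`mock_correct()`, used for
epitope-tag ChIP where antibody stickiness is a concern, not for the
native replicative-helicase ChIP), then depleted-condition minus
present-condition (`differential()`). Negative values are retained at
every step; peak calling uses region maxima, so clamping would only
distort the background model. Because subtraction is depth-sensitive,
tracks are scaled to a common mean first (`scale_to_common_depth()`);
the step is separate and skippable for strict replication of designs
whose samples were sequenced to near-equal depth.

## Quantification, background, calling

`quantify_regions()` reports, for every gene and every intergenic region
strictly longer than 5 nt: the maximum signal, mean signal, area under
the curve and length-normalized AUC. `estimate_background()` implements
the two-zone background: windows of 100 kb are tiled along each
replichore by fork travel distance; the zone within 300 kb of ori (where
the copy-number gradient raises the baseline) and the distal zone are
estimated independently as the average of per-window maxima over
peak-free windows. The published criterion (windows devoid of peaks) is
not an algorithm, so the package makes it one: initialize the zone
background as the median of window maxima, flag windows whose maximum
exceeds 5x the running background, recompute the background as the mean
over unflagged windows, iterate to a fixed point. The procedure is
deterministic and converges because the flag set is monotone in the
background between iterations; ties at exactly the threshold resolve to
"not flagged" (strict inequality). Where a published workflow may have
averaged region maxima rather than window maxima inside peak-free
windows, this implementation uses window maxima; on the synthetic nulls
the two differ by well under the calling tolerance.

`call_peaks()` is strict: a region is peak-containing only when its
maximum exceeds `threshold` times its zone background (`> 5`, not `>=`),
so a region at exactly 5-fold is not called. Calls at threshold 6 are
always a subset of calls at threshold 5.

```{r}
b <- coverage_track(10 * copy_number_baseline(0:(g$length_bp - 1), sc) / 2, g)
estimate_background(b)
```

## ChIP-qPCR and RT-qPCR statistics

Template abundance is `E^(-Ct)` with efficiency `E` defaulting to the
ideal 2 (per-locus overrides supported). Fold enrichment is the double
ratio (test chip / test input) / (reference chip / reference input),
computed on abundances; the reference locus is a low-conflict control
region (`yhaX` by convention). The statistic is invariant to any global
Ct shift and equals exactly 1 for the reference locus itself. Technical
replicates are averaged on the Ct scale before conversion by default;
averaging per-replicate folds instead is exposed (`reduce = "fold"`)
because published error bars could have been computed either way.
Relative mRNA level is `E^(ct_ref - ct_gene)`. Under Gaussian Ct noise of
sd σ, the log fold estimate is unbiased with sd `2 σ ln E` (four
independent wells), which the test suite verifies by simulation.

## 2D-gel Y-arc profiling

Branched (Y-shaped) replication intermediates run as an arc on a 2D
agarose gel; local arc intensity reports fork dwell at the corresponding
fragment size. The package replaces interactive lane-conforming with a
deterministic parametric lane: a natural cubic spline through ordered
control points, chord-length parametrized, resampled at 450
arc-length-uniform positions (the conventional resolution for a full
arc). At each position the intensity is the bilinear-interpolated image
integrated along the local normal over the lane width at 1-px steps.
The 1N spot (non-replicating linear fragments) is quantified as the spot
rectangle sum minus a local frame median times the area, and serves as
the loading control. Ratio profiles between conditions are formed on
loading-normalized intensities; points where the denominator falls below
5% of its maximum are masked before summarizing, because ratios against
gel background diverge — published workflows do not state their
handling, so the floor is explicit and adjustable, and `floor_frac = 0`
recovers the unmasked behavior.

## The composed pipeline

`run_pipeline()` chains the stages (simulate or ingest, scale, normalize,
differential, quantify, background, call) under a single master seed with
named substreams per sample, and writes wiggle tracks, region and peak
tables, a background report and a parameter log. Identical configuration
and seed give byte-identical tables. A YAML configuration
(`read_run_config()`) and a thin command-line wrapper
(`inst/scripts/run_pipeline.R`) expose the same composite; the individual
exported functions are the per-stage entry points.

## Numerical choices and problem sizes

* Coverage is stored dense (one double per base); a 4.2-Mb genome is ~34
  MB, and exactness beats sparse cleverness at this scale.
* Pileup is computed by difference-array accumulation; it satisfies the
  conservation law sum(coverage) = sum(fragment lengths) exactly, and the
  test suite checks it against a per-base brute-force scan.
* Wiggle output is 1-based fixedStep step-1 (dialect conversion at I/O
  only); GFF3 is converted from 1-based inclusive to the internal 0-based
  half-open convention at parse time.
* The package's own validation simulations use the full 4.2-Mb genome at
  750k fragments per sample for the detection and gradient checks (20
  seeded replicates for detection, which completes in a few minutes), and
  smaller 0.1-1 Mb genomes for distributional unit tests where genome
  size is not the quantity under test.

## Known limitations

* The background model assumes the proximal zone fits within each
  replichore; degenerate geometries (proximal span exceeding a replichore)
  raise an estimation error rather than silently pooling.
* No replicate-aware statistical testing: peaks are called from single
  differential tracks by fold, as in the workflow this reproduces.
* Arc sampling assumes the arc (expanded by the lane width) stays inside
  the image; automatic arc detection and densitometric film calibration
  are out of scope.
* Real-data idiosyncrasies (duplicates, mappability, copy-number
  perturbations from replication arrest) are not modeled; conclusions
  from synthetic calibration transfer to real data only insofar as those
  effects are small or corrected upstream.
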