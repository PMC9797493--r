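---
title: "Detecting mosaic megabase deletions from seed-coat DNA: methods and models"
author: "MosaicLOH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic megabase deletions from seed-coat DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MosaicLOH)
library(S4Vectors)
library(IRanges)
```

## The problem

A plant grown directly from irradiated material (the M1 generation) is a
mosaic: different cell lineages carry different radiation-induced
mutations. In a double heterozygote for two seed-pigment genes
(`TT4`/`tt4 TT8`/`tt8`), losing the one functional allele at either locus
— loss of heterozygosity, LOH — in the lineage that builds a seed coat
produces visibly pigment-less seeds, and the mature-seed colour tells the
two loci apart. Molecular confirmation works on *seed-coat-enriched* DNA,
which unavoidably contains non-mutated contaminating cells (endosperm,
embryo). Everything quantitative in this package follows from that
mixture structure.

MosaicLOH implements the four analysis stages such a screen needs:

1. **Read-depth dosage (RRD)** — find megabase heterozygous deletions as
   runs of depressed binned coverage and estimate what fraction of cells
   carries them.
2. **Comparative-Ct qPCR** — quantify the TT4:TT8 template copy ratio,
   normalized to a non-irradiated control, and predict the ratio a given
   mosaic should show.
3. **Screening statistics** — exact binomial tests of the observed
   tt4:tt8 mutant-class split under an equal-probability null and under a
   gene-length-weighted null.
4. **Survival-curve fitting** — the single-hit multitarget model used to
   choose the irradiation dose.

A synthetic-data generator produces inputs for all four stages with
exactly the statistical structure the estimators assume, so the full
pipeline is testable without any sequencing archive.

## The mixture copy-number model

Let `m` be the fraction of cells in the sampled tissue carrying a de novo
heterozygous deletion. Over the deleted interval the mean copy number is
`c = 2 - m`; elsewhere `c = 2`. Binned mean depth is proportional to
`c/2`, so after normalizing each bin by the median per-bin depth over all
five nuclear chromosomes (the *relative read depth*, RRD):

* a non-deleted bin has RRD ≈ 1,
* a bin fully inside the deletion has RRD ≈ `1 - m/2`,
* inverting gives the mutant-fraction estimator `m = 2 (1 - RRD)`,
  clamped to `[0, 1]` (`estimateMutantFraction()`).

At `m = 0.7` the deleted plateau sits at RRD 0.65 — the level a
contaminated seed-coat sample with a fully heterozygous deletion in its
mutant lineage realistically shows.

```{r rrd}
layout <- arabidopsisLayout()
del <- genomicInterval("Chr4", 5600000, 7100000, layout)  # 1.5 Mb over TT8
bins <- simulateBins(layout, del, mutantFraction = 0.7, meanDepth = 50,
                     seed = 1)
rrd <- computeRRD(bins)
rrd
mean(mcols(rrd)$rrd[overlapsAny(rrd, del)])        # ~0.65
locusRRD(rrd, loci(layout)["TT8"])                 # same plateau
callDeletions(rrd)
```

### Parameters that matter

* `binSize` (default 100 kb): the resolution of the scan. Megabase
  deletions span ≥ 10 bins, so edge effects are negligible; partial
  bin–deletion overlap scales copy number by the overlap fraction, the
  least surprising rule at this resolution.
* `threshold` (default 0.8 RRD) and `minBins` (default 3): a bin is
  "depressed" below 0.8, and only runs of ≥ 3 consecutive depressed bins
  (300 kb) are called. The defaults separate the 0.65 plateau from the
  ≈1 background at ≥ 30x coverage with a wide margin.
* `gap` (default 0): runs are *not* merged across an above-threshold bin;
  setting `gap = 1` bridges single noisy bins if needed.
* The normalization median is taken over the per-bin mean depths of
  **all** bins, including the final partial bin of each chromosome and
  zero-depth bins; with megabase chromosomes at 100-kb bins this choice
  is numerically invisible, and an all-zero table is an error rather than
  a divide-by-zero.

### What the generator emulates — and what it does not

`simulateBins()` draws per-bin *read counts* as Poisson with mean
`width · λ · c / (2 · readLength)` (λ = `meanDepth`, the expected mean
depth at copy number 2; `readLength` 150 bp) and reports the bin's mean
per-base depth, `count · readLength / width`. Bin coverage is therefore
Poisson-distributed with mean exactly `λ c / 2`, and the per-bin
coefficient of variation at 50x and 100-kb bins is ~0.8% — the scale of
counting noise in real binned coverage. An optional negative-binomial
`dispersion` parameter adds overdispersion; it defaults to off.

Real data differ in ways the generator deliberately ignores:
mappability and GC biases that make real RRD noisier and locally
structured, duplicated/repetitive regions, and organellar reads. Passing
tests on synthetic data therefore demonstrate the *estimators* are
correct under the stated model, not that real libraries are free of
artefacts; with real data the same functions apply after the usual
mapping-quality filtering upstream.

The round trip is tested: simulating at `m`, computing RRD and inverting
recovers `m` within ±0.05 for coverage ≥ 30x and ≥ 10 deleted bins.

## Comparative-Ct qPCR and the forward ratio model

For each sample, `ΔCt = mean(Ct_TT4) − mean(Ct_TT8)`; the
control-normalized ratio is `2^−(ΔCt_sample − ΔCt_control)`, assuming
perfect doubling per cycle (an efficiency parameter is out of scope; the
generator likewise amplifies at exactly 2.0/cycle). Replicates are
summarized by the mean Ct for the point estimate; `qpcrRatios()` also
reports the standard error over replicate-wise ratios, matching the
mean ± SE convention for biological replicates.

The *forward* model predicts what a mosaic should show. In the control
double heterozygote the TT4 qPCR target sits only on the wild-type allele
(the mutant tt4 allele is itself a large deletion removing it): 1 copy
per cell. The tt8 lesion is a single-base deletion, so the TT8 target
sits on both alleles: 2 copies. A de novo deletion removes the wild-type
allele at the mutated locus in the mutant fraction `m`:

* tt4-type mosaic: TT4 relative copies `1 − m` (0.25 at `m = 0.75`),
  TT8 unchanged → ratio `1 − m`;
* tt8-type mosaic: TT8 relative copies `(2 − m)/2` (0.65 at `m = 0.7`),
  TT4 unchanged → ratio `2/(2 − m)` ≈ 1.54 at `m = 0.7`.

```{r qpcr}
expectedRatio(0.75, "tt4")
expectedRatio(0.7, "tt8")
ct <- rbind(simulateQpcr("tt8", m = 0.7, seed = 2, sample = "mut"),
            simulateQpcr("control", seed = 3))
qpcrRatios(ct, control = "control")
```

The ratio is monotone in `m` in opposite directions for the two mutant
types, which is what makes it diagnostic. `classifyMutant()` combines the
ratio with the deletion calls, treating ratios within `[1/1.25, 1.25]`
as inconclusive: the assay only promises a directional signal, and the
guard band keeps replicate noise from driving a classification. A call
overlapping a marker locus and a ratio pointing the other way yield
`"unclassified"` rather than a guess.

## Exact binomial screening statistics

With `k` tt4-type among `n` mutants, `binomTestExact()` computes exact
tail sums of the Binomial(`n`, `p0`) pmf — no normal approximation. The
two-sided p-value uses the minimum-likelihood ("minlike") rule: the
probability of all outcomes no more likely than the observed one. At
`p0 = 0.5` this equals twice the smaller tail; for other nulls the
conventions genuinely differ and minlike is the common exact-test choice.
The pmf comes from `dbinom`, which is computed in log space internally
and is accurate far beyond the `n ≤ 10^4` this analysis needs; tests
verify exact agreement with a brute-force `choose()` enumeration for all
`n ≤ 25` and with the reference two-sided implementation.

Two pre-specified nulls are relevant: equal mutability of the two loci
(`p0 = 0.5`, two-sided), and mutability proportional to gene length,
`p0 = lTT4 / (lTT4 + lTT8) = 1789/6432 ≈ 0.28`, one-sided. The full
precision fraction is used in the test; 0.28 is display rounding.

```{r screening}
counts <- screeningCounts(2588, nTT4 = 2, nTT8 = 17)
binomTestExact(2, 19, 0.5)$p.value                     # < 0.001
binomTestExact(2, 19, lengthWeightedNull(1789, 4643), "less")$p.value
mutationFrequency(counts); classRatio(counts)
```

Type-I calibration is property-tested: screening counts simulated under
the null and tested at α = 0.05 reject at the exact discrete attained
size (~0.049 at `n = 1000`), within Monte-Carlo error over 10,000
replicates. No multiplicity correction is applied — exactly two
pre-specified tests exist.

## Single-hit multitarget survival model

`S(D) = 1 − (1 − e^{−D/D0})^N`: each of `N` targets is inactivated
independently with 1/e dose `D0`, and the plant dies when all are hit.
The quasi-threshold ("shoulder") dose `Dq = D0 ln N` is where survival
starts to fall sharply from ~100% — the quantitative counterpart of
reading the shoulder off the curve, and the dose used (halved) to choose
a mutagenesis exposure.

`fitMultitarget()` does unweighted least squares on the linear survival
scale with bounds `D0 > 0`, `N ≥ 1` (Levenberg–Marquardt). Starting
values come from the terminal log-linear slope (`−1/D0`) and its
extrapolation to dose 0 (`N`); both can be overridden. On noiseless
model-generated data the fit recovers the parameters to at least 4
significant digits with residual ~0; with binomial noise at 50
plants/dose the median relative error of `D0` over repeated experiments
is ~9%. Degenerate inputs (fewer than 3 distinct doses, all-survive,
all-die) are errors, not silent extrapolations.

```{r survival}
dat <- simulateSurvival(D0 = 10, N = 20, doses = seq(0, 60, 10),
                        nPerDose = 50, seed = 4)
fit <- fitMultitarget(dat)
fit
shoulderDose(fit)
```

## Numerical and design choices

* **Coordinates.** All on-disk formats (layout YAML, depth/BED-like
  TSVs) are 0-based half-open; in memory everything is a 1-based closed
  `GRanges`. Conversion happens only at the I/O boundary.
* **Amplicon presence.** A primer pair is called failed ("absent") as
  soon as ≥ 1 bp of its template is deleted — the conservative rule for
  interval evidence.
* **Determinism.** Every simulator takes a `seed` and is bit-reproducible
  given it, without touching the caller's RNG state (`withr::with_seed`).
* **Ties and clamps.** Mutant-fraction estimates are clamped to `[0, 1]`;
  deletion calls at exactly the threshold RRD are *not* depressed
  (strict `<`); p-values are capped at 1.
* **Problem sizes.** The bundled examples and tests run the full
  five-chromosome layout at 100-kb bins (1193 bins), 10,000-replicate
  calibration, and 100-experiment fit-recovery studies; all complete in
  well under a minute each on a laptop core.

## Known limitations

* Breakpoints are bin-aligned: calls are accurate to one bin, and
  intragenic inversions or translocation junctions that do not change
  copy number are invisible to a dosage analysis by construction.
* The qPCR model fixes amplification efficiency at 2.0; efficiency
  calibration is upstream lab QC, not modelled here.
* The generator's noise is pure counting noise; real coverage biases
  (GC, mappability) are not emulated, so thresholds may need widening on
  noisy real libraries.
* The mutant fraction estimator assumes the deletion is heterozygous in
  the mutant lineage; a homozygous event would read as `m/2` doubled.
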