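---
title: "Bin-based crossover calling and recombination landscape comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based crossover calling and recombination landscape comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombscape)
```

## The measurement problem

An F2 population of a cross between two sequenced parents carries, in each
individual, two independent meiotic gametes per chromosome. Every crossover
(CO) leaves a transition in the parent-of-origin mosaic of an F2 chromosome,
so genotyping the mosaic along the genome of many F2 individuals measures the
recombination landscape of the cross. With low-coverage
genotyping-by-sequencing (GBS) there are too few reads to genotype SNPs
individually; instead, each chromosome pair is divided into the same number
of ~1 Mb bins in the two parental assemblies and the parent-specific reads in
each matched bin pair are counted. `recombscape` implements this bin
genotyping, the crossover calling on top of it, population genetic maps in
cM and cM/Mb, and the statistics used to compare maps between populations
(e.g. a gene-silencing treatment against wild type). A synthetic
F2-meiosis/GBS generator with recorded truth makes every stage testable
without sequencing data.

## The pipeline, stage by stage

**Read filtering and binning.** Read records are kept when mapping quality
is strictly above 30, the read maps uniquely, and it matches the reference
perfectly (`filter_reads()`). A read on parent k at position x increments
matched bin `floor(x / bin_width_k)` (`aggregate_counts()`); bin widths
differ slightly between parents because both tilings use the same bin count,
`round(length_p1 / 1e6)` per chromosome (598 to 851 bins for wheat-sized
chromosomes).

**Ratio smoothing and genotype calls.** The per-bin statistic is the
parent-1 read fraction `r = p1 / (p1 + p2)`, on which the homozygosity
thresholds apply directly: after re-calculating each bin as the mean raw
ratio of the surrounding 15 bins (7 each side plus the focal bin), a bin is
called `HOM_P1` when the smoothed ratio is strictly above 0.9, `HOM_P2`
strictly below 0.1, `HET` otherwise. Bins with fewer than 10 reads are
masked *before* smoothing and contribute nothing to any window; a masked bin
whose window still contains data receives a smoothed value from its
neighbours, and only bins with no usable window data stay `MISSING`. Windows
are truncated at chromosome ends rather than padded, because padding would
bias exactly the subtelomeric bins where most crossovers sit. Window width
and centering, the thresholds and the read floor are all configuration
options; defaults follow the protocol above.

**Parental-consistency mask.** The same binning applied to pure parental
libraries flags unreliable bins: any bin where the parent-1 library is not
`HOM_P1` or the parent-2 library is not `HOM_P2` is masked in all progeny.
Parental tracks are called *unsmoothed* (`window_bins = 1`): window
averaging would dilute precisely the isolated aberrant bins this screen
exists to catch — with 15-bin smoothing a single collapsed bin in a parental
library is invisible (a 0.5 ratio averaged with 14 clean bins stays above
0.9) and the screen would mask essentially nothing.

**Crossover events.** One event is emitted per adjacent change between
non-missing bin genotypes; the genotype is carried across `MISSING` runs and
the event's bounding interval spans the gap (events bridging more than
100 Mb of missing data are flagged `low_conf`). Genotypes are dosage-coded
(`HOM_P1` = 2, `HET` = 1, `HOM_P2` = 0) and an event's recombinant-gamete
weight is the absolute dosage difference of its flanks — the only accounting
consistent with the two independent gametes of an F2, under which a
homozygote-to-homozygote change counts two recombinant gametes.

*Junction refinement.* Window smoothing displaces the threshold crossing
systematically toward the homozygous flank: with exact ratios (1.0 vs 0.5)
and a 15-bin window, the called transition sits ~5 bins from the true
junction, because the 0.9 threshold is crossed as soon as 3 of 15 window
bins lie beyond the junction. Each called junction is therefore refined
within its two flanking genotype runs — crossing any masked bins between
them, whose ratios are simply uninformative — to the bin boundary that
minimizes the squared deviation of the *raw* ratios from the expected
values of the two flanking genotypes. On noiseless data this restores the
true junction exactly (the recovery tests assert containment of the true
position in the bounding interval). The event's bounding interval runs
between the
nearest non-missing bins flanking the refined junction (two bins in the
common case), which contains the true crossover up to the bin resolution,
and the event position used in all distance computations is the interval
midpoint (the junction itself).

**Double-crossover filter.** Two genotype changes close together are more
likely genotyping noise or gene conversion than two real crossovers. For
each pair of consecutive events, if their midpoint separation is below the
threshold of the *intervening segment's* region class — 8 Mb outside
pericentric regions, 70 Mb inside — both events are removed and the short
segment reverts to its flanking genotype. The scan removes the shortest
qualifying segment first (ties leftmost) and repeats to a fixed point, which
makes the filter idempotent. In the triple-change edge case where the two
flanks differ, the pair is replaced by one merged event spanning both. The
segment-class rule is used because the segment between the events is what
the filter deems implausible; removal (rather than merging) is used when the
flanks agree because an isolated short segment between identical genotypes
carries no net recombination.

**Population maps and region delimitation.** Each surviving event adds its
gamete weight to the bin containing its midpoint; with n individuals (2n
gametes), `cM = 100 x gamete-weighted COs / (2n)` per bin or interval and
`cM/Mb` divides by physical width, so per-bin rates integrate exactly back
to interval cM. Pericentric regions are delimited on the control map:
starting from the centromere bin, the span extends while the 10 Mb windowed
mean rate stays below 0.1 cM/Mb. The 10 Mb window is needed because most
single ~1 Mb bins carry zero observed crossovers at n = 90, which would make
a raw per-bin threshold degenerate; the window size is a configuration
option and 10 Mb is this package's choice.

**Comparisons.** Recombination rates of an interval are compared between
two populations with a Pearson chi-square (df 1, no continuity correction —
the common default for recombination-fraction contingency tables; Yates
correction is available as an option) on recombinant vs non-recombinant
gametes, where "recombinant gametes" is the gamete-weighted CO count capped
at 2n. Genome-wide pericentric effects use a two-sided paired Wilcoxon
signed-rank across chromosomes (N = 14 in tetraploid wheat), exact for
N <= 25. Marker-based interval distances are direct recombinant-gamete
counts, `100 x sum(|dosage difference|) / (2n)`, with no mapping function:
at the 9-22 cM interval sizes the marker path targets, Haldane or Kosambi
corrections are smaller than the counting noise. No multiple-testing
correction is applied by default, mirroring common practice of reporting
raw p < 0.05 per interval; callers can correct downstream.

## The synthetic generator

`simulate_f2_population()` draws, per gamete, a Poisson number of crossovers
with mean `total cM / 100` and positions from the landscape density — a
no-interference model, chosen because the analysis pipeline never models
interference. F2 dosage tracks are the sum of two independent gametes.
`simulate_bin_counts()` draws per-bin totals as Poisson with region-class
means defaulting to the depth regimes of a real wheat F2 GBS experiment
(arms 62.9 reads/bin, pericentric 38.8, subtelomeric 102.7 left / 73.9
right) and assigns each read to parent 1 with probability
`d/2 (1 - eps) + (1 - d/2) eps`, where `d` is the bin's majority-length true
dosage (bins are the resolution limit, so a crossover inside a bin gives the
bin its majority dosage) and `eps` (default 0.01) a per-read misassignment
rate. The per-read error process is an assumption — the real protocol
reports no per-read rate — and is flagged as such.

Two features of real data the generator adds beyond the per-read model:
*artifact bins* (default 2.5% of bins) in which reads are assigned to either
parent at random, emulating collapsed or near-identical regions of the two
assemblies. They are positional — the same bins misbehave in every library —
which is what makes the parental-consistency screen able to find and remove
them; with these defaults the screen masks a few percent of bins (the
acceptance script reports the realized fraction), in line with what such
screens remove in practice. A per-read error alone cannot produce a masked
fraction of that order: smoothed (or even raw, at 60+ reads) parental
ratios sit many standard errors away from the 0.9/0.1 thresholds.

What the generator does *not* emulate: sequence-level reads (no FASTQ, PCR
duplicates or restriction-site model), crossover interference, segregation
distortion, and assembly-scale structural differences beyond the
proportional bin matching. Passing tests therefore validate the calling and
comparison machinery under the stated statistical model, not the upstream
mapping pipeline.

## Standard study design used by tests and the acceptance script

One wheat-like chromosome of 600 Mb (parent 2: 595 Mb), centromere at
300 Mb, pericentric core [150, 450] Mb: 70 cM split equally between two
60 Mb subtelomeric hotspot blocks plus 2 cM spread over the pericentric
core; n = 90 individuals, default coverage model. The genome-wide design
uses 14 chromosomes spanning 598-851 Mb (centromeres at 0.45 of the
length, pericentric cores [0.2, 0.7] of the length, 30 + 30 cM hotspots).
For the treatment-power experiment the control pericentric density is
0.09 cM/Mb — deliberately just under the 0.1 cM/Mb delimitation threshold,
the regime the pericentric definition describes — and the treatment
multiplies it by 1.5 on five of the fourteen chromosomes. The experiment's
population size (n = 150 per population) comes from a filter-aware power
analysis: under the no-interference simulator the 70 Mb pericentric
double-crossover filter removes an appreciable fraction of true pericentric
crossover pairs (the acceptance script reports the recovered vs detectable
pericentric cM side by side), and n = 150 gives each treated chromosome
enough per-chromosome power to be flagged in a clear majority of replicate
seeds while untreated chromosomes stay near the nominal false-positive
rate — the power experiment measures both rates.

Three design points deserve a note:

* **Recovery is scored against the detectable truth.** The double-crossover
  filter removes, by construction, true crossover pairs closer than its
  thresholds, and dosage-cancelling pairs (the two gametes crossing in
  opposite directions within a bin) are invisible to any dosage-based
  caller. Truth for parameter-recovery comparisons is therefore the
  dosage-level breakpoint set passed through the same distance filter
  (`true_dosage_events()` + `filter_double_crossovers()`). Under the
  no-interference simulator the filter's cost is visible (a few cM in a
  35 cM hotspot block); in real wheat, interference makes sub-8 Mb double
  COs rare, so the filter costs little there.
* **Chi-square calibration is checked at the pericentric scale.** The
  gamete-weighted CO count of an interval is Poisson-like, while the 2x2
  chi-square assumes binomial counts; for large intervals (tens of cM) the
  multi-CO overdispersion inflates the type-I error well above the nominal
  level — the effect grows with the interval's cM, since the variance
  excess is the chance of multiple crossovers per gamete. At a small
  (few-cM) pericentric interval — the scale of the comparisons this
  pipeline is built for — multi-CO gametes are negligible and the test is
  calibrated, which the null-calibration test verifies empirically. The
  calibration check accordingly uses the pericentric interval;
  whole-chromosome chi-square p-values should be read qualitatively.
* **Null calibration runs on truth-level maps.** The 200-replicate null
  experiment builds maps from the simulator's true crossovers rather than
  re-running read-level GBS 400 times: the quantity under test is the
  calibration of the comparison statistics, and the read-level machinery is
  exercised (and scored) by the recovery and power experiments.

Problem sizes (n = 90 individuals; 200 null replicates; 50 seeds for the
power experiment) are the package's standard synthetic study conditions and
keep the full suite comfortably within a desktop run.

## Numerical and degenerate-input conventions

Threshold comparisons are strict (`> 0.9`, `< 0.1`, `< 10` reads, `< 8` /
`< 70` Mb), mirroring the protocol's wording. Positions on a bin boundary
belong to the right-hand bin (0-based, half-open intervals everywhere; BED
on output). Ties in junction refinement go to the cut closest to the
unrefined junction, then leftmost; ties in per-bin majority dosage go to
the lower dosage. All-zero 2x2 margins return p = 1 with a warning;
all-zero Wilcoxon difference vectors return p = 1; an all-missing genotype
track yields no events with a warning. Even smoothing windows are rejected
(a centered window must be odd). Seeds fan out to stages via a deterministic
substream scheme, so identical configurations give byte-identical reports.

## Known limitations

* Bin-scale resolution: events are localized to ~1 Mb at best, and double
  crossovers within a bin (or below the filter distances) are not
  observable; genuine gene conversions are indistinguishable from noise and
  are removed by the same filter.
* The chi-square on gamete-weighted counts is anti-conservative for
  large-cM intervals (see above).
* The generator's error model is parametric and deliberately simple; the
  2-3% masked-bin figure is reproduced via the artifact-bin mechanism, not
  derived from sequence data.
* Phasing of which gamete carries a crossover, interference modelling, and
  LOD-based map construction are out of scope.
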