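---
title: "Methods: coverage windowing, enrichment screening and permutation FDR in netscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage windowing, enrichment screening and permutation FDR in netscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the models
and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis problem

Three whole-genome samples — undifferentiated HL-60 cells,
DMSO-differentiated dHL60 cells, and the extracellular trap (ecTrap)
DNA those differentiated cells release — are compared for regional
differences in sequencing coverage. Released trap DNA is not expected
to be a uniform genome sample: telomeric repeats, mitochondrial DNA and
particular gene loci may be over- or under-represented. A parallel LFQ
proteomics comparison (Benzonase-treated versus untreated trap
preparations, three replicates each) asks which proteins are
differentially recovered.

## Coverage, windows, and the two normalizations

Per-base depth is the number of alignments whose half-open interval
covers a position (pileup is delegated to `IRanges::coverage`; a
configurable MAPQ floor defaults to 0, keep-all). Chromosomes are tiled
by non-overlapping windows of width $w \in \{20, 100, 500, 5000\}$ nt;
a window's value is the **sum** of per-base depths inside it, so window
sums refine exactly (250 consecutive 20-nt windows sum to one 5,000-nt
window) and a read that spans a boundary contributes each base to its
own window. The terminal window may be short; it is kept and flagged
(dropping it is an option).

"Sliding" windows are implemented as tiling (step = width). Only under
tiling do the per-window values of one sample on one chromosome sum to
that chromosome's total coverage, which is what makes the normalization
fractions meaningful; a true sliding step remains available for
exploration but is not used by the screen.

Two normalizations are exposed, both plain coverage fractions:

* **Per chromosome** (screen substrate):
  $v_{w,s,c} = (x_{w,s,c} + \pi) / \sum_{w' \in c} (x_{w',s,c} + \pi)$
  with pseudocount $\pi = 0$ by default — the fraction exactly as
  defined, conserving to 1 per sample per covered chromosome (checked to
  $10^{-9}$). Zero-coverage chromosomes yield absent values, which the
  screen skips and counts.
* **Genome-wide** (mitochondrial enrichment): window coverage divided by
  the sample's total coverage over *all* chromosomes, MT included.
  Whether the MT denominator should include MT itself is not decidable
  from the analysis definition alone; it is included here, which makes
  the per-sample MT summary a true fraction of that sample's sequencing
  output and keeps it invariant under uniform scaling of the sample.

A third rescaling — a gene's coverage divided by the mean of the three
samples' coverage of that gene — exists for per-gene visualization
only (`gene_sample_vs_mean()`, used by `roi_profile()` and
`plot_gene_track()`); it plays no role in the screen.

## The 1.5-fold screen

For each window and focal sample, ratios are formed on per-chromosome
normalized values against each other sample and against the mean of the
other two, with a ratio pseudocount added to numerator and denominator.
A window is **enriched** for the focal sample when the chosen criterion
reaches the cutoff (default 1.5), **depleted** when it falls below the
reciprocal $1/1.5$ — the reciprocal threshold makes enrichment and
depletion symmetric under sample swap. The default criterion is
`either`: the union of "$\geq$ cutoff against both others
simultaneously" and "$\geq$ cutoff against their average", with the
satisfied criterion recorded per call so a simultaneous-only analysis is
recoverable afterwards.

Two numerical choices deserve note:

* **Ratio pseudocount.** The default is half the smallest positive
  normalized value the table can *represent* — one unit of raw coverage
  over the largest per-sample-per-chromosome total. On deeply covered
  toy chromosomes no window is near zero, so the smallest *observed*
  value is large (at $w = 5000$ on a 100 kb chromosome, about 0.03) and
  would shift every ratio materially; the smallest representable value
  is tiny in exactly the way a genome-scale table's smallest observed
  value would be, guards against infinite folds on empty windows, and
  preserves ordering. The parameter is explicit and logged.
* **Mirror calls.** At a window where one sample is strongly depleted,
  the other two samples exceed the three-sample average; under the
  `either` criterion they can be called enriched there. These mirrors
  are a property of the comparison design, not a bug, and they are
  direction-consistent: the planted sample's call always carries the
  planted direction.

Consecutive same-direction calls for one focal sample merge into
**regions** (`merge_regions()`, gap 0); the merging rule behind any
particular published region count is not reconstructible, so merging
exists here as declared structure. Regions intersect gene and exon
annotation by half-open interval overlap ($\geq$ 1 nt), and hit genes
compare against an external expression gene list by case-folded set
algebra.

## Telomere and mitochondrial quantification

Telomere content is the count of the 12-mer `TTAGGGTTAGGG` in mapped
read *sequences*, grouped by mapped chromosome — counting in the
reference would be sample-invariant and could not distinguish samples.
The 12-mer (rather than the hexamer unit) is the operational motif; the
hexamer remains available via the `motif` argument. Both strands are
searched by default (reads come from either strand of an array);
non-overlapping counting advances past each match, overlapping counting
scores every start. Raw counts and counts per million mapped reads are
both reported; per-million values, one per chromosome, are the
replicates for a one-way ANOVA across samples.

Mitochondrial enrichment tiles MT into 500-nt windows under the
genome-wide fraction. The per-sample summary is the sum of that
sample's normalized MT windows — the fraction of its sequencing output
drawn from MT — and an ANOVA across samples runs on the window values.
A planted 10× MT multiplier is recovered as a summary ratio near 10
(slightly below, since the multiplier also inflates the denominator).

## Proteomics: permutation FDR

Intensities are $\log_2$-transformed; absent values are an explicit
marker (NA), never zero, and are excluded rather than imputed
(imputation is a documented extension point). Proteins need
`min_valid = 2` present values per group. Per protein, a Welch $t$
(unequal variances — replicate variances are not assumed equal) compares
the two groups. The null distribution comes from group-label
permutations: all distinct splits are enumerated when few enough,
counting swap-equivalent splits once and **excluding the observed
labelling** — for 3 vs 3 this leaves 9 effective null splits. Including
the observed split (and its mirror) would bound every q-value below by
$2/20 = 0.1$, making an FDR-0.05 decision unattainable at this design
size. For each observed $|t|$,

$$\mathrm{FDR}(t) = \frac{\operatorname{mean}_{\text{perm}} \#\{p : |t_{\text{perm},p}| \ge t\}}{\#\{p : |t_{\text{obs},p}| \ge t\}},$$

clipped to $[0,1]$ and enforced monotone non-increasing in $|t|$ by a
running minimum from the largest statistic (the mean, not the median,
summarizes the permutation counts; both the summary and the absence of
an $s_0$ stabilization term are explicit parameters). Significance
requires $q \le 0.05$ **and** a signed linear fold change of at least 2
(ratio $\ge 2$ in either direction, the common LFQ display convention; a
$\log_2$ reading of the cutoff is selectable).

Two small-$n$ behaviours are worth knowing:

* Under a global null, discoveries are doubly gated (q and fold change);
  with replicate CV 0.15 a 2-fold group difference is a $\sim 5$-sigma
  event, so the realized false-discovery proportion is far below the
  nominal level (measured in the acceptance suite over 50 null
  simulations).
* When a large fraction of proteins is truly differential *and* carries
  missing values, a permuted split can reconstitute the clean
  separation after NA removal (a pure 2 vs 2), fattening the null tail;
  at the study-like differential fraction of ~5% this is negligible.
  Power checks therefore plant 25 differential proteins among 500.

Sensitivity against the planted truth is reported among planted proteins
that were actually testable (passed the presence filter): low-abundance
censoring can erase a planted protein's down-shifted group entirely,
which measures the generator's missingness mechanism, not the test. The
pipeline's scoring block reports both this figure and the all-planted
one.

Significant proteins are z-scored per row across present values
(sample sd; zero-spread rows are flagged and placed last) and clustered
with Euclidean distance and average linkage; absent values enter the
distance as 0 — the row mean after z-scoring — and ties break by input
order, so leaf order is deterministic.

## The synthetic-data generator

The generator emulates the statistical structure of the study's inputs
at desk scale, not their content:

* **Genome**: three autosome-like chromosomes (default 100 kb) capped at
  both ends by perfect tandem `TTAGGG` arrays (600 nt; the 3' array is
  on the minus strand, recorded in the truth record), plus a 2 kb
  circular MT chromosome. Perfect arrays give motif counting an exact
  analytic expectation. Twelve genes with 1–3 exons are placed per
  autosome, outside the arrays.
* **Reads**: fixed-length (100 nt) reads emitted *pre-aligned* — the
  true placement is the alignment — since mapping is outside the
  analysis and true placements make coverage oracles exact. Start
  positions are Poisson-sampled uniformly, with the sampling intensity
  multiplied inside planted intervals and on MT; telomere-excess reads
  are drawn wholly inside arrays at a per-million rate. Qualities are
  high with a configurable fraction of 3'-decayed reads (below Q25), so
  the trimming stage has something to do. Realized mean depth is within
  5% of target for chromosomes ≥ 50 kb and calibrated to ±2% in the
  mean over 20 simulations.
* **Planted signal defaults**: each sample carries one 2.0× interval of
  two 5,000-nt windows on its own chromosome and one 0.5× interval of
  one window on another; planted intervals are kept ≤ 10% of a
  chromosome so the per-chromosome normalization denominator is only
  mildly perturbed — on a genome-scale run differential regions are a
  small fraction of any chromosome, and a 25%-of-chromosome plant would
  cap the achievable normalized fold at $2/1.25 = 1.6$. MT multipliers
  default to (1, 1, 10) and telomere rates to (1,000, 5,000, 15,000)
  per million for the HL60/dHL60/ecTrap roles, emulating the trap
  sample's mitochondrial and telomeric excess.
* **LFQ**: 2,000 proteins, log-normal baseline spanning > 5 orders of
  magnitude, 126 differential at 4-fold (split up/down), multiplicative
  replicate noise at CV 0.15, and missingness that decays logistically
  above a low-abundance threshold (~10% overall). Group sizes 3 + 3.

What the generator does **not** emulate — sequencing errors, indels and
soft-clipping, paired ends, PCR duplicates, GC bias, mappability,
NUMTs, origin-wrapping MT reads, peptide-level proteomics effects —
bounds what green tests mean: they validate the window math, the screen,
the counters and the FDR machinery on data whose generative process is
known exactly, not the upstream read processing of real libraries.

## Reading trimming

The two-step 3' rule: remove a fixed 15 nt (primer removal), then
remove further 3' bases while the terminal quality is below Q25. The
quality clause is implemented as 3' trimming rather than whole-read
discard — it follows the fixed trim in the same processing step and
retains reads — with whole-read filtering available behind a flag.
The order (fixed cut first) is fixed but configurable. Reads shorter
than 20 nt after trimming are discarded and counted; the default
prevents zero-length reads from entering coverage. In the pipeline the
trimming stage runs on the simulated FASTQ and reports its counts;
coverage itself uses the recorded true placements.

## Statistics

`anova_oneway()`, `mann_whitney()` and `spearman()` are implemented in
the package so its results are fully specified here, with exact
small-sample paths (toy fixtures are small): Mann-Whitney enumerates
all rank assignments for $\min(n,m) \le 8$ without ties (normal
approximation with tie and continuity correction otherwise), Spearman
enumerates all orderings for $n \le 7$ without ties ($t$ approximation
otherwise), and the degenerate all-identical ANOVA input reports
$F = 0, p = 1$ with a flag. The test suite cross-checks each against
the standard library implementations on random cases.

## Problem sizes and determinism

Simulation-based checks use 3 × 100 kb (or smaller) genomes at depth
10, 20 seeds for the screen-recovery and depth-calibration properties,
50 repetitions for null FDR calibration, and 5 for the power check —
sizes chosen so the whole suite and the acceptance script each run in
minutes on one core while leaving the measured margins wide. Every
stochastic step takes a seed; the pipeline derives per-stage seeds from
one global seed through a fixed recorded map (`derive_seed()`), so
stages are independently re-runnable and two runs with one config and
seed produce byte-identical summaries.

## Known limitations

* The screen attaches no per-window significance — it is a fold-change
  filter, as defined; region counts therefore depend directly on the
  cutoff, the pseudocount and the merging rule, all of which are logged.
* Permutation granularity at 3 vs 3 is coarse (9 effective splits);
  q-values move in steps and the FDR is conservative near the top of
  the ranking. More replicates, not more permutations, is the remedy.
* Gene-symbol matching is case-insensitive exact match; no alias
  resolution.
* BAM/CRAM input is out of scope (SAM text and a 6-column TSV dialect
  are supported); the SAM writer emits standard 11-column records, so
  external tools can consume its output.
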