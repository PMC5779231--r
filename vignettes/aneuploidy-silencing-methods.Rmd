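---
title: "Methods: linking aneuploid karyotypes to chromatin-silencing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking aneuploid karyotypes to chromatin-silencing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneusilence)
```

## The problem this package addresses

Budding yeast tolerates a remarkable range of aneuploid karyotypes, and
chromosome stoichiometry alone — with no change in DNA sequence — can
perturb heritable chromatin states. The experimental design this package
supports starts from a triploid strain carrying a fluorescent reporter
inserted into the silenced *HML* mating-type locus: triploid meiosis
scrambles chromosome numbers, essentially every viable spore is aneuploid,
and colonies that light up have lost silencing. Downstream, specific
karyotypes (notably gain of chromosome X) are characterized by single-cell
fluorescence, nuclear-position assays of the silenced locus, and
copy-number-aware RNA-seq/ChIP-seq comparisons.

`aneusilence` implements the full quantitative path of that analysis as
testable functions, plus a synthetic-data module that generates every input
the pipeline consumes, so each stage can be validated by parameter recovery
without any deposited data.

## Karyotypes and enrichment statistics

A karyotype is the vector of copy numbers of the sixteen chromosomes. Its
**basal ploidy** is the modal copy number — the copy number possessed by
most chromosomes — and a chromosome is *aneuploid* when it deviates from
it. An exact tie (eight chromosomes at one copy number, eight at another)
leaves the basal ploidy undefined; `basal_ploidy()` raises an error
carrying both candidates rather than guessing. This is not an exotic
corner: spores of a triploid meiosis with balanced 1-or-2 segregation tie
with probability `dbinom(8, 16, 0.5)` ≈ 0.196, which is why the screen's
aneuploidy *rate* is computed from the raw copy vectors and only stable,
basal-ploidy-defined strains enter the per-chromosome statistics.

**Enrichment.** For a case set of desilenced strains against a reference
set of stable aneuploids, each chromosome is tested with an exact binomial
upper tail: with $x$ of $n$ case strains aneuploid for that chromosome and
reference frequency $f$,

$$p = \sum_{k \ge x} \binom{n}{k} f^k (1-f)^{n-k}.$$

Choices made where the design was open:

* counting is *any deviation* from basal ploidy by default, with a
  gains-only flag, because the phenotype is dominated by gains;
* a chromosome never aneuploid in the reference gets the half-count
  pseudofrequency $0.5/n_{\mathrm{ref}}$ so the upper tail is computable;
* the upper (overrepresentation) tail is the default, a two-sided exact
  test is available;
* raw p-values carry the significance flags (matching how such screens are
  reported) and Benjamini–Hochberg adjusted values are always reported
  alongside.

**qPCR copy calling** inverts the ΔΔCt model: relative quantity
$E^{-\Delta\Delta C_t}$ (efficiency $E = 2$ per cycle by default), averaged
over replicates, scaled by the basal ploidy and rounded to the nearest
integer with ties away from zero. Calls farther than 0.35 from an integer
are flagged ambiguous — at realistic Ct noise (sd ≤ 0.1 cycles) calls are
exact, and the flag marks strains worth re-running rather than silently
rounding a 1.5-copy signal.

## Single-cell fluorescence

Inputs are per-cell summaries (mean, sd, pixel count) of
background-subtracted sum projections; raw image processing is upstream of
this package. A helper reduces per-pixel lists with the population
(divide-by-$n$) sd convention, which also fixes the convention for the
**coefficient of variation** (sd/mean) used to quantify how sharply Sir2 is
concentrated in nuclear foci: diffuse signal → low CV.

**Desilenced-cell calling** uses Tukey's outlier fence on the wild-type
distribution: threshold $Q_3 + 1.5\,\mathrm{IQR}$ with quartiles by linear
interpolation between order statistics (the common type-7 rule — the fence
variant had to be fixed explicitly, and these are the standard choices). A
cell is desilenced iff strictly above the fence; the desilenced fraction
carries a Clopper–Pearson 95% interval. One property worth recording: this
fence is *not* monotone under adding high values (growing $n$ shifts the
two quartile indices unequally, so the fence can drop slightly); it is
affinely equivariant, and insensitive to outlier magnitude, and those are
the properties the tests assert.

**Distribution comparisons** use the Mann–Whitney U test: exhaustive
enumeration of all labelings when both groups have ≤ 8 observations (the
two-sided p is the permutation probability of a U at least as far from
$n_1 n_2 / 2$ as observed, which handles ties uniformly), and the
tie-corrected normal approximation, without continuity correction, for
larger groups. At the imaging depth used throughout (175 cells per strain)
the normal path holds the nominal 5% size within sampling error.

**Lineage traces** are scanned with a two-threshold hysteresis state
machine (default on-threshold: wild-type Tukey fence; off-threshold:
wild-type median): an off→on event fires when intensity rises to the on
threshold, on→off when it falls to the off threshold, and excursions
within the band produce no chatter. **DNA-content G2 gating** places the
boundary at the midpoint of the 1N and 2N modes — the instrument gating of
the original assay is not described, and the midpoint is the neutral
choice for well-separated modes.

## Nuclear three-zone assay

The circular nuclear cross-section is split into three concentric zones of
equal area — boundaries at relative radii $\sqrt{1/3}$ and $\sqrt{2/3}$ —
so a uniformly positioned locus falls in each zone with probability 1/3.
Zoning is planar by default (the classical form of the assay); a 3D
equal-volume variant (cube-root boundaries) is available behind a flag.
Boundary points are assigned inward (ties to the more central zone), an
arbitrary but fixed convention. Loci up to 5% of the radius outside the
fitted circle are clamped to the envelope (segmentation jitter at the
nuclear-envelope marker); anything farther is rejected. The zone
distribution is tested against the uniform null with Pearson's χ² (df = 2),
and a multinomial Monte-Carlo p-value is reported alongside for small
totals.

## Copy-number-aware genomics

The central confound of aneuploid expression data is dosage: a gene on a
gained chromosome doubles its reads without any regulation.
`normalize_counts()` divides each gene's count by the chromosome's copy
ratio (copies / basal ploidy) in that sample, so pure dosage effects
normalize to fold change 1 and only trans-acting changes remain.

* **Expression gate**: RPKM $= 10^9 \cdot c / (L \cdot N)$, expressed iff
  RPKM > 1 (strict); differential testing is restricted to genes expressed
  in both strains.
* **Fold-change categories**: fold change is the ratio of mean normalized
  counts with pseudocount 0.5; significance comes from a moderated t-test
  on $\log_2(\text{count} + 0.5)$ with a mean–variance trend (limma),
  BH-adjusted; up/down requires both the 1.5-fold and adjusted p < 0.01
  gates. A naive per-gene pooled-variance t at 3 replicates has 4 degrees
  of freedom and essentially no power at these gates; borrowing variance
  information across genes is the standard remedy for replicate-based
  tests on log-counts, and is the package's declared substitute for a full
  negative-binomial fit, which is out of scope.
* **Peak-to-gene assignment**: each ChIP peak goes to the gene with the
  nearest TSS (distance 0 if the TSS lies inside the peak) and is kept iff
  that distance is ≤ 600 bp; multi-peak genes keep the maximum score (sum
  available). Peak scores are −log10 q-values, divided by the chromosome
  copy ratio before **Z-scoring** (population sd within each strain), and
  ΔZ is computed over genes scored in both strains.
* **Subtelomeric genes**: strictly closer than 25 kb (configurable) to
  either chromosome end — the literature has no single numeric definition,
  so the default is declared, not inferred. Category enrichment (e.g.
  subtelomeric within upregulated-and-ΔZ-positive) uses the two-sided
  Fisher exact test.
* **Variant filtering** removes, from each aneuploid strain, variants
  present in all sequenced strains or in any parental strain (background
  mutations), plus anything flagged `repetitive`, `homopolymer` or
  `low_qual`, with per-reason removal counts (precedence shared > parental
  > flag).

## The synthetic-data module

Every generator draws from a named substream of one master seed, so
identical configurations give byte-identical outputs and adding a
generator never perturbs another, and each generator emits a truth record
enabling end-to-end parameter recovery. Defaults are the study conditions
the analysis was designed around:

| parameter | default | rationale |
|---|---|---|
| `n_spores` | 3418 | size of the silencing screen |
| `p_two_copies` | 0.5 | balanced 1-or-2 trivalent segregation |
| `n_cells` | 175 | imaged cells per strain |
| `desilenced_fraction` | 0.35 | desilenced share of disome X cells |
| `silenced_mean/sd` | 100 / 12 a.u. | dim, tight background-level reporter |
| `desilenced_mean/sd` | 500 / 150 a.u. | clearly separated bimodal states |
| `zone_probs` | (1/3, 1/3, 1/3) | uniform positioning null |
| `nb_mean`, `nb_dispersion` | 100, 0.05 | typical coverage, replicate-level dispersion |
| `trans_fraction` | 0.075 | the 5–10% of genes with non-dosage changes |
| `subtel_derepression_fc` | 3 | strong subtelomeric derepression |
| `g2_fraction_true` | 0.14 | disome X G2 fraction after pheromone arrest |
| `ct_noise_sd` | 0.05 cycles | replicate-level qPCR noise |
| `switch_on/off_rate` | 0.1 / 0.1 | placeholders: no measured rates exist |

Intensities are log-normal (non-negative, right-skewed, as fluorescence
is); the silenced sd is deliberately tight so the two states are cleanly
bimodal — with a heavier silenced tail the Tukey-fence classifier picks up
wild-type tail cells and its fraction estimate drifts upward by more than
a percentage point, which is a property of the classifier, not of the
generator. Trans-effect genes are drawn off the gained chromosome with
log-uniform magnitudes in [1.5, 4] and symmetric direction. Triploid
meiosis is modeled as independent per-chromosome 1-or-2 segregation; real
trivalent segregation is more structured, but no distribution for it is
available, so this is a declared simplification.

What the generators do **not** emulate: raw reads, images or FACS event
files; spatial correlation of silencing within colonies; replicate batch
effects; karyotype instability over passaging; mapping biases. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated statistical model, not robustness to every artifact of
real data.

## Numerical choices and degenerate inputs

* Copy rounding: nearest integer, ties away from zero; ambiguity flag at
  0.35.
* Pseudofrequency 0.5/n for never-aneuploid reference chromosomes;
  pseudocount 0.5 for fold changes and log-counts.
* Population (divide-by-n) sd for pixel summaries and Z-scores — declared,
  since either convention is defensible.
* Boundary conventions: desilenced strictly above the fence; expressed
  strictly above RPKM 1; subtelomeric strictly below the threshold; zone
  boundaries inward; peak kept at exactly 600 bp.
* Degenerate cases are explicit: identical pooled samples give p = 1
  (flagged) in the Mann–Whitney test; zero-variance score sets and
  constant vectors are errors; empty Fisher margins return p = 1 with a
  degeneracy flag.
* Exact-test calibration: a discrete exact binomial test cannot reject at
  exactly 5% under the null — its attainable level is below nominal — so
  calibration compares the empirical rejection rate against the exactly
  computed attainable level and bounds it by the nominal level, rather
  than demanding 5% on the nose.

## Problem sizes used by the test suite

The shipped tests run the zoning null at 100,000 loci, the meiosis
closed-form check at 4,000–10,000 spores, fraction-recovery at 1,200
replicates of 175 cells, enrichment calibration at 1,000 simulated
screens of 24 case strains against 40 reference strains, and
dosage-normalization checks on ~2,000-gene count tables with 3 replicates
per condition — sizes chosen so the full suite completes in well under a
minute while keeping Monte-Carlo error far below every asserted tolerance.

## Known limitations

* Strain-level published quantities (specific intensity distributions,
  ChIP enrichments, the exact subtelomeric Fisher p) require the deposited
  sequencing and imaging data and are out of desk-scale reach; the package
  validates the *methods* by parameter recovery and oracle equivalence
  instead.
* Nuclear geometry is a fitted circle; ellipses and full 3D stacks are not
  supported.
* The moderated-t count test is a stand-in: it shares limma's assumptions
  (approximately normal log-counts, common mean–variance trend) and is not
  a negative-binomial likelihood fit.
* The subtelomere threshold and the lineage switching rates are declared
  assumptions, exposed as parameters.
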