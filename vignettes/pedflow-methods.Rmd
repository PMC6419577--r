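---
title: "Tracing genome flow through a breeding pedigree: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing genome flow through a breeding pedigree: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pedflow` implements a pipeline for dissecting the genomic consequences of
a documented breeding program: diversity and selective-sweep scans
contrasting a wild-type panel with the pedigree accessions, sliding-window
identity-by-descent (IBD) detection and origin tracing through the
pedigree graph, and candidate-SNP association for the improved trait. This
vignette states the models, the tunable parameters and their defaults, the
numerical conventions, and the limits of what the simulation-based tests
demonstrate.

## The IBD identity-ratio model

Cotton cultivars are inbred lines: each accession is (nearly) homozygous,
so a chromosome segment transmitted intact from parent to released
derivative is carried identically in both. The detection rule exploits
this directly. Windows of `size = 200` consecutive SNPs advancing by
`step = 20` SNPs are compared between descendant and candidate parent;
within a window the *identity ratio* is the fraction of sites, non-missing
in both, with the same unordered genotype code. A window qualifies as an
inheritable IBD fragment when the ratio is at least `ratio_min = 0.99` and
at least `min_informative = size/2` sites were compared. Qualifying
windows whose site spans overlap or abut merge into segments bounded by
their first and last SNP positions — segment lengths therefore inherit the
local SNP density at the edges, which the output records via `n_snps`.

Choices worth knowing about:

* **Genotype vs allele matching.** Codes are compared as unordered
  genotypes (0/1/2). An allele-level variant would credit half-matches at
  heterozygous sites; for inbred material the two coincide, and genotype
  matching is the stricter, simpler default.
* **Uninformative windows.** Where two candidate source parents are
  themselves ≥ 99 % identical, a match cannot be attributed; such windows
  are masked before detection. The cutoff deliberately mirrors the IBD
  threshold: "uninformative" means "sources mutually IBD-indistinguishable".
* **`min_informative`.** Guards truncated and missing-heavy windows; half
  the window size is conservative at the default 2 % missingness.
* **`min_run`.** A fragment may be required to contain several consecutive
  qualifying windows; the default of 1 reflects that a single 200-SNP
  window already spans a genetically meaningful interval at realistic SNP
  densities.
* **Unique vs shared attribution.** After per-parent detection, segments
  are overlaid: base-pair regions qualifying for exactly one parent are
  *unique* and enter per-ancestor contribution percentages; multi-source
  regions are reported as *shared* and kept out of those percentages, so
  contributions + shared + unknown always total 100 %.
* **Chained tracing.** "Stably inherited" analyses require a region to be
  transmitted at every parent–child link of some pedigree path *and* to be
  directly IBD between target and ancestor. The second condition matters at
  window resolution: qualifying windows over-extend past true segment
  boundaries by up to one window span per link, so a purely link-wise
  definition could exceed the direct set near boundaries. With it, chained
  bp is a subset of direct bp by construction.

## Diversity, sweeps, and their estimators

Nucleotide diversity uses the unbiased per-site form
π_s = c_ref·c_alt / C(n, 2) over the n non-missing allele calls, summed per
window and divided by the true window width (100 kb windows sliding 20 kb,
anchored at position 1; terminal windows are normalised by their actual
covered bp). F_ST is the Weir–Cockerham ratio-of-sums Σa / Σ(a+b+c) from
the standard two-population variance components — the estimator the widely
used VCF tooling defaults to. LD is r² from two-locus haplotype
frequencies when phased (equal to the squared Pearson correlation of
allele indicators; the unphased fallback uses genotype correlation).
Distances for tree building are allele-sharing distances
d = 1 − mean shared-allele fraction; the neighbour-joining agglomeration is
delegated to `ape::nj`, with negative branch lengths clamped to zero and
the deficit moved to the sibling branch.

The sweep scan flags windows at or above the empirical 95th percentile of
log₁₀(π_wild/π_ped), one-sided in the direction of diversity loss in the
pedigree. Windows where the pedigree is invariant but the wild panel is
not have ratio +∞ and are always flagged; windows invariant in both groups
carry no signal and are excluded from the quantile. Ties at the threshold
are flagged inclusively.

XP-EHH confirmation: per core site, EHH at marker x is the fraction of
haplotype pairs identical at every marker between core and x (core
excluded), evaluated outward until EHH < 0.05, the chromosome ends, or the
integration radius `max_extend = 200 kb` is reached; iHH is the trapezoidal
integral over physical distance, both directions summed, and the raw score
ln(iHH_ped/iHH_wild) is standardised genome-wide. Window scores take the
maximum standardised site score in each 100 kb window (a mean aggregation
is available), and the top 5 % of windows are flagged. A sweep is
*confirmed* where both flag sets agree; adjacent confirmed windows merge
into sweep segments. The integration radius is a numerical choice, not a
biological one: pedigree panels carry very long shared haplotypes, and on
the 20 Mb test condition sweep recovery does not improve beyond a 200 kb
radius while cost grows linearly with it. The hot loop (group refinement with
haplotype bitsets, singletons dropped) is compiled C++; tests verify it
against brute-force pair enumeration in R.

## The mixed-model association

Candidate SNPs are tested under y = μ + PCs·β + marker·α + u + e with
cov(u) = σ²_g K, K the VanRaden genomic relationship matrix on
mean-imputed, filtered genotypes. The variance ratio δ = σ²_e/σ²_g is
profiled once under the null model via the eigendecomposition of K and
reused for every marker (the P3D shortcut; exact per-marker
re-estimation is available behind `exact = TRUE`). Each marker is then a
generalized-least-squares fixed effect with a Wald t test on n − p
residual degrees of freedom — a convention chosen so that with K = I and
no covariates the scan collapses *exactly* to ordinary least squares,
which the tests assert to 10⁻⁶. Three PCs are included by default
(configurable); no multiple-testing correction is applied because the
design is a small candidate set, not a genome-wide scan. Genotype-group
trait comparisons contrast the two homozygous classes only, with an F test
at 0.05 choosing pooled vs Welch t tests.

## What the simulator emulates — and what it does not

The generator is first-class, tested code; its defaults are the package's
standing study conditions:

* **Genome**: two chromosomes (one per sub-genome, `A01`/`D01`) of 10 Mb —
  a deliberate ~100× scale-down of the allotetraploid cotton genome. The
  recombination rate is raised to 10 cM/Mb so the *per-chromosome*
  crossover count per meiosis (~1) stays realistic on the shortened
  chromosomes.
* **Sites**: 61 000 SNPs per chromosome with alternate-allele frequencies
  from a neutral 1/i spectrum over H = 40 haplotype classes. The closed
  form E[π_s] ≈ (1 − 1/K_block)/a_{H−1} (a the harmonic number, K_block
  the per-block prototype pool) gives a 100 kb-window π of ≈ 1.3 × 10⁻³
  per bp for the outbred wild panel — the density was set from this
  calculation, and an acceptance test checks the realised value within
  ±20 %.
* **Haplotype structure**: founder haplotypes copy one of 16 prototype
  haplotypes per 50-SNP block, giving the local LD that EHH statistics
  need; no coalescent machinery is used.
* **Inbreeding**: by default every accession is a fully homozygous line; a
  cross is collapsed single-seed descent (one gamete per parent, one
  derivation recombination, doubled). This is the regime in which the
  ≥ 99 % genotype-identity rule is meaningful — an outbred F1 is
  heterozygous wherever its parents differ and matches neither. The
  literal gamete-union model remains available as `mode = "outbred"` for
  studying transmission itself.
* **Imperfection**: 2 % missing calls and 0.1 % wrong codes, i.i.d. per
  site × sample, typical of high-depth short-read genotyping; the error
  rate is what makes the 99 % (rather than 100 %) threshold earn its keep.
* **Truth**: every meiosis records its crossovers and every child the
  intervals transmitted per parent, which tile each chromosome exactly;
  ancestor-level truth is obtained by composing transmissions along the
  pedigree.

Not emulated: mutation within the pedigree, structural variation, linked
selection outside planted sweeps, genotype-calling artefacts that correlate
along the genome, and — importantly — the *ascertainment depth* of real
panels. Real pedigree accessions share far more of their genomes than five
independent founders can produce, which is why the simulated pedigree π
(≈ 0.9 × 10⁻³) does not drop all the way to the ≈ 3.6-fold reduction seen
in real domesticated cotton: pushing founder relatedness that far would
make the sources mutually IBD-indistinguishable and origin tracing
vacuous. Passing tests therefore demonstrate that the *procedures* recover
planted truth under realistic noise, not that the simulator reproduces
every marginal statistic of the real data.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere internally; BED export
  converts to 0-based half-open at the boundary only. Chromosome names
  accept both `A1` and `A01` and are zero-padded internally.
* A window with no jointly observed sites has an undefined identity ratio
  and never qualifies; an F_ST window with no usable site (or an entirely
  missing group) is `NA`, not 0.
* Empirical quantiles use R's default type-7 definition; ties at a
  flagging threshold are flagged inclusively.
* Genotype PCA fixes each component's sign by making its
  largest-magnitude loading positive; eigenvalues of K are clipped at 0
  before rotation.
* `validate_pedigree` is Kahn's algorithm; a cycle is reported with one of
  its edges. Composite crosses are modelled by inserting an unnamed
  `hybrid` intermediate so every node keeps ≤ 2 recorded parents.
* The 26-accession pedigree fixture records the sequenced accessions; the
  variance between published counts of 26 vs 27 pedigree members is noted
  in the fixture's documentation and not modelled.

## Problem sizes used by the tests

Unit tests run on kilobase-scale toys. The end-to-end accuracy suite uses
the sizes the checks are specified at: 20 Mb × 112 000 SNPs for the sweep
recovery (10 seeds), 10 Mb × 10 000 SNPs for trio IBD and 3-generation
contribution tracing (10 seeds), n = 258 accessions × 2 000 markers for
association calibration and power, and 100 kb windows throughout. These
sizes were chosen so that each property is measured at a scale where its
sampling noise is well below the asserted margin.

## Known limitations

* Segment boundaries are SNP positions, so detected segment lengths are
  conservative in sparse regions.
* The identity-ratio method cannot attribute regions where candidate
  sources are near-identical (masked as uninformative) or where the true
  source was never genotyped ("unknown" in contribution reports) — both
  are properties of the method, not bugs of the implementation.
* XP-EHH assumes phased haplotypes; the package does not phase. Unphased
  input is rejected with a pointer to the simulator or to pre-phased data.
* The mixed model fits a single genetic variance component; environments
  are analysed per environment rather than jointly.
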