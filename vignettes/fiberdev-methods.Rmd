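---
title: "Methods: models, conventions and design choices in fiberdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in fiberdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberdev)
```

`fiberdev` reimplements a comparative-transcriptome candidate-gene workflow
for cotton fiber quality as a deterministic, testable pipeline. This
vignette records the statistical models, the numeric conventions, and the
places where the verbal description of the workflow left genuine design
freedom — and what was chosen there, and why.

## Study design and stage model

The design is an unreplicated two-species time course: two *G. barbadense*
(Gb) and two *G. hirsutum* (Gh) accessions, each with one pooled RNA-seq
library at 0, 5, 10, 15, 20, 25 and 30 days post-anthesis (DPA). The stage
map is fixed throughout the package: 0 DPA represents lint initiation
(ovule sample), 5–15 DPA fiber elongation, and 20–30 DPA secondary cell
wall (SCW) biosynthesis. Pooling many plants per library is what justifies
treating each library as a precise estimate of the accession mean; there is
no replicate axis anywhere in the package.

## Expression and differential expression

Expression is RPKM, `count * 1e9 / (length * library_size)`; the inverse of
the same formula converts simulated mean RPKM into expected counts, so
quantification conserves the total count exactly.

For a pair of libraries without replicates, differential expression is the
pooled two-proportion z-test on library-normalised counts: with counts
`k1, k2` and library sizes `n1, n2`,
`z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
`phat = (k1 + k2)/(n1 + n2)`, two-sided p from the normal tail. The fold
change is `log2((k1 + 0.5)/n1) - log2((k2 + 0.5)/n2)`; the 0.5 pseudo-count
applies to the fold change only (it prevents infinite estimates at zero
counts) and never to the test statistic. A gene with `k1 + k2 = 0` carries
no information and is pinned to `log2FC = 0, p = 1`. The tests agree with
Fisher's exact test on the corresponding 2x2 table to within half a decade
of p wherever p-values are numerically meaningful (the suite checks
p >= 1e-12); in the farther tail both tests agree on overwhelming
significance but the normal tail cannot track the exact tail in log scale —
irrelevant at the `Q < 0.005` decision boundary.

Q-values are Benjamini–Hochberg, applied per comparison family: one
timepoint pair across all genes. Calls use the strict thresholds
`log2FC > 1` (or `< -1`) **and** `Q < 0.005`. Sample PCA runs on
`log2(RPKM + 1)` with genes as features, samples mean-centred.

## Trend grouping without clustering

The published groups came from a cluster analysis whose algorithm,
distance and boundaries are unstated. For reproducibility the package
replaces clustering with deterministic rules that match the groups' verbal
definitions:

* a stage counts as "up" only when the gene is called up versus 0 DPA at
  **all** of the stage's timepoints (the strictest reading, and the one the
  headline gene-set descriptions use);
* elongation groups I–IV split the elongation-up genes by the number `u`
  of SCW timepoints also called up (`u = 3` with higher SCW mean RPKM ->
  I, `u = 3` otherwise -> II, `u` in 1..2 -> III, `u = 0` -> IV), and SCW
  groups I–V mirror this with group V capturing the `u = 0` genes whose
  profile peaks at 30 DPA;
* group IV peak subgroups use a peak set of elongation timepoints within
  90% of the elongation maximum: 5 without 15 -> IV-I, 15 without 5 ->
  IV-III, otherwise IV-II. The 0.9 factor and the flat-top tie-break to
  IV-II are package conventions; the source gives no numeric rule.

Group assignment uses species-pooled Gb stage calls and the mean RPKM
across the two Gb accessions; the accession-level calls feed the
common-set intersection that precedes grouping. All rules are pure
functions of the calls and profiles, so the same inputs always give the
same labels.

## Cross-species candidate filter

"Upregulated in Gb compared with Gh during a stage" is implemented as:
pool counts and library sizes within species at each stage timepoint, test
Gb against Gh with the two-library test, adjust per timepoint across all
genes, and require an `up` call at **every** stage timepoint. Pooling is
the minimal faithful reading of a species-level comparison with two
accessions per species; a `strict = TRUE` mode additionally requires every
one of the four accession pairs to pass, and is never more permissive. SCW
candidates are split into type I when the Gh ortholog is itself called up
(vs 0 DPA) at two or more of the three SCW timepoints in **both** Gh
accessions, type II otherwise; the two-of-three/both-accessions rule is a
reconstruction — the dichotomy is described verbally in the source. The
ortholog mapping is the shared gene-id space of a single reference genome;
no ortholog inference is performed.

GO-style enrichment is the hypergeometric upper tail `P(X >= k)` for `k`
study hits among `n` drawn from a universe of `N` with `M` annotated,
BH-adjusted across terms, significant at `Q < 0.05`.

## Tri-primer marker model

For each candidate locus the package holds a gap-free aligned quartet of
sequences (species x subgenome). Sites are classified as
`interspecific_target` (Gb differs from Gh on the target subgenome, other
subgenome invariant), `subgenomic` (At differs from Dt, conserved within
species) or `other`. The assay anchors the allele-specific primers P1
(Gb allele) and P2 (Gh allele) with their 3'-terminal base on an
interspecific site and the common primer P3 on a subgenomic site, so the
homeologous copy is excluded by a guaranteed 3' mismatch.

Conventions and numeric choices:

* coordinates are 1-based; primers are always written 5'->3';
* melting temperature is the GC-content formula
  `64.9 + 41 (GC - 16.4)/L` for `L >= 14` (Wallace rule `2(A+T) + 4(G+C)`
  below), chosen for closed-form oracle checkability over nearest-neighbour
  thermodynamics;
* default constraints: length 18–25 nt, Tm 55–65 °C, pairwise ΔTm <= 5 °C,
  GC 40–60%, product span 100–600 bp — common AS-PCR practice;
* the **product span** is reported as the inclusive distance between the
  two 3' anchors. This makes the reported size a property of the site pair
  alone (the full amplicon additionally includes the primers' 5' tails);
* the amplification model requires an exact 3'-terminal match, at most one
  mismatch within the 3'-terminal five bases, and >= 90% overall identity,
  with convergent binding and the span inside the window. These thresholds
  model empirical AS-PCR discrimination and are configurable;
* the design search enumerates every (interspecific anchor, subgenomic
  anchor, AS-primer length, P3 length) combination in both layouts
  (allele-specific primers forward with P3 reverse, and the mirror),
  keeps combinations meeting the constraints, **and** requires the
  candidate triplet to reproduce the correct amplification pattern on all
  four quartet sequences under the package's own in-silico PCR model
  (Gb target copy -> P1/P3 only, Gh target copy -> P2/P3 only, neither
  non-target homeolog amplifies alone). This in-silico validation step
  mirrors how assays that cross-react or fail are discarded in practice and
  guarantees that genotyping a simulated population reproduces the
  simulated truth exactly wherever a design exists. Loci with no valid
  design are reported with status `NA`, as some published candidates were;
* ties among feasible designs break by smallest product span, then
  leftmost allele-specific anchor, then leftmost P3 anchor, then
  lexicographically smallest primer sequences — a total order, so the
  design is a pure function of the locus and constraints. The suite checks
  it against an independent exhaustive-search oracle.

Genotype calls map the two band patterns directly: (product, none) ->
Gb/Gb, (none, product) -> Gh/Gh, (product, product) -> Gb/Gh and
(none, none) -> `Missing` (the double-failure case is not defined by the
assay description; `Missing` is the package's convention).

## BC3F5 population simulator

Lines descend by explicit gamete simulation: the F1 is heterozygous at
every locus; each of the 3 backcrosses combines a recombinant gamete with
the recurrent Gh haplotype; each of the 4 selfings draws two independent
gametes from the same parent. Crossovers between adjacent markers occur
with the Haldane map function `r = (1 - exp(-2d/100))/2` on the cM
spacing — chosen because it is closed-form and makes the expectations
exactly testable: donor allele frequency `(1/2)^(1 + n_backcross)` (1/16
at BC3), unchanged by selfing; heterozygosity further halved per selfing
(`1/128` at BC3F5). The marker-assisted selection applied in the real
BC3F1–BC3F3 generations is deliberately not modelled (its map positions
are unknown); simulated populations are therefore selection-free.

Phenotypes are environment baseline + sum of planted additive effects for
donor-carrying genotypes (Gb/Gb or Gb/Gh pooled, matching how introgression
effects are assessed) + Gaussian residual noise. Defaults: two
environments with baselines at levels typical of modern upland cotton
(length ~29 mm, strength ~30 cN/tex, micronaire ~4.2, elongation ~6.6%,
uniformity ~85%), residual standard deviations of 0.9 mm, 1.1 cN/tex,
0.2, 0.25% and 0.8%, and two planted effects — +1.6 cN/tex strength and
-0.35 micronaire — the two effect directions relevant to the type I and
type II SCW candidates. Effects are environment-shared; the environment
enters as a baseline shift only.

The association scan runs a two-tailed pooled-variance t-test (Welch
optional) per marker, trait and environment, with no multiple-testing
correction by default (per-marker reporting; BH available behind a flag)
and groups smaller than two flagged `NA` rather than tested.

## The synthetic count generator

Planted genes follow mean-RPKM archetypes over the seven timepoints (one
archetype per trend group, e.g. the group IV elongation shapes peak at
5/10, 10, or 10/15 DPA and return to baseline through the SCW stage;
background genes are flat at RPKM 20). Cross-species candidates carry a
planted `effect_log2fc` (default 2) of Gb over Gh at their stage
timepoints; type II SCW candidates are additionally flat in Gh so their Gh
ortholog is not upregulated at all. Archetype levels are set so every
intended call clears the `|log2FC| > 1` gate with a wide margin at the
default library size of 5e6 reads, because the purpose of the generator is
to make the pipeline's decisions *recoverable*, not marginal. Counts are
Poisson around the expected value by default — with one pooled library per
sample there is no replicate-level overdispersion to estimate — and a
negative-binomial option (dispersion 0.05) is available for
sensitivity analysis.

What the generator does **not** emulate: genuine biological dispersion
between plants, length biases, multi-mapping between homeologs (about 11%
of real reads), unannotated transcription, or any correlation structure
among genes. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its own assumptions, not that the
thresholds are optimal for real libraries.

## Problem sizes and determinism

Default problem sizes are chosen to represent the study conditions at desk
scale: 2000 genes x 28 libraries for the count course (418 planted genes
across all archetypes, including 40/25/23 cross-species candidates,
mirroring the published 42/25/23), 48 loci x 600 bp for marker design, 167
lines for the default population, 10,000 lines for the population-genetics
checks and 150 replicate populations for the null calibration of the
association scan. Every generator takes a single integer seed and is
byte-reproducible under it; the pipeline derives all stage seeds from one
master seed.

## Known limitations

* The published genome-scale gene counts (e.g. 965/906 -> 759 common
  elongation-up genes) depend on the deposited raw sequencing data and are
  out of scope; the package reproduces the *logic* of the cascade and the
  published candidate tables, which ship as parsed fixtures.
* Which exact two-library method the original DEGSeq run used is unstated;
  the pooled two-proportion z-test is the standard unreplicated choice and
  is oracle-checked against Fisher's exact test.
* Quartets are assumed gap-free aligned (the generator guarantees this);
  indel-aware alignment is out of scope and length mismatches are
  rejected.
* Primer thermodynamics are deliberately simple; no dimer/hairpin checks,
  no KASP/TaqMan chemistry.
* The association scan is a marginal t-test per marker; no interval
  mapping, kinship correction or disentangling of linked candidates.
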