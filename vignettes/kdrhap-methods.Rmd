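---
title: "Methods: haplotype analysis of target-site insecticide resistance"
author: "kdrhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype analysis of target-site insecticide resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`kdrhap` analyses phased diploid genotypes around a single gene under
recent positive selection — the motivating case is the voltage-gated
sodium channel (*Vgsc*) of *Anopheles* mosquitoes, where target-site
substitutions such as L995F and L995S ("*kdr*") confer pyrethroid
resistance and have swept through African populations. The substrate of
every statistic is a haplotype matrix: sites × haplotypes of small integer
allele codes (0 = reference), two haplotypes per diploid sample, each
haplotype tagged with population, species and collection year. Phasing is
taken as given; unphased genotypes are rejected at import because every
downstream quantity (linkage, haplotype homozygosity, networks, shared
lengths) is defined on haplotypes.

# Codon-effect annotation

SNPs are mapped onto the coding frame of one or more transcripts (GFF3 CDS
features). Annotation is strand-aware: on the minus strand both the
reference codon and the substituted allele are complemented and codons are
read in transcription order. Effects are classed synonymous / missense /
nonsense; nonsense is kept separate rather than merged into missense so
that a premature stop can never masquerade as an ordinary
amino-acid change. Positions outside the CDS are reported as non-coding
rather than dropped, so multi-transcript comparisons can flag variants
that are coding in one isoform only.

Cross-species codon numbering (e.g. *An. gambiae* 995 ↔ *M. domestica*
1014, the numbering used throughout the resistance literature) is derived
from a global end-to-end protein alignment (BLOSUM62, affine gaps with
opening 10 and extension 1, via `Biostrings::pairwiseAlignment`). Aligned
residue pairs become map entries; gapped residues are reported as
unmapped. The scoring scheme is configurable because published codon
equivalences were produced with interactive aligners whose parameters are
rarely stated.

# Population statistics

**Allele frequencies and the 5% screen.** Frequencies are exact haplotype
count ratios per population; multi-allelic sites are decomposed into one
record per (site, alternate) pair so that every downstream statistic is
allele-level. The screening filter retains alleles whose *maximum*
per-population frequency is **at or above** the threshold (default 5%):
a resistance allele that is common anywhere is of interest everywhere.

**Lewontin's D′.** For two alleles with carrier frequencies $p_A$, $p_B$
and joint frequency $p_{AB}$ over haplotypes, $D = p_{AB} - p_A p_B$ and
$D' = D / D_{\max}$, with $D_{\max} = \min\{p_A(1-p_B), (1-p_A)p_B\}$ for
$D > 0$ and $\min\{p_A p_B, (1-p_A)(1-p_B)\}$ otherwise. $D' = 1$ means
one allele occurs only with the other; $D' = -1$ that they are never found
together. Multi-allelic sites are binarized per allele
(carrier/non-carrier), so each allele pair gets its own value, matching an
allele-level LD matrix. Monomorphic inputs yield a flagged undefined
result, never a silent NaN.

**Nucleotide diversity.** π is the mean pairwise Hamming difference over
all unordered haplotype pairs divided by the interval length, i.e. the
unbiased $\binom{n}{2}$ estimator; it is checked in the tests against the
algebraically identical per-site form $\sum_i 2p_i(1-p_i)\,n/(n-1)/L$.
πN/πS restricts the pairwise differences to missense (plus nonsense) and
synonymous sites respectively and normalizes each by the number of
site-opportunities in the CDS, counted per codon as the fraction of the
nine possible single-base changes that are synonymous versus not
(Nei–Gojobori-style; changes to or from stop count as non-synonymous).
The unnormalized variant-site ratio is available behind
`normalize = FALSE`. With πS = 0 the ratio is flagged undefined.

**Heterozygote-excess test.** Where two resistance alleles segregate in
one population, a deficit of inter-allele heterozygotes relative to
Hardy–Weinberg expectation suggests population structure, and an excess a
possible advantage of carrying both alleles. The Monte-Carlo construction:
draw allele frequencies from Dirichlet(counts + 1) — a flat prior over the
three-allele simplex; the published description names the Dirichlet but no
prior, and adding one to each count is the least-informative conjugate
choice — form Hardy–Weinberg genotype probabilities, draw genotype counts
for *n* diploids from the implied multinomial, and record the F/S
heterozygote count. Because the marginal of a single multinomial category
is binomial, the count is drawn directly as Binomial$(n, 2p_Fp_S)$, which
is distributionally identical and lets $10^6$ replicates run in seconds.
The p-value is the fraction of replicates *strictly greater* than the
observed count ("higher proportions of heterozygotes"); ties are excluded.
The test suite verifies calibration under the test's own generative null:
frequencies drawn from the same Dirichlet, an observed count drawn from
the same binomial, nominal 5% rejection recovered empirically.

# Haplotype groups

**Distances and clustering.** Pairwise Hamming distances over the gene
window use biallelic SNPs by default (multi-allelic sites are a separate
allele-level analysis; networks require binary coding). Agglomerative
clustering (default average linkage) is cut at a height expressed in SNP
differences — default 4, i.e. clusters of haplotypes within a few SNPs of
each other, far below the hundreds of differences between unrelated
backgrounds, and above the handful of private mutations expected within a
young sweep group.

**Labelling.** Clusters (and network components) are labelled by their
focal-allele content: within each focal class, groups are numbered by
decreasing carrier count (F1 = largest group of L995F-type carriers).
A group label is applied only to haplotypes that actually carry the focal
allele: a wild-type haplotype whose background matches a sweep group's
ancestral haplotype (which genuinely occurs — the sweep rose on an
existing background) stays `wt`, carriers outside any sizeable group
become `OR` ("other resistant"), and clusters below the minimum size
(default 3) are not named.

**Median-joining networks.** The construction iterates: build the
ε-relaxed minimum spanning network over the current node set (a pair is
connected iff its distance is within ε of its bottleneck/minimax distance;
ε = 0, the default, gives the union of all minimum spanning trees); for
every mutually connected node triple propose the per-site majority
consensus as an inferred ("median") node; add the proposal that most
shortens the minimum spanning length, and repeat to fixation. Candidate
generation is restricted to connected triples (the standard heuristic) and
candidates are examined in lexicographic order, so the network is
reproducible and invariant to haplotype input order. Unused median nodes
(degree ≤ 1) are removed. Finally, edges longer than the maximum edge
distance (default 2 SNPs) are pruned; pruning happens *after* full
construction, treating the threshold as an analysis/display cut whose
removal reproduces disconnected components. Components with fewer
haplotypes than a display minimum (default 3) are flagged but never
removed from the data structure. Edges whose distinguishing sites include
a missense site are flagged and labelled with the codon change, oriented
away from the reference allele.

**Concordance.** Agreement between the clustering and network groupings is
the fraction of haplotypes identically assigned after the best one-to-one
matching of the two label sets — a maximum-agreement assignment on the
confusion table, solved exactly with an internal Hungarian algorithm — so
pure relabellings score 1.

# Selection scans

**Core haplotypes.** A core region (1-based start, end-exclusive end; the
published *Vgsc* core 2L:2,420,443–2,426,521 spans 6,078 bp under this
convention) defines core haplotypes as the distinct allele strings over
its sites. Cores at cohort frequency *strictly above* 1% are retained
("above 1%") and labelled by focal content as for groups.

**EHH.** For the carriers of one core, extended haplotype homozygosity at
a site is the probability that two random carriers are identical at every
included site from the core edge out to that site:
$\mathrm{EHH} = \sum_i \binom{c_i}{2}/\binom{n}{2}$ over the prefix
partition classes. Cohort-wide singleton sites and non-synonymous sites
are excluded from the partitioning — singletons are recent private
mutations and missense sites are themselves potential selection targets;
neither reflects the shared ancestry of the flanking background. The
singleton rule is cohort-wide (not per population): exclusion mirrors the
variant-filtering step of the genotyping pipeline, which is cohort-level.
EHH is 1 at the core, non-increasing outward, computed as a step function
at site positions without interpolation, and stops at the region edge.

**Windowed homozygosity and divergence tracts.** Per window,
$H = \sum_i c_i(c_i-1)/(n(n-1))$ over distinct-haplotype class sizes — the
unbiased estimator consistent with EHH. The divergence scan counts sites
fixed for different alleles between two groups per window and merges
contiguous positive windows into tracts; it is how a gene-conversion tract
separating two otherwise identical sweep groups is localized, and a site
polymorphic within either group never counts.

**Shared haplotype lengths.** For each unordered carrier pair the maximal
interval of identity around the core (extending independently per flank to
the first mismatch at an included site) is converted to centimorgans with
a genetic map. The default map is a single constant rate of 1 cM/Mb —
a deliberate, configurable simplification: the published medians are in cM
but name no map, so absolute cM values here are only comparable within an
analysis. Pairs identical to the region edge get the censored length and
a censor flag. Medians carry a seeded percentile-bootstrap CI (default
2,000 replicates). The year–length association uses the Pearson
correlation with its two-sided t-transform p-value and is flagged
undefined when either variable has zero variance.

# Surveillance panel design

Haplotypes are labelled by their core (all non-resistant cores merged into
a single wild-type class) and biallelic SNPs in the gene ± 10 kb become
binary features. Information gain ranks SNPs; decision trees are grown
greedily (ID3 with information gain, or CART-style with Gini decrease,
restricted to binary features). Ties in gain break to the lowest SNP
index and leaf ties to the lowest class label, so tree shape is
deterministic and row-order invariant; repeats with different seeds only
affect cross-validation folds. One subtlety: a strict "stop when no split
has positive gain" rule cannot learn XOR-patterned allele combinations
whose individual gains are zero, while unconditional zero-gain splitting
would grow spurious depth on label-independent features. The tree
therefore accepts a zero-gain split only with one step of lookahead — some
feature must achieve positive gain in a child — which separates the two
cases exactly.

Cross-validation is stratified k-fold (default k = 5, following the more
conservative of the two fold counts reported for this design; k is a
parameter because published accounts differ between five and ten-fold),
repeated (default 10×) under one seed, reporting per-fold accuracy and the
number of distinct SNPs each tree used. Classes with fewer members than k
are merged into wild type with a warning rather than erroring — real
cohorts contain tiny groups.

# The synthetic cohort generator

The generator plants a fully known truth so that every stage of the
pipeline can be tested end to end without external data. Its default
parameters are chosen once to emulate the structure of a multi-country
phased cohort.

* **Scale.** 500 kb region, one 20 kb gene of five CDS exons, 8
  populations × 50 haplotypes (400 haplotypes, 200 diploids) of two
  species, collection years 2000–2012. These sizes keep every analysis in
  seconds-to-minutes while preserving the qualitative structure (many
  cohorts, a focal gene inside a broad flanking region).
* **Wild-type diversity.** Background mutations are dropped at density θ
  (default 0.0055/bp) on 25 founder haplotypes with a 1/i-weighted
  frequency spectrum; each wild-type haplotype is a founder mosaic with
  Poisson switch points (default 10⁻⁵/bp), giving background LD blocks.
  These defaults produce wild-type π ≈ 1.4 × 10⁻³/bp, the diversity scale
  reported for wild-type *Vgsc* haplotypes.
* **Sweep groups.** Twelve groups: five on each of two adjacent kdr-like
  missense focal alleles (F and S classes), plus two groups on private
  putative-resistance alleles (L1, L2). Each group copies one
  (group-specific) founder, sets the focal allele, and gives each carrier
  an independent Exponential(g·r) breakpoint distance per flank (g·r
  defaults 1–4 × 10⁻⁶/bp), beyond which the carrier continues as a fresh
  wild-type mosaic — a one-parameter stand-in for recombination since the
  sweep began that produces EHH decay and shared-length behaviour without
  a coalescent simulation. Poisson private mutations (default 1 per
  carrier) give within-group diversity on the 10⁻⁵/bp scale.
* **Secondary radiation.** Three extra missense mutations are planted on
  nested subsets of the largest F group (30 ⊃ 15 ⊃ 8 carriers), mirroring
  secondary substitutions radiating on a kdr background.
* **Divergence tract.** One S group shares another's founder and receives
  a tract of six derived alleles fixed across all its carriers. The tract
  is applied after recombination, which guarantees the planted
  fixed-difference count exactly, for any seed; it is a
  gene-conversion-like event represented by its observable consequence
  (a tract of fixed differences between otherwise identical groups)
  rather than by a mechanistic donor-copy model.
* **Determinism.** Everything is driven by one mandatory seed; the
  generator saves and restores the caller's RNG state, regeneration is
  byte-identical, and configs round-trip through JSON.

**What the generator does not emulate.** Recombination is a
nearest-breakpoint approximation, not a coalescent: there is no linkage
between carriers' breakpoints, no incomplete sweep softness, no gene flow
or admixture between populations (population labels affect only carrier
placement), no mutation-rate heterogeneity, and the allele-frequency
spectrum of real cohorts is only coarsely approximated. Passing the
recovery tests therefore shows that the pipeline's statistics recover the
structure they are defined to measure — near-identical high-frequency
backgrounds, planted fixed-difference tracts, group-diagnostic SNPs — not
that they would behave identically on data with realistic coalescent
noise, phasing error, or genotyping artefacts.

**Summary statistic for the diversity contrast.** The within-group versus
wild-type π contrast is summarized as the *median* across the planted
sweep groups. The published contrast statement concerns the groups that
are nearly identical across the gene; in any one simulated cohort a group
can contain a carrier whose recombination breakpoint fell inside the gene,
legitimately inflating that single group's π, and the median is the
natural robust summary of the typical group's diversity.

# Numerical and testing choices

Problem sizes in the test suite were chosen so the whole run completes in
a few minutes: the default 400-haplotype cohort for recovery checks, a
smaller 80-haplotype two-population configuration for I/O and property
tests, 10⁶ Monte-Carlo replicates for the two heterozygote-excess anchor
values, 2,000 replicates × 1,000 datasets for the calibration check, and
brute-force oracles (naive Hamming loops, explicit prefix partitions,
exhaustive assignment enumeration, hand-computed entropies) frozen
alongside each statistic. Genomic coordinates are 1-based inclusive
(VCF/GFF convention) everywhere except the core region, whose end is
exclusive — documented at the constructor — and interval arithmetic inside
functions notes its convention where it deviates.

# Known limitations

* The constant-rate genetic map makes cM lengths comparable only within
  an analysis; supplying a real map is a one-function extension.
* πN/πS normalization assumes the simple standard genetic code
  opportunity counting; no correction for transition/transversion bias.
* The median-joining implementation targets the modest node counts of a
  single gene region (hundreds of distinct haplotypes), not genome-scale
  input.
* Alternative transcripts are exercised with synthetic gene models only;
  behaviour on curated multi-isoform annotations follows the same code
  path but has not been validated against a published isoform set.
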