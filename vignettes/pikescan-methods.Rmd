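---
title: "pikescan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pikescan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

pikescan re-implements, as a tested and reusable pipeline, the
population-genomic analysis used to characterize whole-genome resequencing
data of North American northern pike (*Esox lucius*): a fish with very low
genome-wide diversity, a striking west-to-east diversity gradient produced
by post-glacial recolonization from Beringia, and an XY sex-determination
system (master gene *amhby*, absent from the female-derived reference
assembly) that has been lost in populations east of the continental
divide. The pipeline starts from a multi-sample VCF (read alignment and
genotype calling are out of scope) and covers:

* a GATK/VCFtools-style variant hard-filter cascade with a per-step
  retention report;
* per-individual and per-population diversity statistics (genotype
  tallies, observed heterozygosity H~OBS~, private alleles, fixed
  differences, windowed Tajima's D, identity-by-state distances);
* a chromosome-window polymorphism scan with Tukey boxplot outlier
  detection;
* DAPC (principal component analysis followed by linear discriminant
  analysis) built from first principles, with a BIC-driven cluster search
  and a Ward-clustering loading selector;
* three complementary detectors for sex-linked regions: sex-specific
  31-mers from raw reads (reference-free), an exact genotype-pattern scan
  combined with a DAPC screen, and read-depth-ratio presence/absence
  genotyping of a male-limited scaffold.

Because the original study is empirical and its full cohort is not
desk-scale, all validation runs on a synthetic cohort with planted truth.
The generator is first-class, tested code, and its defaults restate the
study's own conditions wherever the study states them.

## The synthetic cohort model

**Sites and frequencies.** Biallelic SNP sites are placed uniformly along
a simulated reference (i.i.d. bases at a target GC content, default 0.44).
Each site receives an ancestral allele frequency $q \sim U(0,1)$. Each
population sees a frequency drawn from the Balding–Nichols drift model

$$p_{\text{pop}} \sim \mathrm{Beta}\!\left(m\tfrac{1-F}{F},\,
(1-m)\tfrac{1-F}{F}\right), \qquad m = s_{\text{pop}}\, q ,$$

with a single drift parameter $F$ (default `fst = 0.25`). Strong drift is
the defining feature of these founder-effect populations — the study
reports hundreds of thousands of population-private alleles and tens of
thousands of fixed differences between Alaska and the St. Lawrence — and
Balding–Nichols reproduces exactly that phenomenology (mass near 0 and 1,
population-private and fixed alleles) while keeping moments analytic.

**Calibration to heterozygosity.** The per-population shrinkage factor
$s_{\text{pop}}$ is solved from the requested per-site expected
heterozygosity $\theta$ via
$E[2p(1-p)] = (1-F)\,(s - \tfrac{2}{3}s^2)$ (exact for $q \sim U(0,1)$),
so the expected per-individual heterozygous-genotype count is exactly
$(n_{\text{shared}} + n_{\text{private:pop}})\,\theta\,(1 -
\text{missing rate})$, which the truth set records. The model caps
$\theta$ at $\tfrac{3}{8}(1-F)$; requests beyond that are rejected. The
default $\theta$ values in the demo (0.161 for the Alaska-like carrier
population, 0.044 for the Manitoba-like population) are the published
per-population H~OBS~ values.

**Genotypes** are drawn Hardy–Weinberg within populations and
site-independently. There is no linkage disequilibrium: LD-based methods
are unsupported by this generator, and a green test here says nothing
about them. Private sites (default 15% of sites; the demo uses the same
default) have a nonzero frequency parameter in exactly one population.
A stated fraction of sites is emitted as 2-bp indels to exercise SNP
selection (28.6% in the demo, the published raw-table proportion).

**Caller semantics.** Only sites whose alternate allele is realized in at
least one genotype are emitted — a genotyper never reports a site without
variant evidence. Dropped sites contribute zero heterozygotes, so the
per-individual expected het count is unchanged, but two consequences are
worth noting: the emitted site count is below the attempted `n_sites`
(strong drift fixes many low-frequency sites), and H~OBS~ computed over
called sites exceeds $\theta$ (which is calibrated per attempted site)
because calling ascertains segregating sites. Retention percentages are
reported relative to the raw *SNP* count, matching the published
definition (the indel-inclusive raw row is reported but is not the
denominator).

**INFO annotations** (QD, FS, MQ, MQRankSum, ReadPosRankSum, QUAL,
per-genotype DP) are drawn from pass distributions with stated
per-criterion deliberate-failure fractions, so the filter report is
checkable against plants. The default fractions are calibrated to the
published per-step removal fractions (each hard-filter criterion fails
2.7% of sites so that $(1-f)^5 \approx 0.872$, the printed hard-filter
retention). Rank-sum annotations are absent at a small fraction of sites
(1%) to exercise the missing-passes rule. Per-sample mean depth is
N(20, 3.3), the published cohort's 20 ± 3.3×.

**The sex region.** `plant_sex_region()` adds the stated number of SNPs
inside a chromosomal interval at which every carrier-population male is
heterozygous and everyone else homozygous reference (the XY signature
against a female reference), plus a male-only insert contig — an
*amhby*-like scaffold modeled as pure presence/absence, carried on one
haplotype of carrier males and absent from the reference FASTA. The demo
interval is 650–1,150 kb of a 5-Mbp "LG24", the study's reported interval
on the real 29.5-Mbp LG24, with 100 planted SNPs (the acceptance scale;
the study reports 3,552 at full scale).

**Reads.** Each individual's two haplotypes are the reference edited by
its genotypes (heterozygous alternate alleles assigned to a random
haplotype per site); carrier males append the insert to haplotype 2.
Single-end reads of fixed length (default 150 bp, the study's PE150 read
length; pairing is irrelevant to every consumer here) are sampled
uniformly over haplotypes in proportion to length, giving the insert the
hemizygous expectation of half the autosomal depth. Per-base substitution
errors are applied at a stated rate; the acceptance world is error-free
at 15×. Uniform sampling means no coverage biases (GC, mappability),
which real data would have.

## Filter cascade conventions

The cascade applies, in the published order: SNP selection (REF and every
ALT a single base; multiallelic SNPs retained), the GATK hard filter
(QD < 2, FS > 60, MQ < 30, MQRankSum < −12.5, ReadPosRankSum < −8
remove a site; a missing annotation never does, matching GATK's behavior),
then QUAL ≥ 20, site mean depth within [10, 60] computed over non-missing
genotypes (the VCFtools convention), missing-genotype count ≤ 10, minor
allele count ≥ 1, and the "per-locus heterozygous genotypes < 100%" rule.
That last printed row enforces both "at least one homozygote" and "not
all heterozygous"; the first implies the second for called genotypes, and
both are individually switchable.

Minor allele count follows VCFtools semantics: copies of the least
frequent allele of the declared REF/ALT set among non-missing genotypes,
so a monomorphic site (declared ALT never observed) has mac 0 and is
removed. For multiallelic sites the minor allele is the least frequent of
all declared alleles, and the zygosity rules use genotype heterozygosity
regardless of which alleles are involved.

The report is defined for the published order only; since every step is a
per-site predicate, the final retained set is the intersection of the
predicates and is invariant under step permutation (asserted in tests),
while intermediate counts are not. The cascade is idempotent.

## Diversity statistics

* **H~OBS~** is the mean over loci of (heterozygous calls / non-missing
  calls) within a population, skipping loci without calls; with no
  missing data this equals mean per-sample heterozygous count divided by
  locus count (asserted as an identity). The published per-population
  H~OBS~ values do not exactly equal that ratio (plausibly missing-data
  handling in the original toolchain), so they are treated as approximate
  reference points, not targets.
* **Tajima's D** uses the standard constants
  ($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) with
  $n = 2 \times$ (non-missing diploids). Per 10-kb window,
  $S$ counts sites polymorphic within the population and
  $\pi = \sum_{\text{sites}} 2j(n-j)/(n(n-1))$ from unphased allele
  counts (exact for a random union of gametes);
  $D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$. The constants use the
  minimum per-site $n$ across the window's usable sites — a conservative
  choice the original tool leaves unstated. Windows with $S = 0$ have
  undefined D and are excluded from the per-population mean, which is the
  unweighted mean over defined windows (the original aggregation is also
  unstated). Sites with $n < 4$ are skipped and counted.
* **Private alleles**: a (locus, allele) pair is private to a population
  iff its copy count is positive there and zero everywhere else; a
  minimum copy count (1 or 4 in the study) thresholds the report.
* **Fixed differences** count biallelic sites fixed alternate in one
  population and fixed reference in another (non-missing calls only).
* **IBS distance** is mean allele-sharing mismatch over co-called sites,
  in [0, 1]; it stands in for the study's genome-wide dendrogram input
  (the ML tree itself is out of scope).

## Window scan

1-Mbp half-open windows tile each chromosome (final window truncated);
a variant at 1-based position $p$ belongs to the window containing
$p - 1$. The outlier rule is the boxplot convention: Tukey hinges
(median-inclusive halves, i.e. `fivenum`, deliberately *not* type-7
quantiles — the difference is material for small window counts), with
threshold = upper hinge + 1.5 × inter-hinge range and outliers strictly
above it.

## DAPC machinery

The genotype matrix (0/1/2 alternate-allele dosage; missing values
mean-imputed per site, the source ecosystem's default and a documented
limitation) is centered (optionally scaled; default unscaled, the likelier
configuration) and decomposed by PCA. The cluster search runs seeded
k-means (10 restarts) for each k on all PCs and records
$\mathrm{BIC} = n \ln(\mathrm{WSS}/n) + k \ln n$; the selected k minimizes
BIC. This is the standard k-means BIC and matches the source package's
formula; note it only exhibits an interior minimum when scores carry many
noise dimensions relative to samples (the "all PCs kept" regime it is used
in) — in low-dimensional embeddings it keeps decreasing with k, which the
tests exercise explicitly.

LDA maximizes the between/within variance ratio on the retained PCs
(eigenvectors of $W^{-1}B$; a singular $W$ is ridge-regularized with a
logged epsilon; axes are normalized to unit within-group variance).
Per-variant loadings are the composition of PC rotations with discriminant
coefficients. The snpzip-style selector Ward-clusters absolute loadings
(1-D, `ward.D2`) into two groups and keeps the higher-mean cluster;
all-equal loadings yield an empty selection with a warning. Defaults
n_pc = 24 and n_df = 3 are the published choices; they are capped at the
available rank and group count.

## Sex-linked-region detectors

**Sex-specific k-mers.** Canonical 31-mers (lexicographic minimum of a
k-mer and its reverse complement; odd k required to exclude palindromic
ties) are counted per sample in C++ (2-bit rolling encoding, flat
open-addressing hash table). A k-mer is sex-specific within a population
iff every opposite-sex individual has ≤ 2 copies (sequencing-error
allowance), every target-sex individual has ≥ 1 copy, and the target-sex
sum exceeds 7 — read as strictly greater, i.e. ≥ 8, with the boundary
tested. Populations need at least 3 individuals per sex (the study's
inclusion criterion). The per-individual thresholds are applied within
each population (the study's comparison is stated to be within
population). The streaming whole-cohort path fixes candidates from the
first target-sex sample (lossless when the per-individual minimum is
≥ 1), counts the other samples against them, and prunes candidates as
soon as an opposite-sex bound fails, which makes the later passes
cache-resident.

**Genomic anchoring.** Retained k-mers are anchored by scanning the
reference's windows against a hash set of the query k-mers' canonical
forms — exact matching by default. The original study mapped k-mers with
a short-read aligner that tolerates mismatches, and that tolerance is
load-bearing: a k-mer diagnostic of a male-heterozygous SNP carries the
alternate allele and can never exact-match the reference. With
`max_mismatch = 1` every single-substitution neighbor is added to the
query set (neighbors of the reverse complement are reverse complements of
neighbors, so canonical space covers both strands), which anchors
SNP-derived k-mers while insert-derived k-mers remain unmapped — and
unmapped k-mers are first-class output, being exactly the *amhby*-like
signal expected to be absent from a female-derived reference. Mapped hits
are counted in 10-kb windows.

**Genotype-pattern/DAPC screen.** Sites where any group member is
homozygous alternate are first dropped — against a female reference with
an XY system, sex-linked variation appears only as heterozygous or
homozygous-reference (the alternative of masking individual genotypes
instead of dropping sites is exposed as a flag). The exact pattern scan
flags sites where at most `tolerance` (default 0) males are not
heterozygous and at most `tolerance` females are heterozygous (missing
calls excluded from both tallies), and symmetrically for female-specific
heterozygosity. The DAPC screen runs sex-grouped DAPC on the prefiltered
table and intersects the snpzip structural set with the pattern-scan
hits, reporting candidates with their loadings.

**Coverage-ratio genotyping.** Mean depth on the male-limited target
region divided by mean depth on a control chromosome. The study reports
only "a clear difference in coverage"; the call thresholds here are
package defaults justified by the hemizygous expectation — a carrier male
holds the insert on one haplotype, so its depth ratio concentrates near
0.5, while a non-carrier's is near 0. Present ≥ 0.25, absent ≤ 0.05,
ambiguous between; calls are invariant to uniform depth rescaling.

## Seeds and reproducibility

Every stochastic operation takes a seed. The orchestrator fans a single
master seed into per-stage seeds through a fixed affine map modulo
$2^{31}-1$ (`derive_seed()`), and per-sample read seeds derive similarly,
so any stage or sample can be regenerated in isolation. All outputs are
byte-reproducible for a fixed seed, and every output file carries a
provenance header (package version, seed, stage parameters).

## Numerical choices and degenerate inputs

* Spacing figures round half-up to integer bp (matching the published
  "5,199 bp" convention); retention rounds to one decimal.
* `retention_percent` rejects a zero denominator; spacing rejects zero
  variant counts.
* Tajima constants require $n \ge 4$ and assert $e_1, e_2 > 0$.
* The Tukey rule requires ≥ 5 windows.
* PCA truncates `n_pc` beyond the matrix rank with a warning and rejects
  all-constant matrices; LDA requires ≥ 2 groups with ≥ 2 samples each.
* A site matching both sex-specific patterns (possible only in degenerate
  tiny cohorts) is reported once per pattern.
* IBS pairs with zero co-called sites are NA and flagged rather than
  dropped silently.

## What a green test establishes — and what it does not

The synthetic world has independent sites, Balding–Nichols drift, uniform
coverage, and a clean planted XY signature. Green acceptance therefore
establishes that the *statistics and detectors are implemented correctly*
and recover planted truth under the stated model; it does not establish
robustness to LD, alignment artifacts, reference bias, repeat-driven
coverage structure, batch effects between sequencing libraries, or
sex-ratio-skewed cohorts, none of which the generator emulates. The
published headline numbers that depend on the real 47-sample cohort
(1,127,943 retained SNPs; per-population H~OBS~ and Tajima's D; 3,552
male-specific SNPs; 59 outlier windows) are not desk-scale reproducible
and are deliberately replaced by planted-truth recovery criteria; only
the printed-arithmetic quantities (retention percentage, SNP spacing,
divergence) are reproduced exactly.
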