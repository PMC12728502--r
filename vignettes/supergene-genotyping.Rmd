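---
title: "Genotyping a social supergene: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a social supergene: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`supergeneR` infers supergene genotypes, candidate genes and mutation-load
contrasts from multi-sample SNP data. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The inference problem

A social supergene is a large non-recombining region segregating as two
haplotypes: ancestral M and derived P. Because recombination between them
is suppressed, an M/P individual is heterozygous at every position where
the haplotypes differ — thousands of linked sites — while M/M individuals
look like ordinary homozygotes. Haplodiploidy adds a twist: males are
haploid, so a *truly* heterozygous male call is impossible; when it occurs
consistently it means reads from two collapsed paralogous copies are
mapping to one locus (pseudo-heterozygosity), which is diagnostic of a
duplication. The package turns these signatures into five stages:
QC, genotyping, region delimitation, candidate scanning, and load
contrasts.

## Variant QC

`filter_thresholds()` reproduces a standard hard-filter chain for
joint-called SNP matrices, applied in a fixed order: non-biallelic or
non-SNP records are dropped (as are records whose FILTER column carries a
non-PASS value, when one is present); genotypes with depth < 3 are set
missing *before* any count-based rule; then sites are kept only with
QUAL ≥ 20, non-reference allele count ≥ 5, minor allele count ≥ 5, and at
least 60% of samples called; sites heterozygous in more than 90% of all
samples are removed (a mapping-artifact screen); finally samples missing
≥ 10% of the remaining sites are excluded. Fraction rules compare exact
rationals; a `1e-9` slack keeps binary floating point from misclassifying
counts that sit exactly on a bound (e.g. 1 missing carrier out of 5
against a 0.2 limit).

Order matters downstream: the minor-allele-count filter removes
singletons, so per-sample rare variants never reach the inbreeding
coefficient or the heterozygosity scan. The genotyping stage is specified
on the *filtered* matrix.

## Inbreeding coefficients and carrier detection

`compute_fis()` implements the method-of-moments estimator
$$F = \frac{O_{hom} - E_{hom}}{N - E_{hom}}, \qquad
E_{hom} = \sum_i \left[1 - 2 p_i (1 - p_i)\,\frac{n_i}{n_i - 1}\right],$$
with $p_i$ the cohort alternative-allele frequency and $n_i$ the number of
called alleles at site $i$; sites with fewer than two called alleles are
skipped. The finite-sample correction $n_i/(n_i-1)$ matches the classic
per-individual heterozygosity screens used on joint-called cohorts. An
M/P worker is heterozygous across the whole supergene, so its observed
homozygosity collapses far below expectation: the carrier threshold is
`F_IS < −0.5`, strict, and only diploid samples are eligible. The
threshold is a parameter (`fis_threshold`), but −0.5 separates the two
modes by a wide margin whenever the supergene contributes an appreciable
fraction of the chromosome's SNPs.

## Region delimitation

`window_het_scan()` counts heterozygous calls per carrier in 20 kb
windows tiled from position 1 (the last partial window is retained).
`delimit_region()` then finds the longest run of windows whose
carrier-group mean exceeds `min_fold = 5` times the median of the windows
*outside* the run, iterated to a fixed point; the first pass uses the
lower quartile as the background level because the elevated region may
span half the chromosome. Window counts are Poisson-noisy, so the run is
made robust the way peak callers are: interior dips of at most `max_gap =
3` windows are absorbed, and run edges are extended by hysteresis while
neighbouring windows clear *half* the fold threshold. These three
parameters are exposed; the defaults recover planted boundaries to the
window exactly in the reference simulations. The delimitation algorithm
as a whole is a design choice of this package — the underlying studies
report region bounds without an algorithmic definition.

## Trans-species haplotype-specific SNPs and class assignment

`extract_trans_specific()` keeps a site iff every *called* carrier is
heterozygous and the missing fraction among carriers is strictly below
0.2. With a panel of $k$ carriers, a background site slips through by
chance with probability $\prod_j 2p(1-p) \le 0.5^k$: negligible at the
study-scale panel of 19, but an expected handful of coincidental sites at
panels of 3–5. Extraction robustness therefore trades off against panel
size in opposite directions for false positives (small panels) and error
sensitivity (large panels: a site is lost if *any* carrier is miscalled,
so recall is $(1-e)^k$ at genotype error $e$).

`classify_by_proportions()` computes each sample's genotype proportions
p00/p01/p11 over the panel. Stored proportions use all panel sites in the
denominator (so p00 + p01 + p11 + missing = 1); the decision rule
renormalizes by the called fraction and assigns by majority
(`majority = 0.8`): reference-homozygous majority → `MM`/`hapM`,
alternative-homozygous majority → `PP`/`hapP`, heterozygous majority →
`MP` for diploids and, for haploids, `hapP` with a duplication flag.
Samples with under half the panel called are `ambiguous`. The 0.8
majority is far from every case the decision rule is meant to separate
(real cohorts sit near 0 or 1) and is exposed as a parameter.

## Candidate-gene scan

`count_p_specific()` counts, per gene and M/M worker, panel sites in CDS
where the genotype is heterozygous or alternative-homozygous ("P-specific
alleles"); missing genotypes contribute nothing. `contrast_groups()`
tests each gene for more P-specific alleles in obligately polygynous than
in socially polymorphic species. The observational unit is the *species
mean* (three per group by default), not the worker — workers within a
species share demographic history, and using them directly would
pseudo-replicate. The test is the pooled-variance two-sample t
(equivalently a two-level one-factor linear model), computed from the
textbook formula so that zero-variance groups are well-defined (equal
means → t = 0, p = 1; unequal → p = 0); `stats::t.test` is the
cross-check in the test suite. Bonferroni adjustment multiplies by
`n_tests` (by default the number of genes with at least one panel CDS
site) and caps at 1.

Duplications are confirmed by two independent signals:

* `normalize_depth()` divides each sample's per-CDS depths by its own
  all-CDS mean (every sample's mean normalized depth is exactly 1), and
  `depth_contrast()` runs two-sided Wilcoxon rank-sum tests on the
  per-CDS-part values between genotype groups. Note that normalizing by a
  mean that itself contains the duplicated parts shrinks the observed
  ratio below the true copy-number multiplier by a factor
  $n/(n + d(m-1))$ for $d$ of $n$ parts duplicated at multiplier $m$ —
  about 6% at the reference configuration.
* `haploid_pseudo_het()` flags genes in which a haploid male is
  heterozygous at ≥ 90% of its called panel CDS sites, requiring at least
  `min_sites = 3` called sites — a fraction over one or two sites can be
  a single miscall, not duplication evidence.

`pairwise_identity()` (used to characterize paralog divergence) counts
matching columns over columns where not both sequences are gapped; a gap
aligned to a base is a mismatch. `tpm()` computes
`(count/length)/(total/1e6)` with expression classes at the public-atlas
cutoffs (below < 0.5, low [0.5, 10], medium (10, 1000], high > 1000).

## Coding consequences and mutation load

`classify_effect()` reconstructs the affected codon from the CDS in
transcript orientation (reverse-complementing on minus-strand genes),
translates reference and alternative codons with the standard genetic
code, and maps consequences to impacts: stop_gained, stop_lost,
start_lost and splice_disrupting (within 2 bp of an intron end — the
canonical donor/acceptor positions) are `high`; missense `moderate`;
synonymous `low`; everything else `modifier`. Fixed conventions: one
transcript per gene (the longest CDS when an annotation has several), and
at codon 1 any amino-acid-changing substitution of an ATG is `start_lost`
even if it also creates a stop. The test suite checks the classifier
against an independent oracle that mutates the genome, re-extracts the
CDS with Biostrings and compares full translated proteins — exhaustively,
over every possible substitution of randomly generated genes on both
strands.

`per_sample_load()` restricts to sites inside the supergene region where
the sample carries at least one alternative allele (the per-sample
mac-1 extraction) and reports counts and proportions over
high/moderate/low; the denominator excludes `modifier` sites, matching
the three-category presentation such analyses use. `contrast_load()` is
a two-sided Wilcoxon rank-sum test on the per-sample proportions (normal
approximation with continuity correction, so ties are handled uniformly).

## The synthetic cohort generator

`simulate_cohort()` plants the statistical structure the analysis
assumes, with truth recorded for every planted feature. Channels:

* **Divergent sites** (default 500 in a 0.5 Mb supergene on a 1 Mb
  chromosome): fixed M-vs-P differences; M/P samples heterozygous, hapP
  and P/P alternative-homozygous. A `homogenized_fraction` (default
  0.15) of them is erased by gene conversion and segregates like
  background.
* **Background sites** (default 300): allele frequencies uniform on
  [0.05, 0.95], genotypes binomial per sample, independent of class.
* **Duplicated block**: two adjacent genes inside the supergene with 22
  and 5 pseudo-heterozygous trans-specific CDS sites (the block genes'
  only trans-specific sites — inside a collapsed duplication every such
  site reads heterozygous in carriers) and 2× read depth in carriers —
  the copy-number expectation for a two-copy collapse. Carriers are all
  M/P, P/P and hapP samples plus M/M workers at per-species frequencies
  (`mm_dup_freq`): near-fixed (0.95) in obligately polygynous species and
  absent in socially polymorphic ones, the configuration under which the
  block is discoverable by the group contrast.
* **Load**: per-haplotype-copy private mutations on supergene CDS sites
  (an infinite-sites model). Each M or P haplotype copy receives
  mutations per impact category at per-site rates; every mutation gets
  its own CDS site whose alternative allele is chosen from the codon
  table so the planted impact is guaranteed. Deleterious variants are
  modeled as young, copy-private alleles — the selection-skewed end of
  the frequency spectrum — while ancient shared P-specific variation is
  carried by the divergent channel. Two consequences worth knowing:
  copy-private singletons are removed by the cohort-level minor-allele
  filter, so they never perturb F_IS or the heterozygosity scan on the
  QC'd matrix (mirroring real filtered callsets, which contain no
  singletons); and the fixed divergent alleles that fall in CDS *do*
  enter M/P workers' load composition — they are genuine P-specific
  coding variants, not differential load, which is why the load
  calibration experiments switch the divergent channel off.
* **Noise**: genotype errors replace a call with one of the other two
  dosages uniformly at rate 0.01; missingness 0.05; per-site depths are
  negative-binomial around 21.9× (the reference cohorts' mean coverage)
  with gamma-noise per-CDS means, dispersion 0.2 (squared CV), and a
  per-sample lognormal efficiency so depth normalization has work to do.

Haploid males are emitted as diploid-style homozygotes, as joint callers
genotype them; their only heterozygous calls (error aside) are at the
planted duplication. One P/P diploid is included in the default cohort so
that all five classes are exercised, although in the real system P/P
workers are absent — the class exists precisely so its absence is a
*finding*, not a blind spot.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, mapping-error haplotype structure, reference bias,
indels and multi-allelic sites, between-species divergence outside the
supergene, and realistic site-frequency spectra for neutral variation.
Passing tests therefore demonstrate the *inference logic* under the
stated statistical structure, not robustness to every artifact of real
short-read data.

## Reference experiment configurations

Two fixed designs (`load_experiment_config()`) standardize the
mutation-load experiments. The *null* design (30 M/M vs 10 M/P, equal
rates on both haplotypes, no divergent channel) simulates under the
rank-sum test's null so its type-I error can be measured; measured
rejection is ~2–4% at α = 0.05 over 200 cohorts. The *power* design
plants a 2× high-impact rate on P in the 5-vs-50 imbalanced setting and
is sized — about 26 kb of supergene CDS per haplotype copy, chosen from
the binomial arithmetic of per-sample variant counts — so the planted
effect separates groups by roughly 2.4 standard deviations per sample,
giving median p well below 0.05.

The candidate-discovery experiments run at genotype error 0. With
per-gene 3-vs-3 t-tests, error-perturbed near-zero counts reject at
roughly the nominal 5% per gene, so at 1% genotype error some false raw
hit would appear in most runs across ~15 tested genes; raw p-values are a
screening statistic, and the discovery experiment is designed to test the
discovery logic, not the multiplicity behaviour of noisy screens (which
the Bonferroni step addresses).

The genotype-recovery experiments use cohorts of 60 samples in all five
classes at 1% error and 5% missingness; class recovery is 100% across
seeds. Trans-species extraction is checked for exactness at error 0 with
a 19-carrier panel (at that panel size the chance of a background site
being heterozygous in every carrier is negligible) and for recall at 1%
error with a 3-carrier panel, the smallest per-species carrier count in
the reference design, where expected recall is $(1-0.01)^3 \times$ the
panel's site survival ≈ 0.97.

## Known limitations

* The proportion-based classifier assumes the reference genome carries
  the M haplotype; if it carried P, the class labels of the homozygote
  majority would be mirrored. Orientation must come from a known-genotype
  sample, as it does in practice.
* The consequence engine is deliberately minimal: SNPs only, one
  transcript per gene, no UTR/regulatory ontology. Frameshift and
  exon-deletion categories exist in the impact map but are not callable
  from SNPs.
* Wilcoxon contrasts of load between M/M and M/P workers inherit a
  pseudo-replication caveat from the design itself: there is only one
  realized pair of haplotypes, so "significance" quantifies the realized
  difference, not a replicated haplotype-level sampling process. The
  calibration experiment sidesteps this by construction (copy-private
  load); shared-variant structure would re-introduce it.
* Region delimitation assumes the supergene's heterozygosity elevation
  is at least about five-fold over background at the chosen window size;
  much weaker contrasts need a larger window or a lower `min_fold`.
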