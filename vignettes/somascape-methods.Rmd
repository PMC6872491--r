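---
title: "Models and methods behind somascape"
author: "somascape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the numerical choices and
the known limitations of the package. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

# The purity/copy-number mixture model

A sequenced tumour sample is a mixture of tumour cells (fraction $p$, the
purity) and normal cells. For a genomic segment with tumour total copy
number $c$, major allele copy number $M$ and germline copy number $n$ (2 on
autosomes, 1 on male X/Y), the expected observables are

* depth ratio $r = \dfrac{pc + n(1-p)}{p\Psi + 2(1-p)}$, normalised so the
  genome-length-weighted mean is 1 at sample ploidy $\Psi$ (the sequencer
  delivers a fixed total depth regardless of how large the tumour genome
  is, which is why $\Psi$ enters the denominator and must be estimated
  jointly with $p$);
* B-allele frequency of germline heterozygous SNPs,
  $b = \dfrac{pM + (1-p)}{pc + 2(1-p)}$ on autosomes.

`fit_purity_ploidy()` grid-searches purity 0.08–1.00 (step 0.01) × ploidy
1.0–8.0 (step 0.02). At each grid point it inverts the two equations per
segment to a real-valued $(c, M)$, snaps to the nearest valid integer
allele-specific state ($M \ge m \ge 0$), and scores

$$\sum_i w^{\mathrm{snp}}_i\,(b_i - \hat b_i)^2 +
  w^{\mathrm{len}}_i\,(r_i - \hat r_i)^2 +
  \lambda\, w^{\mathrm{len}}_i (c_i - \hat c_i)^2,$$

with SNP-count weights on the BAF term, length weights on the ratio term,
and a small integer-attraction term ($\lambda = 0.005$).

## Degeneracies and the tie-break

Two exact degeneracies exist and drove the selection rule:

1. **Purity/ploidy aliasing.** A sample at purity $p$ with states
   $\{(M_i, m_i)\}$ produces *identical* expected observables to one at
   purity $p/(1-jp)$ with states $\{(M_i + j, m_i + j)\}$, for any integer
   $j$ for which all states stay valid. LOH segments ($m = 0$) make the
   downward alias invalid, which is why they are so informative.
2. **State doubling near purity 1.** At $p = 1$ both observables are
   invariant under $(c, M) \to (2c, 2M)$, $\Psi \to 2\Psi$; worse, the
   doubled solution has integer states at half the spacing and therefore
   *overfits noise*, scoring slightly better than the truth.

An additive penalty on ploidy is the obvious remedy but fails: tuned
strongly enough to beat the doubling degeneracy it also drags genuine
whole-genome-duplicated samples to their halved alias even when LOH
segments clearly discriminate. Instead the fit uses a two-stage selection:
all grid points scoring within a fixed relative factor (default 6×) of the
minimum are treated as candidate solutions, and the best-fitting member of
the lowest-ploidy candidate family is returned. Genuinely resolved fits are
untouched (wrong families score an order of magnitude worse than the
optimum), while members of an exact alias family differ only by noise and
resolve to the parsimonious profile. When the profile is entirely balanced
diploid the surface is flat in purity; the fit then reports the lowest grid
purity and sets `purity_unreliable`.

Sample ploidy is always recomputed as the length-weighted mean of the
fitted real-valued copy numbers, so the reported ploidy is an exact
function of the reported segments.

## Decision constants

All downstream rules use strict inequalities at the published constants,
collected as the defaults of `pipeline_config()`: WGD when major allele
ploidy > 1.5 over ≥ 50% of ≥ 11 autosomes; biallelic when variant ploidy
> CN − 0.5; MSI when the qualifying-indel score > 4/Mb; high-level
amplification when minimum exonic CN > 3 × sample ploidy (2× moderate,
1.4× low); homozygous deletion when < 0.5; TMB immunotherapy flag when
> 10 mutations/Mb; SMG significance at q < 0.01; signature reporting
excludes contributions < 5% or fitted loads < 300 variants; purity QC
excludes < 20%; fragile sites need gene length > 500 kb *and* > 30% of
deletions sized 20 kb–1 Mb.

# Variant-level models

**Variant ploidy.** $v = f\,(pc + n(1-p))/p$ for observed VAF $f$. This is
the expected number of chromatids carrying the variant times the cancer
cell fraction, so clonal single-copy variants sit at $v = 1$, clonal
doubled variants at $v = 2$, and a subclone at CCF 0.4 at $v = 0.4$.

**Clonality.** The somatic ploidies of one sample are fitted with a
Gaussian mixture (EM, unequal variances, BIC selection over 1–5 components
via mclust). A peak is subclonal when its location is below CCF 0.85 —
the boundary is a declared design choice; the sources describe a
clonal/subclonal peak decomposition without a numeric bound. Responsibilities
are recomputed from the returned parameters so that peak weights equal the
mean membership probabilities exactly, making the sample subclonal
fraction identical to the probability-weighted variant mean (a tested
invariant). Below 50 variants a single clonal peak is returned with a
warning rather than an unstable mixture.

**MSI.** Qualifying indels are counted per variant (a locus hit twice
counts twice) — whether the original scorer counts per locus or per
variant is not derivable from its description; per-variant is declared
here and used consistently by scorer and generator. The denominator is the
configured genome length in Mb, so mini-genome runs score on the same
scale as full-length runs.

**TMB** counts SNVs + MNVs + indels per Mb; the class list is a
convention choice (inclusive), and the threshold is configurable.

**Signatures.** Non-negative least squares (Lawson–Hanson via pracma)
against a fixed 96 × 30 column-normalised signature matrix; the residual is
the L1 distance between observed and fitted context counts. Fitted loads
are rounded at 10⁻⁶ so that exact-cone inputs hit the reporting filter's
boundary exactly rather than by floating-point accident.

# Driver discovery

**Simplified dN/dS.** Mutation rates per 96-type trinucleotide context are
estimated from synonymous variants cohort-wide (count/opportunity);
expected missense and nonsense counts per gene follow from the gene's
opportunity spectrum, splice expectations from the global mean per-site
rate × essential-splice opportunity, and coding-indel expectations from
coding length. Each gene × class is Poisson-tested against its expectation
and BH-corrected within class. This deliberately omits the covariate and
negative-binomial shrinkage machinery of the full dNdScv model; with the
synthetic genome's homogeneous gene set those refinements address
between-gene rate variation that the generator does not produce. The
splice expectation uses the synonymous-site mean rate while splice sites
are simulated at the all-site mean rate; because synonymous sites are
transition-enriched this overestimates the splice expectation slightly — a
conservative bias (never anticonservative) accepted for simplicity.

**Peak peel-off.** Per chromosome and direction, the gene with maximal
supporting-sample count seeds a peak, extended over the contiguous run of
genes at which every seed-supporting sample also has an event; the target
gene is curated as: panel gene in the peak, else shortest gene fully
inside the peak, else the seed. Supporting samples are peeled off and the
search repeats until support falls below max(5, 2% of the cohort) — a
declared stopping rule preventing noise peaks on small cohorts.

**Driver likelihood.** $E/(E + P_s)$ with $E$ the gene/class excess
(observed − expected, floored at 0) and $P_s$ the expected passenger count
scaled by the sample's TMB relative to the cohort mean. The functional
form is the simplest with the required monotonicities (increasing in
excess, decreasing in sample burden, bounded in [0, 1]); the published
description names the inputs but not the formula. Oncogene variants at or
within 5 nt of a hotspot, TSG variants with biallelic inactivation in
predominantly-biallelic genes, and TERT-promoter hits are floored at 0.99.

**Fusions.** In-frame coding fusions require both breakends intronic with
equal coding phase and a known 5′/3′ pair or promiscuous 3′ partner;
cis-activating events reposition sequence into the 10 kb 5′ window of a
promiscuous partner; intragenic deletions are in-frame when the removed
exons' total length is divisible by 3.

**Germline.** Restricted to the 29-gene high-confidence panel (25 ACMG
cancer genes + CDKN2A, CHEK2, BAP1, ATM). At LOH loci the tumour VAF of
the germline variant decides which allele was lost: variant ploidy above
CN − 0.5 means the wild type was lost; below 0.5 the variant itself was
lost (so it is counted as loss-of-variant, not loss-of-wild-type).

# Actionability

Evidence records carry (gene, event class, detail, drug, level A/B,
direction, disease-ontology id); C/D/E levels are dropped at load.
Matching granularity is exact detail > gene + class > gene, most specific
per drug. On-label status uses a fixture parent–child ontology table
(reproducible without network access); tumours without an ontology id
match off-label with a warning. Treatments with resistance evidence from
*another* biomarker at the same or higher level are excluded — exclusion
is keyed on the drug, the simplest equivalence class consistent with the
described rule. Remaining matches rank A on-label > A off-label > B
on-label > B off-label; the ranking is a total order, so results are
invariant to match order (tested by permutation).

# The synthetic cohort generator

The default genome scales GRCh37 chromosome lengths by 1/30 (≈103 Mb),
keeping per-autosome WGD logic intact at desk-scale runtime; `scale = 1`
gives full lengths. Defaults emulate the deep tumour/normal design the
stack targets: 106× tumour and 38× normal depth, negative-binomial
per-site depth (size 10), binomial read sampling of VAFs under the
mixture model, heterozygous SNPs at ≈0.67/kb, purity 0.65, and clone CCFs
restricted to {1} ∪ (0.1, 0.9) so clonal/subclonal truth is unambiguous.
Segment depth-ratio noise is gamma with shape proportional to the
effective read count of the segment (cv ≈ 0.2% on 1 Mb at 106×),
consistent with the read-sampling noise model; mapping and GC noise are
off by default (a GC-bias amplitude is exposed, and the QC metric tests
the residual-vs-GC slope against a declared threshold of 0.25, since no
published numeric criterion exists).

Aberrant segment states are drawn from weighted pools (loss-dominated for
non-WGD profiles, centred on (2,2) for WGD), and every profile carries at
least one LOH segment — both realistic (LOH affects roughly a quarter of
the autosomal genome in advanced tumours) and necessary for purity
identifiability. The truth WGD flag is the duplication rule applied to the
truth profile, not the configuration switch.

Two simplifications matter for interpreting test results. The genome
carries no nucleotide sequence outside gene coding regions: trinucleotide
contexts of non-coding SNVs are drawn from the signature mixture and
carried as annotations, and segment BAF is reported as the
haplotype-resolved major-allele fraction (the generator knows phase),
avoiding the folded-BAF bias real pipelines must correct. Consequently,
passing tests demonstrate correct inversion of the generator's mixture
model and correct rule application — they do not exercise alignment
artefacts, fold-bias correction, or context estimation from raw sequence.
Read-level simulation (FASTQ/BAM) is out of scope.

# Problem sizes and numerical choices

Test and acceptance runs use the 1/30 mini-genome with cohorts of 8–20
samples, 50–2,000 SNVs per sample, dN/dS cohorts of 40 samples (neutral
control, 20 replicates) and 200 samples (power, 20 replicates), and
10-seed replicates for clonality and signature recovery — sizes chosen so
each property is measured with useful precision on a single CPU. Grid
tie-breaking, the 10⁻⁶ contribution rounding in the signature refit, the
purity-1 parameterisation used when sweeping the biallelic boundary (so
the VAF inversion is floating-point exact), and deterministic child-seed
derivation (`derive_seed`, all seeds < 2³¹) are the notable numerical
choices. Degenerate inputs (no informative SNPs, empty cohorts, zero
synonymous variants, missing ontology ids) raise informative errors or
flagged fallbacks rather than silent results.

# Known limitations

* The purity objective is a surrogate: the original tool's exact objective
  and segmentation-refinement rules are not public in the main text, so
  agreement is demonstrated on the mixture model's boundaries and
  parameter recovery, not on tool-identical output.
* The simplified dN/dS has no covariates; on real cohorts with strong
  regional mutation-rate variation it would be anticonservative.
* Hotspots, known fusions, the evidence knowledgebase and the disease
  ontology are synthetic fixtures that mirror the structure, not the
  content, of COSMIC/CGI/CIViC/OncoKB resources.
* The clonality mixture operates in variant-ploidy space without
  copy-number-aware multiplicity deconvolution; variants at multi-copy
  states contribute clonal peaks at integer locations rather than being
  re-mapped to CCF.
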