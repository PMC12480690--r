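---
title: "Methods: splice-site usage, single-site mapping and hexamer rankings"
author: "splicehex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-site usage, single-site mapping and hexamer rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind every stage of the
package, the parameters that matter, the behaviour of the synthetic-data
generator, and the design decisions taken where more than one reasonable
reading existed. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The usage estimate and its filtering

The splice-site strength estimate for a site in one sample is
`SSE = alpha / (alpha + beta)`: `alpha` junction reads spliced at the site,
`beta` reads crossing the site position without splicing there (continuous
spanning reads and junction reads splicing past it both count toward `beta`;
a configuration of the upstream counting step, not of this package). The
estimate is a binomial proportion, so its sampling noise scales as
`sqrt(p(1-p)/n)` with the crossing depth `n` — all downstream depth
thresholds exist to control this term. Where `alpha + beta = 0` the value is
missing, never `0/0`.

This package deliberately uses the plain ratio; partner-weighted refinements
of `beta` used by dedicated quantifiers are out of scope, which should be
kept in mind when comparing absolute values across tools.

Filtering (defaults; all configurable):

* `min_reads = 10` crossing reads for a replicate to count,
* `min_replicates = 3` such replicates for a genotype to count
  (`1` for unreplicated cohorts),
* `min_genotypes = 100` such genotypes for a site to be retained,
* genotype means require `min_pass = 2` passing replicates (`1` without
  replication); strata such as sex or tissue are averaged separately.

Filtering is monotone by construction: raising any threshold can only drop
sites. Missing genotypes are excluded from a site's statistics, not imputed.

## 2. Variability, heritability, and site selection

Per site we report the range (max − min) and sample variance of
genotype-mean usage, plus a binned summary (bins of width 0.1 on the range,
mean variance per bin). Broad-sense heritability comes from a one-way ANOVA
of replicate-level SSE on genotype:
`sigma_g^2 = (MS_between - MS_within) / r_harmonic`,
`H^2 = sigma_g^2 / (sigma_g^2 + MS_within)`, clamped to [0, 1]. The
harmonic-mean replicate count handles unbalanced designs; genotypes need at
least two passing replicates to enter, and at least two such genotypes are
needed or H² is missing. Note that `MS_within` absorbs both the replicate
noise and the binomial sampling term `p(1-p)/depth`, so even with equal
planted genotype and residual standard deviations the estimate sits slightly
below 0.5 at finite depth — the acceptance experiment (100 genotypes × 4
replicates, depth 150) shows exactly this behaviour, within the stated ±0.1.

Sites for mapping: the intersection of the top variance quartile and the top
H² quartile (variance quartile alone when H² is unavailable), with at least
100 observed genotypes. Quartile cut-offs are computed on the sites that
passed coverage filtering, not the whole transcriptome, matching the order
of operations of the rest of the pipeline; selection uses `>=` the 0.75
quantile.

## 3. Association mapping and peak calling

The association engine is ordinary least squares of genotype-mean SSE on
dosage, one variant at a time, two-sided p from the slope t-test. When a
kinship matrix is supplied, phenotype and dosages are first residualised
against its leading eigenvectors (default 5) — a deliberately transparent
stand-in for a full mixed model, recorded in the output metadata. P-values
are floored at the smallest positive double rather than reported as 0.

* **MAF filter:** `>= 0.05`. Stated boundary conventions differ between
  "greater than 5%" and ">= 0.05" in the field; the inclusive reading is
  implemented and the threshold is a parameter.
* **Significance threshold:** Bonferroni `0.05 / n_variants` by default,
  configurable and recorded.
* **Peaks:** significant variants merged within 100 kb (configurable — the
  grouping granularity is data-density dependent), peaks below
  `min_peak_snps` dropped. The default of 50 reflects dense population
  panels; the sparse synthetic fixtures in the tests use 1, because a planted
  causal SNP has no LD partners there.
* **Noise gate:** a peak passes iff `-log10(p)` of its top SNP is at least
  1.33 × the mean `-log10(p)` of the five lowest-p variants genome-wide, no
  two within 750 kb (greedy selection in ascending p; fewer than five
  eligible variants are used as-is and flagged). The reference set includes
  the peak's own members — the alternative (excluding them) is not
  distinguishable from the stated rule, and including them is the more
  conservative gate.
* **Top SNP:** minimum p; ties break to the variant closest to the site.
* **Distances:** strand-normalised, position 0 = the intron-terminal G (of
  the donor GT / acceptor AG); the transcribed-strand sign convention makes
  donor-intronic positions positive and acceptor-intronic negative.
* **cis/trans:** cis iff same chromosome and |genomic distance| <= 1 Mb;
  different chromosomes are trans by definition (the rule is a distance, and
  no distance exists across chromosomes).
* **Effects:** ΔSSE = mean(minor-allele SSE) − mean(major-allele SSE);
  PVE = `2β²f(1−f) / (2β²f(1−f) + se²·2N·f(1−f))`, the standard single-SNP
  variance-explained formula (the allele-frequency factor cancels;
  equivalently `β²/(β² + se²N)`).

## 4. Position-wise and pairwise nucleotide effects

Windows: donor −3..+7, acceptor −7..+3 (relative, transcribed strand). Per
position and base we report the mean of site-level mean SSE, the site count,
the best/worst base, and the proportion of variance
`(TSS − RSS)/TSS` (0 by convention when TSS = 0). Pairwise interactions
compare the observed mean usage of sites carrying a base pair against the
additive expectation `grand + (m1 − grand) + (m2 − grand)`, capped to [0, 1]
before differencing. Site × position-pair combinations are down-sampled to a
cap (default 2 × 10⁶) with a seeded uniform sample.

Because the interacting cell also feeds the marginal means, a planted
interaction of size δ is measured attenuated by a factor
`1 - f1 - f2 + f1·f2` (the base frequencies at the two positions); the
package reports the raw deviation and the test suite checks recovery against
this attenuated value, not against δ itself.

Outliers on the sorted deviation profile use the elbow construction: both
axes (rank, value) normalised to [0, 1]; for each tail, the line from the
profile midpoint to the extreme is drawn and the point of maximum
perpendicular distance is the elbow; thresholds are the elbow values moved
outward by a conservative buffer of 0.1 (in usage units). The
perpendicular-distance geometry needs a scale decision because the axes have
different units; min–max normalisation of both axes is used. All-equal
deviations yield no outliers.

Promoting/reducing nucleotides are inferred only from associations whose top
SNP lies within 100 bp of the site, each SNP assigned to its single closest
site (ties: donor before acceptor, then lower coordinate — ties are
negligible in practice and the rule exists purely for determinism). The
allele whose carriers splice more is "promoting", judged on genotype-class
means (equivalently the sign of ΔSSE); every association counts equally
rather than weighted by effect size, the simplest defensible reading.
Alleles are complemented onto the transcribed strand of minus-strand sites.
Synthetic 100-bp introns concatenate the donor-side (0..+49) and
acceptor-side (−49..0) profile bases, force GT/AG anchors and a branch-point
adenosine, fill unsupported positions from the per-position mean-usage
best/worst bases and finally from a default base, and accept modifications
(polypyrimidine tract, consensus branch point, top-ranked terminal hexamers).

## 5. Hexamer rankings and the choice-explanation statistic

K-mer keys are intron-anchored: donors `GT` + (k−2) intronic bases, acceptors
(k−2) intronic bases + `AG`; there are `4^(k-2)` possible keys per type. A
key's strength is the mean of site-level mean SSE over the sites carrying it
— sites are averaged across individuals *first*, so sequencing depth does not
weight the key mean. Ranks are descending by strength with deterministic
ties (larger site count, then lexicographic). Keys never observed are absent
from the table, not zero-filled.

The choice-explanation scan asks, per used site with no other used site of
the same type within the window (±100 bp default, ±200 available): among all
GT (donors) or AG (acceptors) occurrences on the transcribed strand in the
window, is the site's own key the unique occurrence of the best-ranked key?
Keys absent from the table rank below all present keys; "unique" means the
best key occurs exactly once among candidates. The raw success rate is then
multiplied by the fraction of possible keys observed
(`adjusted_percent = raw × fraction × 100`). This multiplicative reading of
the adjustment penalises long k-mers whose key spaces are mostly unobserved
while leaving k ≤ 6 nearly untouched, and it is what produces the hexamer
optimum on hexamer-determined data; the raw rate is always reported alongside
so other readings can be inspected. The proximity exclusion is applied per
site type, because the scan competes GT candidates for donors and AG
candidates for acceptors — a nearby used acceptor does not contaminate a
donor window.

Cross-table comparisons use Spearman correlations of shared-key strengths,
reported as R² with the sign kept separately; at least 10 shared keys are
required. p-distance profiles group keys by the fraction of mismatching
positions from a reference (the donor consensus GTAAGT, complementary to the
U1 snRNA binding site, or the strongest acceptor hexamer) and report
per-group mean strengths and their correlation with distance. Occurrence
profiles partition every anchored k-mer occurrence in gene bodies into
used-as-splice-site vs not and correlate each partition's occurrence
proportions with the strength table.

Minigene competing pairs: the winner is the site with higher SSE; a pair is
explained when the winner's hexamer is stronger in the table; ties in either
quantity drop the pair from numerator and denominator. The permutation null
shuffles the strength-to-key assignment (default 10,000 times) and recomputes
the explained fraction overall and per strength-gap bin (default split at
0.25); the null's upper quantile (default 0.99) is the reported threshold,
bit-reproducible under a fixed seed.

## 6. The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes:

* gene models with exons (80–160 bp) and introns (100–250 bp by default) on
  both strands, assembled into chromosomes with random intergenic spacers;
* every intron starts with a donor hexamer and ends with an acceptor hexamer
  drawn from a strength model, so true usage is an exact function of the
  hexamer; sampling is strength-proportional by default (mirroring the
  observed strength–frequency association), uniform on request;
* the default strength model decays with mismatch count from a consensus
  (GTAAGT / TTGCAG) plus substantial per-hexamer jitter
  (`jitter_sd = 0.15`), clamped to [0.02, 0.98]. The jitter is deliberate:
  single-base changes must be able to flip a site from strong to weak, while
  mismatch-group averages still decay smoothly with distance;
* causal SNPs are planted only in the four variable hexamer bases (never the
  GT/AG anchor), in `effect_mode = "max"` choosing the single-base change
  with the largest strength gap — a large-effect splice-site mutation;
  background variants land outside all hexamers with MAF uniform in
  (0.05, 0.5);
* counts: crossing totals are negative-binomial
  (`variance = mu + dispersion·mu²`; dispersion 0.1 by default, 0 gives
  Poisson — the depth distribution of real cohorts is not prescribed
  anywhere, so the dispersion is an honest free parameter), and supporting
  reads are binomial with
  `p = clamp(truth + genotype effect + replicate noise, 0, 1)`. The genotype
  effect is drawn once per site × genotype and shared across replicates;
  this is the sole source of heritability. Noise is additive on the
  probability scale and clamped — the simplest model consistent with a
  bounded phenotype;
* minigene constructs carry two competing donors (40 bp apart by default)
  and split a fixed read depth by a logistic contrast of the true strengths
  (slope 6) with optional logit noise; with zero noise the stronger donor
  wins every construct, with symmetric strengths the split is 50/50.

Default cohort structure: 200 genotypes × 3 replicates at mean depth 50,
`genotype_sd = residual_sd = 0.05`, a fifth of sites carrying a causal SNP
with MAF in [0.1, 0.4]. All stages derive their RNG streams from the single
config seed (fixed offsets per stage), so identical configurations produce
byte-identical FASTA/VCF/BED/TSV output.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium (each variant is drawn
independently, so there are no LD proxies competing with the causal SNP),
population structure and kinship, alignment and mappability artefacts,
exonic/branch-point/polypyrimidine sequence effects beyond the hexamer,
trans-acting variation (available only via explicit `trans_effects` entries),
multi-allelic variants and indels, and any read-level error process.

## 7. Problem sizes and numerical conventions

The validation experiments use sizes chosen to make the statistical targets
sharp while staying comfortably small: causal-SNP recovery uses 200 genotypes
× 3 replicates at depth 50 with 20 planted sites of strength gap ≥ 0.5;
heritability recovery uses 100 genotypes × 4 replicates at depth 150;
the k-scan optimum uses ten independent ~3,000-site transcriptomes; the
ranking-recovery experiment uses ~7,800 donors (≈30 sites per hexamer,
uniform weighting); the permutation calibration uses 2,000 coin-flip pairs ×
10,000 permutations. The brute-force window enumerator used as an oracle is
an independent implementation (per-base loops) and must agree bit-exactly.

Conventions: BED output is 0-based half-open and converted at the I/O
boundary (internal coordinates are 1-based); VCF positions are 1-based;
p-values are floored at the smallest positive double; the
variance-partition statistic returns 0 when TSS = 0; zero-coverage cells are
missing, not zero; all tie-breaks are documented and deterministic. The
pipeline manifest records parameters, seed, package version and input
digests, and enforces one junction dialect per run.

## 8. Known limitations

The OLS engine does not model relatedness beyond eigenvector whitening, so
stratified cohorts will inflate test statistics. The plain-ratio SSE ignores
partner-site structure. The noise-gate and peak parameters are heuristics
tuned for dense panels and should be re-examined for sparse designs. Hexamer
rankings compress splice-sites into 256 groups; they are a comparable,
interpretable feature, not a maximal-accuracy predictor, and condition- or
tissue-specific rankings require condition-specific input data.
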