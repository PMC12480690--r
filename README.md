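# splicehex

Treating the usage of *individual* splice-sites as a quantitative molecular
phenotype: quantification, genetic mapping, and a hexamer-based account of
splice-site choice.

Most splicing quantifications (exon inclusion, intron clusters, isoform
ratios) pool several splice-sites into one number, which blurs the link
between a genetic variant and the specific donor or acceptor it perturbs.
`splicehex` works at single-site resolution throughout. It is aimed at
researchers analysing population-scale RNA-seq panels (replicated inbred
cohorts such as plant accession panels or fly reference lines, or unreplicated
human cohorts) who want to map genetic variation in splice-site usage and to
understand how the intron-terminal sequence drives splice-site choice.

## The quantities at the core

**Splice-site strength estimate (SSE).** For a splice-site *s* in one sample,

    SSE(s) = alpha / (alpha + beta)

where `alpha` counts junction reads spliced at *s* and `beta` counts reads
crossing the position of *s* without being spliced there. SSE is in [0, 1]
and is undefined (missing, never 0/0) where no read crosses the site.
Sites are filtered for coverage (by default >= 10 crossing reads in >= 3
replicates of >= 100 genotypes), averaged within genotype, and summarised per
site by the range and variance of usage across genotypes.

**Broad-sense heritability.** With replicated genotypes, a one-way ANOVA with
genotype as the factor gives H² = σg² / (σg² + σe²), where
σg² = (MS_between − MS_within)/r̄ with r̄ the harmonic-mean replicate count,
clamped to [0, 1]. Sites in the top quartile of both variance and H² (top
quartile of variance alone for unreplicated cohorts) are carried into
association mapping.

**Per-site association mapping.** Each selected site's genotype-mean SSE is
regressed on every variant with MAF >= 0.05 (OLS slope t-test, optionally
pre-whitened against leading kinship eigenvectors). Significant variants are
merged into peaks; a peak needs a minimum SNP count and must clear a noise
gate: −log10(p) of its top SNP >= 1.33 × the mean −log10(p) of the five
lowest-p variants genome-wide, no two within 750 kb. Top-SNP distances are
normalised to the splice-site (position 0 = the intron-terminal G of the
donor GT or acceptor AG, strand-aware), classified **cis** within 1 Mb on the
same chromosome and **trans** otherwise, and annotated with ΔSSE (mean minor-
minus major-allele usage) and PVE = β² / (β² + se²·N).

**Hexamer rankings and splice-site choice.** Splice-sites are grouped by
their intron-terminal hexamer — GT[N]₄ for donors, [N]₄AG for acceptors
(256 possible keys each) — and each hexamer is scored by the mean usage of
the sites carrying it, then ranked. The *choice-explanation* statistic asks:
for what fraction of used sites is the site's own k-mer the unique
best-ranked one among all GT/AG occurrences within ±100 bp on the transcribed
strand? The raw rate is adjusted by the fraction of the 4^(k−2) possible
k-mers actually observed, which penalises long k-mers with sparse tables;
on hexamer-determined data the adjusted statistic peaks at k = 6.
Competing donor pairs in minigene libraries are scored the same way (does the
higher-usage site carry the stronger hexamer?) against a 10,000-permutation
null that shuffles the strength-to-hexamer assignment.

A synthetic-data generator (`generateGenome`, `simulateGenotypes`,
`simulateJunctionCounts`, `simulateMinigeneLibrary`) produces genomes whose
site usage is an exact function of the planted hexamers, with causal SNPs
inside splice-site hexamers, genotype-level variance driving heritability,
and negative-binomial sequencing depth — so every stage of the pipeline can
be validated against known truth.

## Worked example

```r
library(splicehex)

cfg   <- synthConfig(n_genes = 40, introns_per_gene = 2, n_genotypes = 150,
                     replicates_per_genotype = 3, read_depth_mean = 50,
                     causal_fraction = 0.25, seed = 1)
model <- defaultStrengthModel(1)
synth <- generateGenome(cfg, model)
geno  <- simulateGenotypes(cfg, synth, model)
sse   <- simulateJunctionCounts(trueSSETable(synth, geno, model), cfg,
                                synth$sites)
sse
#> SSEExperiment: 160 splice-sites ( 80 donors, 80 acceptors ) x 450 samples
#>   genotypes: 150  assays: alpha, beta
#>   median crossing depth: 48 ; zero-coverage cells: 0

kept <- filterSites(sse, min_reads = 10, min_replicates = 3,
                    min_genotypes = 100)
gm   <- genotypeAverage(kept, min_reads = 10, min_pass = 2)
summ <- siteSummaries(kept)
mappable <- selectMappableSites(summ, "replicated")  # 39 of 160 sites

ta <- topAssociations(gm[mappable, , drop = FALSE], synth$sites,
                      geno$dosages, geno$variants, min_peak_snps = 1)
head(ta[, c("site_id", "top_snp", "p_value", "relative_distance",
            "cis_trans", "delta_sse", "pve")], 3)
#>   site_id top_snp  p_value relative_distance cis_trans delta_sse   pve
#> 1  s00003  v00005 2.29e-57                 4       cis    -0.389 0.820
#> 2  s00006  v00008 3.26e-80                 4       cis     0.385 0.912
#> 3  s00008  v00013 3.18e-65                 3       cis     0.438 0.859
```

Every recovered top SNP here is the planted hexamer SNP of its site (hence
relative distances of +3/+4, inside the donor hexamer), all classified cis.
ΔSSE is the usage change carried by the minor allele and PVE the fraction of
the phenotype's variance the SNP explains.

```r
strength <- rowMeans(gm, na.rm = TRUE)
tab <- strengthTable(synth$sites, synth$genome, strength, k = 6,
                     site_type = "donor")
head(tab, 3)
#>      key n_sites mean_sse rank
#> 1 GTAAAT       1    0.948    1
#> 2 GTAAGT       3    0.913    2
#> 3 GTAGGT       3    0.780    3

choiceExplained(synth$genome, synth$sites, tab, k = 6, site_type = "donor",
                window = 100)[c("raw_rate", "adjusted_percent")]
#> raw 0.388, adjusted 9.4% (80 sites tested)
```

With only 80 donors, most of the 256 hexamers are unobserved, so the
adjustment is severe; on transcriptome-scale synthetic data (thousands of
sites) the adjusted percentage peaks at k = 6, and the ranking recovers the
planted strength map with Spearman ρ > 0.99 (see the methods vignette and
`scripts/acceptance.R`).

`runPipeline(pipelineConfig(out_dir, cfg))` chains all stages and writes the
TSV outputs plus a JSON run manifest.

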