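## Small in-code fixtures shared across test files.

mkGenome <- function(...) {
  g <- Biostrings::DNAStringSet(unlist(list(...)))
  g
}

mkSites <- function(chrom, position, strand, site_type,
                    gene_id = "geneX", site_id = NULL) {
  n <- length(position)
  if (is.null(site_id)) site_id <- sprintf("s%03d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = position, width = 1L),
    strand = rep_len(strand, n),
    site_id = site_id, site_type = rep_len(site_type, n),
    gene_id = rep_len(gene_id, n))
  names(gr) <- site_id
  gr
}

## SSEExperiment with exact SSE values: alpha = value * total
sseFixture <- function(values, total, genotype, replicate, sites = NULL) {
  values <- as.matrix(values)
  alpha <- round(values * total)
  beta <- total - alpha
  if (is.null(sites)) {
    sites <- mkSites("chr1", seq(100, by = 500, length.out = nrow(values)),
                     "+", "donor",
                     site_id = sprintf("s%03d", seq_len(nrow(values))))
  }
  SSEExperiment(alpha, beta, sites, genotype = genotype,
                replicate = replicate)
}

## shared moderate synthetic dataset, generated once per test run
synthSmall <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthConfig(n_genes = 30, introns_per_gene = 2,
                         n_genotypes = 120, replicates_per_genotype = 3,
                         read_depth_mean = 50, causal_fraction = 0.3,
                         seed = 42)
      model <- defaultStrengthModel(42)
      synth <- generateGenome(cfg, model)
      geno <- simulateGenotypes(cfg, synth, model)
      truth <- trueSSETable(synth, geno, model)
      sse <- simulateJunctionCounts(truth, cfg, synth$sites)
      cache <<- list(cfg = cfg, model = model, synth = synth, geno = geno,
                     truth = truth, sse = sse)
    }
    cache
  }
})
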