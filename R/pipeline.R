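#' End-to-end pipeline configuration
#'
#' Bundles the generator configuration with stage parameters and the output
#' directory. Parameters mirror the module defaults; any can be overridden.
#'
#' @param out_dir output directory.
#' @param config a \linkS4class{SynthConfig}.
#' @param min_reads,min_replicates,min_genotypes coverage filter.
#' @param min_pass replicates required for a genotype mean.
#' @param maf_min,min_peak_snps,merge_window,noise_factor,spread_window
#'   association-stage parameters.
#' @param k_values k-mer lengths scanned in the hexamer stage.
#' @param window choice-explanation scan half-width.
#' @param n_perm,n_constructs minigene stage sizes.
#' @param stages character subset of c("simulate", "sse", "gwas", "seqfx",
#'   "hexrank", "minigene"); upstream stages must precede downstream ones.
#' @return a classed list.
#' @export
pipelineConfig <- function(out_dir, config = synthConfig(),
                           min_reads = 10, min_replicates = 3,
                           min_genotypes = 100, min_pass = 2,
                           maf_min = 0.05, min_peak_snps = 1,
                           merge_window = 1e5, noise_factor = 1.33,
                           spread_window = 750000,
                           k_values = c(4L, 6L, 8L), window = 100,
                           n_perm = 1000, n_constructs = 300,
                           stages = c("simulate", "sse", "gwas", "seqfx",
                                      "hexrank", "minigene")) {
  structure(list(out_dir = out_dir, config = config, min_reads = min_reads,
                 min_replicates = min_replicates,
                 min_genotypes = min_genotypes, min_pass = min_pass,
                 maf_min = maf_min, min_peak_snps = min_peak_snps,
                 merge_window = merge_window, noise_factor = noise_factor,
                 spread_window = spread_window, k_values = k_values,
                 window = window, n_perm = n_perm,
                 n_constructs = n_constructs, stages = stages),
            class = "splicehex_pipeline_config")
}

#' Run the full synthetic-to-analysis pipeline
#'
#' Executes the configured stages in dependency order: synthetic-data
#' generation, usage quantification and site selection, per-site association
#' mapping, sequence-effect analysis, hexamer ranking/choice explanation and
#' the minigene competing-pair analysis. All tables are written as TSV under
#' \code{out_dir}; a machine-readable JSON manifest records the parameters,
#' seed, package version and input digests. Any stage failure raises a
#' stage-tagged error.
#'
#' @param pc a \code{\link{pipelineConfig}}.
#' @return invisible list of in-memory stage results plus the manifest.
#' @export
runPipeline <- function(pc) {
  stopifnot2(inherits(pc, "splicehex_pipeline_config"),
             "pc must come from pipelineConfig()")
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    if (!name %in% pc$stages) return(NULL)
    message("[", name, "] running")
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  need <- function(what, from) {
    if (is.null(res[[what]])) {
      stop(sprintf("stage '%s' requires missing upstream output '%s'",
                   from, what), call. = FALSE)
    }
  }

  stage("simulate", {
    model <- defaultStrengthModel(seed = pc$config@seed)
    synth <- generateGenome(pc$config, model)
    geno <- simulateGenotypes(pc$config, synth, model)
    truth <- trueSSETable(synth, geno, model)
    sse <- simulateJunctionCounts(truth, pc$config, synth$sites)
    writeSynthBundle(synth, geno, sse, file.path(pc$out_dir, "synth"))
    res$model <- model; res$synth <- synth; res$geno <- geno
    res$truth <- truth; res$sse <- sse
  })

  stage("sse", {
    need("sse", "sse")
    filt <- filterSites(res$sse, pc$min_reads, pc$min_replicates,
                        pc$min_genotypes)
    gm <- genotypeAverage(filt, pc$min_reads, pc$min_pass)
    summ <- siteSummaries(filt, pc$min_reads, pc$min_pass)
    mappable <- selectMappableSites(summ, "replicated")
    writeTableChecked(cbind(site_id = rownames(gm), as.data.frame(gm)),
                      file.path(pc$out_dir, "sse_genotype_means.tsv"))
    writeTableChecked(summ, file.path(pc$out_dir, "site_summaries.tsv"))
    res$filtered <- filt; res$geno_means <- gm; res$summaries <- summ
    res$mappable <- mappable
  })

  stage("gwas", {
    need("geno_means", "gwas")
    ids <- intersect(res$mappable, rownames(res$geno_means))
    ta <- topAssociations(res$geno_means[ids, , drop = FALSE],
                          res$synth$sites, res$geno$dosages,
                          res$geno$variants, maf_min = pc$maf_min,
                          min_peak_snps = pc$min_peak_snps,
                          merge_window = pc$merge_window,
                          noise_factor = pc$noise_factor,
                          spread_window = pc$spread_window)
    writeTableChecked(ta, file.path(pc$out_dir, "top_associations.tsv"))
    res$top_assoc <- ta
  })

  stage("seqfx", {
    need("geno_means", "seqfx")
    strength <- rowMeans(res$geno_means, na.rm = TRUE)
    pm <- positionNucleotideMeans(res$synth$sites, res$synth$genome, strength)
    for (type in names(pm)) {
      writeTableChecked(pm[[type]]$stats,
                        file.path(pc$out_dir,
                                  paste0("position_means_", type, ".tsv")))
    }
    inter <- pairwiseInteractions(pm$donor$base_matrix,
                                  pm$donor$site_strength,
                                  seed = pc$config@seed)
    eo <- elbowOutliers(inter$deviation)
    inter$outlier <- eo$outlier
    writeTableChecked(inter, file.path(pc$out_dir, "interactions_donor.tsv"))
    prom <- if (!is.null(res$top_assoc) && nrow(res$top_assoc) > 0) {
      inferPromotingNucleotides(res$top_assoc, res$geno$variants,
                                res$geno$dosages)
    } else list(profile = data.frame(), details = data.frame())
    if (nrow(prom$profile) > 0) {
      writeTableChecked(prom$profile,
                        file.path(pc$out_dir, "promoting_profile.tsv"))
    }
    introns <- c(best = buildSyntheticIntron(prom$profile, "best", pm),
                 worst = buildSyntheticIntron(prom$profile, "worst", pm))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(introns),
                                file.path(pc$out_dir,
                                          "synthetic_introns.fa"))
    res$position_means <- pm; res$interactions <- inter
    res$promoting <- prom; res$synthetic_introns <- introns
  })

  stage("hexrank", {
    need("geno_means", "hexrank")
    strength <- rowMeans(res$geno_means, na.rm = TRUE)
    tabs <- list()
    choice <- list()
    for (type in c("donor", "acceptor")) {
      tabs[[type]] <- strengthTable(res$synth$sites, res$synth$genome,
                                    strength, k = 6, site_type = type)
      writeTableChecked(tabs[[type]],
                        file.path(pc$out_dir,
                                  paste0("strength_table_", type, ".tsv")))
    }
    for (k in pc$k_values) {
      tk <- strengthTable(res$synth$sites, res$synth$genome, strength,
                          k = k, site_type = "donor")
      ce <- choiceExplained(res$synth$genome, res$synth$sites, tk, k = k,
                            site_type = "donor", window = pc$window)
      choice[[as.character(k)]] <- ce[c("k", "window", "n_sites_tested",
                                        "n_success", "raw_rate",
                                        "possible_fraction",
                                        "adjusted_percent")]
    }
    ch <- do.call(rbind, lapply(choice, as.data.frame))
    writeTableChecked(ch, file.path(pc$out_dir, "choice_explained.tsv"))
    res$strength_tables <- tabs; res$choice <- ch
  })

  stage("minigene", {
    need("strength_tables", "minigene")
    lib <- simulateMinigeneLibrary(res$model,
                                   n_constructs = pc$n_constructs,
                                   seed = pc$config@seed + 3L)
    cp <- competingPairAnalysis(lib$pairs, res$strength_tables$donor,
                                n_perm = pc$n_perm,
                                seed = pc$config@seed + 4L)
    writeTableChecked(lib$pairs, file.path(pc$out_dir,
                                           "minigene_pairs.tsv"))
    writeTableChecked(cp$by_gap, file.path(pc$out_dir,
                                           "minigene_explained.tsv"))
    res$minigene <- list(library = lib, analysis = cp)
  })

  manifest <- list(
    package = "splicehex",
    version = as.character(utils::packageVersion("splicehex")),
    seed = pc$config@seed,
    stages = pc$stages,
    parameters = pc[setdiff(names(pc), c("out_dir", "config"))],
    generator = list(n_genes = pc$config@n_genes,
                     introns_per_gene = pc$config@introns_per_gene,
                     n_genotypes = pc$config@n_genotypes,
                     replicates_per_genotype =
                       pc$config@replicates_per_genotype,
                     read_depth_mean = pc$config@read_depth_mean,
                     genotype_sd = pc$config@genotype_sd,
                     residual_sd = pc$config@residual_sd,
                     causal_fraction = pc$config@causal_fraction),
    input_digests = as.list(tools::md5sum(
      list.files(file.path(pc$out_dir, "synth"), full.names = TRUE,
                 recursive = TRUE, pattern = "\\.(fa|vcf|tsv)$"))))
  jsonlite::write_json(manifest, file.path(pc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
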