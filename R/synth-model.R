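#' Enumerate all possible intron-anchored k-mer keys
#'
#' Donor keys are "GT" followed by k-2 intronic bases; acceptor keys are k-2
#' intronic bases followed by "AG". There are 4^(k-2) possible keys per site
#' type: 16 tetramers, 256 hexamers, 4096 octamers.
#'
#' @param site_type "donor" or "acceptor".
#' @param k k-mer length, 2..8.
#' @return character vector of all 4^(k-2) keys, sorted.
#' @export
possibleKeys <- function(site_type = c("donor", "acceptor"), k = 6) {
  site_type <- match.arg(site_type)
  stopifnot2(k >= 2 && k <= 8, "k must be in [2, 8]")
  if (k == 2) return(if (site_type == "donor") "GT" else "AG")
  inner <- do.call(expand.grid,
                   c(rep(list(DNA_BASES), k - 2),
                     list(stringsAsFactors = FALSE)))
  inner <- apply(inner[, rev(seq_len(k - 2)), drop = FALSE], 1, paste,
                 collapse = "")
  sort(if (site_type == "donor") paste0("GT", inner) else paste0(inner, "AG"))
}

#' TrueStrengthModel: ground-truth hexamer strengths for simulation
#'
#' Maps each of the 256 donor (GT[N]4) and 256 acceptor ([N]4AG) hexamers to a
#' base usage strength in [0, 1]. Optionally carries trans effects: named list
#' entries with a multiplicative \code{effect} applied to \code{site_ids} in
#' carriers of a given variant.
#'
#' @aliases TrueStrengthModel-class
#' @exportClass TrueStrengthModel
setClass("TrueStrengthModel",
         representation(donor_map = "numeric", acceptor_map = "numeric",
                        trans_effects = "list"))

setValidity("TrueStrengthModel", function(object) {
  for (nm in c("donor_map", "acceptor_map")) {
    m <- methods::slot(object, nm)
    keys <- possibleKeys(if (nm == "donor_map") "donor" else "acceptor", 6)
    if (length(m) != 256 || !setequal(names(m), keys)) {
      return(sprintf("%s must map exactly the 256 possible hexamers", nm))
    }
    if (any(m < 0 | m > 1)) return(sprintf("%s strengths must be in [0,1]", nm))
  }
  TRUE
})

#' @describeIn TrueStrengthModel constructor
#' @param donor_map,acceptor_map named numeric vectors over all 256 hexamers.
#' @param trans_effects optional list of lists with elements
#'   \code{variant_id}, \code{effect}, \code{site_ids}.
#' @export
trueStrengthModel <- function(donor_map, acceptor_map, trans_effects = list()) {
  methods::new("TrueStrengthModel",
               donor_map = donor_map[sort(names(donor_map))],
               acceptor_map = acceptor_map[sort(names(acceptor_map))],
               trans_effects = trans_effects)
}

setMethod("show", "TrueStrengthModel", function(object) {
  cat("TrueStrengthModel: 256 donor + 256 acceptor hexamer strengths\n")
  cat(sprintf("  donor strengths    [%.3f, %.3f], strongest %s\n",
              min(object@donor_map), max(object@donor_map),
              names(which.max(object@donor_map))))
  cat(sprintf("  acceptor strengths [%.3f, %.3f], strongest %s\n",
              min(object@acceptor_map), max(object@acceptor_map),
              names(which.max(object@acceptor_map))))
  if (length(object@trans_effects)) {
    cat("  trans effects:", length(object@trans_effects), "\n")
  }
  invisible(NULL)
})

#' @describeIn TrueStrengthModel strength map for one site type
#' @param model a TrueStrengthModel
#' @param site_type "donor" or "acceptor"
#' @export
strengthMap <- function(model, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (site_type == "donor") model@donor_map else model@acceptor_map
}

#' Default ground-truth strength model
#'
#' Base strengths decay with the number of mismatches of the variable
#' tetramer from a consensus (GTAAGT for donors, mirroring U1 snRNA
#' base-pairing; TTGCAG for acceptors), plus seeded jitter, clamped to
#' [0.02, 0.98]. This plants a negative p-distance/strength correlation and a
#' wide spread of per-hexamer strengths, the two structural features the
#' downstream analyses are designed to recover.
#'
#' The jitter is deliberately substantial: within a mismatch group, real
#' hexamers span a wide strength range (single-base changes can flip a site
#' from strong to weak), while the group averages still decay with distance.
#'
#' @param seed integer seed for the jitter.
#' @param jitter_sd standard deviation of the per-hexamer jitter.
#' @return A \linkS4class{TrueStrengthModel}.
#' @export
defaultStrengthModel <- function(seed = 1L, jitter_sd = 0.15) {
  set.seed(seed)
  mk <- function(type, ref) {
    keys <- possibleKeys(type, 6)
    mism <- vapply(keys, function(k) {
      sum(strsplit(k, "")[[1]] != strsplit(ref, "")[[1]])
    }, integer(1))
    s <- 0.95 - 0.9 * mism / 4 + stats::rnorm(length(keys), 0, jitter_sd)
    stats::setNames(pmin(0.98, pmax(0.02, s)), keys)
  }
  trueStrengthModel(mk("donor", "GTAAGT"), mk("acceptor", "TTGCAG"))
}

#' SynthConfig: parameters of the synthetic-data generator
#'
#' Holds the cohort and noise structure the generator emulates: a replicated
#' inbred panel with genotype-level usage variance (driving heritability),
#' causal SNPs planted inside splice-site hexamers, and negative-binomial
#' sequencing depth.
#'
#' @aliases SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
         representation(n_genes = "integer", introns_per_gene = "integer",
                        intron_length_range = "integer",
                        n_genotypes = "integer",
                        replicates_per_genotype = "integer",
                        read_depth_mean = "numeric",
                        depth_dispersion = "numeric",
                        genotype_sd = "numeric", residual_sd = "numeric",
                        causal_fraction = "numeric",
                        causal_maf_range = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@n_genes < 1 || object@introns_per_gene < 1 ||
      object@n_genotypes < 1 || object@replicates_per_genotype < 1) {
    return("all counts must be >= 1")
  }
  if (object@genotype_sd < 0 || object@residual_sd < 0 ||
      object@depth_dispersion < 0) {
    return("sd and dispersion values must be >= 0")
  }
  if (object@causal_fraction < 0 || object@causal_fraction > 1) {
    return("causal_fraction must be in [0, 1]")
  }
  if (length(object@intron_length_range) != 2 ||
      object@intron_length_range[1] > object@intron_length_range[2]) {
    return("intron_length_range must be an increasing pair")
  }
  ## two hexamers plus interior clearance must fit in every intron
  if (object@intron_length_range[1] < 20) {
    return("introns shorter than 20 bp cannot hold both terminal hexamers")
  }
  if (length(object@causal_maf_range) != 2 ||
      any(object@causal_maf_range <= 0) || any(object@causal_maf_range > 0.5) ||
      object@causal_maf_range[1] > object@causal_maf_range[2]) {
    return("causal_maf_range must be an increasing pair in (0, 0.5]")
  }
  TRUE
})

#' @describeIn SynthConfig constructor. Defaults describe a replicated inbred
#'   panel of 200 genotypes with 3 replicates, ~50x crossing depth, moderate
#'   genotype-level variance, and a fifth of sites carrying a hexamer SNP.
#' @param n_genes,introns_per_gene gene-model counts.
#' @param intron_length_range min/max intron length (bp).
#' @param n_genotypes,replicates_per_genotype cohort structure.
#' @param read_depth_mean mean crossing-read depth per site/sample.
#' @param depth_dispersion negative-binomial dispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson depth.
#' @param genotype_sd,residual_sd between-genotype and between-replicate
#'   standard deviations of usage, on the SSE (probability) scale.
#' @param causal_fraction fraction of sites given a strength-altering hexamer
#'   SNP.
#' @param causal_maf_range minor-allele-frequency range of causal SNPs.
#' @param seed master seed; each generator stage derives its own stream.
#' @export
synthConfig <- function(n_genes = 50L, introns_per_gene = 2L,
                        intron_length_range = c(100L, 250L),
                        n_genotypes = 200L, replicates_per_genotype = 3L,
                        read_depth_mean = 50, depth_dispersion = 0.1,
                        genotype_sd = 0.05, residual_sd = 0.05,
                        causal_fraction = 0.2,
                        causal_maf_range = c(0.1, 0.4), seed = 1L) {
  methods::new("SynthConfig",
               n_genes = as.integer(n_genes),
               introns_per_gene = as.integer(introns_per_gene),
               intron_length_range = as.integer(intron_length_range),
               n_genotypes = as.integer(n_genotypes),
               replicates_per_genotype = as.integer(replicates_per_genotype),
               read_depth_mean = read_depth_mean,
               depth_dispersion = depth_dispersion,
               genotype_sd = genotype_sd, residual_sd = residual_sd,
               causal_fraction = causal_fraction,
               causal_maf_range = as.numeric(causal_maf_range),
               seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d genes x %d introns; %d genotypes x %d replicates\n",
    object@n_genes, object@introns_per_gene, object@n_genotypes,
    object@replicates_per_genotype))
  cat(sprintf("  depth NB(mu=%g, disp=%g); genotype_sd=%g residual_sd=%g\n",
              object@read_depth_mean, object@depth_dispersion,
              object@genotype_sd, object@residual_sd))
  cat(sprintf("  causal fraction %g, MAF in [%g, %g], seed %d\n",
              object@causal_fraction, object@causal_maf_range[1],
              object@causal_maf_range[2], object@seed))
  invisible(NULL)
})
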