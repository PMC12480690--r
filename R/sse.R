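#' Coverage filtering of splice-sites
#'
#' A site is retained when the number of genotypes having at least
#' \code{min_replicates} replicates, each with at least \code{min_reads} reads
#' crossing the site, reaches \code{min_genotypes}. The defaults match a
#' replicated population panel; cohorts without replicates should use
#' \code{min_replicates = 1}.
#'
#' @param x an \linkS4class{SSEExperiment}.
#' @param min_reads minimum crossing reads per replicate.
#' @param min_replicates minimum passing replicates per genotype.
#' @param min_genotypes minimum genotypes passing the replicate rule.
#' @return the subsetted \linkS4class{SSEExperiment}; the logical keep vector
#'   is stored in \code{metadata(x)$site_filter}.
#' @export
filterSites <- function(x, min_reads = 10, min_replicates = 3,
                        min_genotypes = 100) {
  tot <- crossingTotals(x)
  pass <- tot >= min_reads
  geno <- genotypeIds(x)
  reps_pass <- t(rowsum(t(pass * 1L), group = geno))  # sites x genotypes
  n_geno_ok <- rowSums(reps_pass >= min_replicates)
  keep <- n_geno_ok >= min_genotypes
  out <- x[keep, ]
  S4Vectors::metadata(out)$site_filter <-
    list(keep = keep, min_reads = min_reads, min_replicates = min_replicates,
         min_genotypes = min_genotypes)
  out
}

#' Average SSE within genotype
#'
#' Per site and genotype, the mean SSE over replicates whose crossing total
#' reaches \code{min_reads}; the genotype is set missing when fewer than
#' \code{min_pass} replicates pass (use \code{min_pass = 1} for cohorts
#' without replication). When \code{stratify} names a colData column (e.g.
#' sex), a separate matrix is returned per stratum.
#'
#' @param x an \linkS4class{SSEExperiment}.
#' @param min_reads coverage threshold per replicate.
#' @param min_pass minimum passing replicates for a genotype mean.
#' @param stratify optional colData column name to average within.
#' @return sites x genotypes numeric matrix (or a named list of matrices, one
#'   per stratum).
#' @export
genotypeAverage <- function(x, min_reads = 10, min_pass = 2,
                            stratify = NULL) {
  if (!is.null(stratify)) {
    strata <- SummarizedExperiment::colData(x)[[stratify]]
    return(lapply(split(seq_len(ncol(x)), strata), function(j) {
      genotypeAverage(x[, j], min_reads = min_reads, min_pass = min_pass)
    }))
  }
  sse <- sseValues(x)
  ok <- crossingTotals(x) >= min_reads & !is.na(sse)
  sse[!ok] <- 0
  geno <- genotypeIds(x)
  sums <- t(rowsum(t(sse), group = geno))
  n <- t(rowsum(t(ok * 1L), group = geno))
  m <- sums / n
  m[n < min_pass] <- NA_real_
  m
}

#' Per-site variability of genotype-level usage
#'
#' @param geno_means sites x genotypes matrix from
#'   \code{\link{genotypeAverage}}.
#' @return data.frame with site_id, n_obs (genotypes with data), range
#'   (max - min SSE) and variance (sample variance across genotypes); sites
#'   with fewer than 2 observations get NA.
#' @export
variabilityMetrics <- function(geno_means) {
  n_obs <- rowSums(!is.na(geno_means))
  rng <- apply(geno_means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else max(v) - min(v)
  })
  va <- apply(geno_means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::var(v)
  })
  data.frame(site_id = rownames(geno_means), n_obs = n_obs, range = rng,
             variance = va, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin sites by usage range and summarise variance per bin
#'
#' Groups sites into bins of width 0.1 on the range of genotype-level usage
#' and reports the number of sites and mean variance per bin, the summary
#' behind range-distribution figures.
#'
#' @param metrics output of \code{\link{variabilityMetrics}}.
#' @return data.frame with bin label, bin midpoint, n_sites, mean_variance,
#'   and the fraction of all scored sites in the bin.
#' @export
rangeBins <- function(metrics) {
  ok <- !is.na(metrics$range)
  b <- cut(metrics$range[ok], breaks = seq(0, 1, by = 0.1),
           include.lowest = TRUE)
  mv <- tapply(metrics$variance[ok], b, mean)
  n <- as.vector(table(b))
  data.frame(bin = levels(b),
             midpoint = seq(0.05, 0.95, by = 0.1),
             n_sites = n,
             mean_variance = as.vector(mv),
             fraction = n / sum(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Broad-sense heritability of splice-site usage
#'
#' One-way ANOVA of replicate-level SSE with genotype as the factor, per
#' site. The between-genotype variance component is
#' (MS_between - MS_within) / r, with r the harmonic-mean replicate count;
#' H^2 = sigma_g^2 / (sigma_g^2 + MS_within), clamped to [0, 1]. Sites without
#' at least 2 genotypes having at least 2 passing replicates return NA
#' (cohorts without replication fall back to variance-only site selection).
#'
#' @param x an \linkS4class{SSEExperiment}.
#' @param min_reads coverage threshold for a replicate to enter the ANOVA.
#' @return data.frame with site_id, h2, n_genotypes, r_harmonic.
#' @export
broadSenseHeritability <- function(x, min_reads = 10) {
  sse <- sseValues(x)
  ok <- crossingTotals(x) >= min_reads & !is.na(sse)
  geno <- genotypeIds(x)
  h2 <- rep(NA_real_, nrow(sse))
  ngv <- integer(nrow(sse)); rh <- rep(NA_real_, nrow(sse))
  for (i in seq_len(nrow(sse))) {
    y <- sse[i, ok[i, ]]
    g <- geno[ok[i, ]]
    reps <- table(g)
    g_use <- names(reps)[reps >= 2]
    ngv[i] <- length(g_use)
    if (length(g_use) < 2) next
    sel <- g %in% g_use
    y <- y[sel]; g <- factor(g[sel])
    if (stats::var(y) == 0) { h2[i] <- 0; rh[i] <- harmonicMean(table(g)); next }
    ## the F-test itself is unused (only the mean squares are), so the
    ## perfect-fit warning is irrelevant here
    av <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
    ms_b <- av$`Mean Sq`[1]; ms_w <- av$`Mean Sq`[2]
    r <- harmonicMean(as.vector(table(g)))
    sg2 <- (ms_b - ms_w) / r
    h2[i] <- clamp01(sg2 / (sg2 + ms_w))
    if (ms_w == 0) h2[i] <- 1
    rh[i] <- r
  }
  data.frame(site_id = rownames(sse), h2 = h2, n_genotypes = ngv,
             r_harmonic = rh, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-site summaries (range, variance, heritability)
#'
#' Convenience wrapper combining \code{\link{genotypeAverage}},
#' \code{\link{variabilityMetrics}} and \code{\link{broadSenseHeritability}}.
#'
#' @param x an \linkS4class{SSEExperiment}.
#' @param min_reads,min_pass forwarded to the component functions.
#' @return data.frame with site_id, n_obs, range, variance, h2, n_genotypes,
#'   r_harmonic.
#' @export
siteSummaries <- function(x, min_reads = 10, min_pass = 2) {
  gm <- genotypeAverage(x, min_reads = min_reads, min_pass = min_pass)
  vm <- variabilityMetrics(gm)
  h <- broadSenseHeritability(x, min_reads = min_reads)
  merge(vm, h, by = "site_id", sort = FALSE)
}

#' Select sites for association mapping
#'
#' Replicated cohorts: the intersection of the top quartile of variance and
#' the top quartile of heritability, with at least \code{min_obs} genotypes
#' observed. Cohorts without replication ("variance" mode): the top quartile
#' of variance alone with at least \code{min_obs} observations.
#'
#' @param summaries output of \code{\link{siteSummaries}}.
#' @param mode "replicated" or "variance".
#' @param min_obs minimum genotypes with data.
#' @return character vector of selected site ids.
#' @export
selectMappableSites <- function(summaries, mode = c("replicated", "variance"),
                                min_obs = 100) {
  mode <- match.arg(mode)
  qv <- stats::quantile(summaries$variance, 0.75, na.rm = TRUE, names = FALSE)
  keep <- !is.na(summaries$variance) & summaries$variance >= qv &
    summaries$n_obs >= min_obs
  if (mode == "replicated") {
    qh <- stats::quantile(summaries$h2, 0.75, na.rm = TRUE, names = FALSE)
    keep <- keep & !is.na(summaries$h2) & summaries$h2 >= qh
  }
  summaries$site_id[keep]
}
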