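#' Per-variant association of one site's usage phenotype
#'
#' Simple linear-model association engine: for every variant passing the
#' minor-allele-frequency filter, fits SSE ~ dosage by ordinary least squares
#' and reports the slope, its standard error and the two-sided p-value from
#' the slope t-test. When a kinship matrix is supplied, both phenotype and
#' dosages are first residualised against its leading eigenvectors
#' (a documented lightweight stand-in for a full mixed model).
#'
#' @param phenotype named numeric vector of per-genotype SSE (names =
#'   genotype ids; NAs allowed).
#' @param dosages variants x genotypes matrix (0/1 inbred or 0/1/2 diploid).
#' @param variants data.frame with at least variant_id, chrom, pos (rows
#'   matching \code{dosages}).
#' @param maf_min minimum minor allele frequency (variants with MAF >= 0.05
#'   are kept by default).
#' @param min_n minimum individuals with both phenotype and genotype.
#' @param kinship optional genotypes x genotypes relatedness matrix.
#' @param n_pc number of kinship eigenvectors to residualise against.
#' @return data.frame with variant_id, chrom, pos, maf, n, beta, se, p_value.
#'   Zero phenotypic variance yields an empty set with a warning; constant
#'   dosages are skipped.
#' @export
associateSite <- function(phenotype, dosages, variants, maf_min = 0.05,
                          min_n = 20, kinship = NULL, n_pc = 5) {
  ids <- intersect(names(phenotype)[!is.na(phenotype)], colnames(dosages))
  y <- phenotype[ids]
  D <- dosages[, ids, drop = FALSE]
  empty <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), maf = numeric(0), n = integer(0),
                      beta = numeric(0), se = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (length(y) < min_n) return(empty)
  if (stats::var(y) == 0) {
    warning("phenotype has zero variance; no associations computed")
    return(empty)
  }
  if (!is.null(kinship)) {
    K <- kinship[ids, ids]
    U <- eigen(K, symmetric = TRUE)$vectors[, seq_len(min(n_pc, length(ids))),
                                            drop = FALSE]
    proj <- function(v) v - U %*% crossprod(U, v)
    y <- drop(proj(y))
    D <- t(apply(D, 1, function(d) drop(proj(d))))
    names(y) <- ids
  }
  ploidy <- max(1, max(dosages, na.rm = TRUE))
  out <- vector("list", nrow(D))
  for (j in seq_len(nrow(D))) {
    d <- D[j, ]
    ok <- !is.na(d)
    n <- sum(ok)
    if (n < min_n) next
    dj <- d[ok]; yj <- y[ok]
    f <- mean(dosages[j, ids][ok]) / ploidy
    maf <- min(f, 1 - f)
    if (maf < maf_min) next
    sxx <- sum((dj - mean(dj))^2)
    if (sxx == 0) next
    sxy <- sum((dj - mean(dj)) * (yj - mean(yj)))
    syy <- sum((yj - mean(yj))^2)
    beta <- sxy / sxx
    rss <- syy - beta * sxy
    s2 <- max(rss, 0) / (n - 2)
    se <- sqrt(s2 / sxx)
    p <- if (se == 0) .Machine$double.xmin else
      2 * stats::pt(-abs(beta / se), df = n - 2)
    p <- max(p, .Machine$double.xmin)  # never exactly 0
    out[[j]] <- data.frame(variant_id = variants$variant_id[j],
                           chrom = variants$chrom[j], pos = variants$pos[j],
                           maf = maf, n = n, beta = beta, se = se,
                           p_value = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Call association peaks from a per-site Manhattan profile
#'
#' Significant variants (p <= \code{sig_threshold}) are grouped into peaks by
#' merging neighbours within \code{merge_window} on the same chromosome;
#' peaks with fewer than \code{min_peak_snps} members are dropped. A
#' genome-wide noise reference is built by greedily taking the 5 lowest-p
#' variants no two of which lie within \code{spread_window} of each other
#' (different chromosomes always qualify; with fewer than 5 eligible variants
#' all available are used and flagged). A peak passes the noise gate when the
#' -log10(p) of its top SNP is at least \code{noise_factor} times the mean
#' -log10(p) of that reference set. Within a peak the top SNP is the one with
#' minimal p; ties go to the member closest to the splice-site.
#'
#' @param records association records from \code{\link{associateSite}}.
#' @param sig_threshold significance threshold on p (e.g. Bonferroni
#'   0.05 / n_variants).
#' @param min_peak_snps minimum members per peak (default 50; sparse test
#'   fixtures use smaller values).
#' @param merge_window bp window for merging significant neighbours.
#' @param noise_factor multiplier of the noise reference (default 1.33).
#' @param spread_window bp spacing required between reference SNPs (750 kb).
#' @param site_pos optional splice-site position (same chromosome given in
#'   \code{site_chrom}) used for p-value tie-breaking and the closest member.
#' @param site_chrom optional splice-site chromosome.
#' @return data.frame of peaks: peak_id, chrom, start, end, n_snps, top_snp,
#'   top_p, top_pos, closest_snp, passes_noise_gate, noise_reference.
#' @export
callPeaks <- function(records, sig_threshold, min_peak_snps = 50,
                      merge_window = 1e5, noise_factor = 1.33,
                      spread_window = 750000, site_pos = NULL,
                      site_chrom = NULL) {
  empty <- data.frame(peak_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), top_snp = character(0),
                      top_p = numeric(0), top_pos = integer(0),
                      closest_snp = character(0),
                      passes_noise_gate = logical(0),
                      noise_reference = numeric(0), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) return(empty)
  ref_mean <- noiseReference(records, spread_window)
  sig <- records[records$p_value <= sig_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), ]
  gap <- c(TRUE, diff(sig$pos) > merge_window) |
    c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)])
  sig$peak <- cumsum(gap)
  peaks <- lapply(split(sig, sig$peak), function(m) {
    if (nrow(m) < min_peak_snps) return(NULL)
    best <- m[m$p_value == min(m$p_value), , drop = FALSE]
    if (nrow(best) > 1 && !is.null(site_pos)) {
      best <- best[order(abs(best$pos - site_pos)), , drop = FALSE]
    }
    top <- best[1, ]
    closest <- if (!is.null(site_pos) && !is.null(site_chrom) &&
                   any(m$chrom == site_chrom)) {
      mm <- m[m$chrom == site_chrom, ]
      mm$variant_id[which.min(abs(mm$pos - site_pos))]
    } else NA_character_
    passes <- -log10(top$p_value) >= noise_factor * ref_mean
    data.frame(chrom = m$chrom[1], start = min(m$pos), end = max(m$pos),
               n_snps = nrow(m), top_snp = top$variant_id,
               top_p = top$p_value, top_pos = top$pos,
               closest_snp = closest, passes_noise_gate = passes,
               noise_reference = ref_mean, stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) return(empty)
  peaks$peak_id <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  peaks[, c("peak_id", setdiff(colnames(peaks), "peak_id"))]
}

## mean -log10(p) of the 5 lowest-p variants no two of which lie within
## spread_window; greedy in ascending p order
noiseReference <- function(records, spread_window) {
  r <- records[order(records$p_value), ]
  sel <- integer(0)
  for (i in seq_len(nrow(r))) {
    if (length(sel) == 5) break
    ok <- all(r$chrom[sel] != r$chrom[i] |
                abs(r$pos[sel] - r$pos[i]) > spread_window)
    if (ok) sel <- c(sel, i)
  }
  mean(-log10(r$p_value[sel]))
}

#' Strand-normalised distance of a variant from a splice-site
#'
#' Position zero is the intron-terminal base (the "G" of the donor GT, i.e.
#' the first intron base; the "G" of the acceptor AG, i.e. the last intron
#' base). The axis follows the transcribed strand: for donors the intronic
#' side is positive, for acceptors negative, with the exonic side taking the
#' opposite sign. Vectorised over variants.
#'
#' @param variant_pos genomic position(s) of variants (same chromosome as the
#'   site; cross-chromosome distances are undefined and handled as trans by
#'   the caller).
#' @param site_pos genomic position of the site anchor.
#' @param strand "+" or "-".
#' @return signed bp distance(s).
#' @export
relativePosition <- function(variant_pos, site_pos, strand) {
  sgn <- ifelse(strand == "+", 1L, -1L)
  sgn * (variant_pos - site_pos)
}

#' Classify an association as cis or trans
#'
#' cis iff the variant lies on the same chromosome within 1 Mb of the site;
#' different chromosomes are trans by definition.
#'
#' @param variant_chrom,variant_pos variant location.
#' @param site_chrom,site_pos site location.
#' @param max_dist cis distance cutoff in bp (1e6).
#' @return "cis" or "trans" (vectorised).
#' @export
classifyCisTrans <- function(variant_chrom, variant_pos, site_chrom, site_pos,
                             max_dist = 1e6) {
  ifelse(variant_chrom == site_chrom &
           abs(variant_pos - site_pos) <= max_dist, "cis", "trans")
}

#' Allelic usage change and variance explained for one variant
#'
#' delta_sse is the mean SSE of minor-allele carriers minus the mean SSE of
#' major-allele carriers. PVE uses the standard single-SNP formula
#' 2 beta^2 f (1-f) / (2 beta^2 f (1-f) + se^2 2 N f (1-f)), which simplifies
#' to beta^2 / (beta^2 + se^2 N).
#'
#' @param dosage dosage vector for the variant (0/1 or 0/1/2).
#' @param phenotype matching SSE vector.
#' @param beta,se,n slope, standard error and sample size from the
#'   association fit.
#' @return list with delta_sse and pve (both NA when only one allele class is
#'   observed).
#' @export
effectSummaries <- function(dosage, phenotype, beta, se, n) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  d <- dosage[ok]; y <- phenotype[ok]
  ploidy <- max(1, max(d))
  f_alt <- mean(d) / ploidy
  carriers <- d > 0
  if (all(carriers) || !any(carriers)) {
    return(list(delta_sse = NA_real_, pve = NA_real_))
  }
  minor_is_alt <- f_alt <= 0.5
  minor <- if (minor_is_alt) carriers else !carriers
  delta <- mean(y[minor]) - mean(y[!minor])
  f <- min(f_alt, 1 - f_alt)
  pve <- (2 * beta^2 * f * (1 - f)) /
    (2 * beta^2 * f * (1 - f) + se^2 * 2 * n * f * (1 - f))
  list(delta_sse = delta, pve = pve)
}

#' Top associations for a set of sites (the "SNP table")
#'
#' Runs \code{\link{associateSite}} and \code{\link{callPeaks}} for every
#' site, keeps the best passing peak (lowest top p), and annotates its top SNP
#' with the strand-normalised distance, cis/trans label, allelic usage change
#' and variance explained.
#'
#' @param geno_means sites x genotypes SSE matrix
#'   (\code{\link{genotypeAverage}}).
#' @param sites GRanges of the sites (rownames of \code{geno_means} must be
#'   site ids present here).
#' @param dosages,variants genotype data as in \code{\link{associateSite}}.
#' @param sig_threshold significance threshold; default Bonferroni
#'   0.05 / nrow(variants).
#' @param maf_min,min_n,kinship,n_pc forwarded to \code{\link{associateSite}}.
#' @param min_peak_snps,merge_window,noise_factor,spread_window forwarded to
#'   \code{\link{callPeaks}}.
#' @return data.frame with one row per site with a passing peak: site_id,
#'   site_chrom, site_pos, strand, site_type, top_snp, chrom, pos, p_value,
#'   beta, se, n, relative_distance, cis_trans, delta_sse, pve.
#' @export
topAssociations <- function(geno_means, sites, dosages, variants,
                            sig_threshold = 0.05 / nrow(variants),
                            maf_min = 0.05, min_n = 20, kinship = NULL,
                            n_pc = 5, min_peak_snps = 50, merge_window = 1e5,
                            noise_factor = 1.33, spread_window = 750000) {
  st <- siteTable(sites)
  rows <- list()
  for (sid in rownames(geno_means)) {
    s <- st[st$site_id == sid, ]
    if (nrow(s) != 1) next
    y <- geno_means[sid, ]
    rec <- associateSite(y, dosages, variants, maf_min = maf_min,
                         min_n = min_n, kinship = kinship, n_pc = n_pc)
    if (nrow(rec) == 0) next
    pk <- callPeaks(rec, sig_threshold, min_peak_snps = min_peak_snps,
                    merge_window = merge_window, noise_factor = noise_factor,
                    spread_window = spread_window, site_pos = s$position,
                    site_chrom = s$chrom)
    pk <- pk[pk$passes_noise_gate, , drop = FALSE]
    if (nrow(pk) == 0) next
    pk <- pk[which.min(pk$top_p), ]
    r <- rec[rec$variant_id == pk$top_snp, ]
    es <- effectSummaries(dosages[r$variant_id, names(y)], y,
                          beta = r$beta, se = r$se, n = r$n)
    rel <- if (r$chrom == s$chrom) {
      relativePosition(r$pos, s$position, s$strand)
    } else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sid, site_chrom = s$chrom, site_pos = s$position,
      strand = s$strand, site_type = s$site_type,
      top_snp = r$variant_id, chrom = r$chrom, pos = r$pos,
      p_value = r$p_value, beta = r$beta, se = r$se, n = r$n,
      relative_distance = rel,
      cis_trans = classifyCisTrans(r$chrom, r$pos, s$chrom, s$position),
      delta_sse = es$delta_sse, pve = es$pve, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_id = character(0))
  }
  attr(out, "engine") <- if (is.null(kinship)) "ols" else
    sprintf("ols+kinship-whitening(%d PCs)", n_pc)
  attr(out, "sig_threshold") <- sig_threshold
  out
}
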