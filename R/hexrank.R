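#' Apply alternate alleles to a genome copy
#'
#' Substitutes single-base alternate alleles (forward-strand coding) into the
#' genome, e.g. to extract an individual's splice-site k-mers.
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param substitutions data.frame with chrom, pos, alt (single bases).
#' @return modified \link[Biostrings]{DNAStringSet}.
#' @export
applySubstitutions <- function(genome, substitutions) {
  out <- as.character(genome)
  for (i in seq_len(nrow(substitutions))) {
    ch <- substitutions$chrom[i]; p <- substitutions$pos[i]
    substr(out[[ch]], p, p) <- substitutions$alt[i]
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(genome)
  res
}

#' Extract intron-anchored k-mers at splice-sites
#'
#' Donor keys span intron positions 0..k-1 (starting at the GT), acceptor
#' keys span -(k-1)..0 (ending at the AG), both read on the transcribed
#' strand. When \code{substitutions} is given (an individual's alternate
#' alleles), they are applied before extraction. Keys violating the GT/AG
#' anchor (annotation/genome mismatch) are returned but flagged.
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param sites GRanges of site anchors.
#' @param k k-mer length in [2, 8].
#' @param substitutions optional data.frame(chrom, pos, alt).
#' @return data.frame with site_id, site_type, key, anchored (logical: key
#'   carries the expected GT/AG anchor).
#' @export
siteKmers <- function(genome, sites, k = 6, substitutions = NULL) {
  stopifnot2(k >= 2 && k <= 8, "k must be in [2, 8]")
  if (!is.null(substitutions) && nrow(substitutions) > 0) {
    genome <- applySubstitutions(genome, substitutions)
  }
  st <- siteTable(sites)
  lo <- ifelse(st$site_type == "donor", 0L, -(k - 1L))
  hi <- lo + k - 1L
  gstart <- ifelse(st$strand == "+", st$position + lo, st$position - hi)
  gend <- gstart + k - 1L
  chr <- as.character(genome)
  keys <- character(nrow(st))
  for (ch in unique(st$chrom)) {
    i <- st$chrom == ch
    keys[i] <- substring(chr[[ch]], gstart[i], gend[i])
  }
  minus <- st$strand == "-"
  if (any(minus)) keys[minus] <- revcompChar(keys[minus])
  anchored <- ifelse(st$site_type == "donor",
                     substr(keys, 1, 2) == "GT",
                     substr(keys, k - 1, k) == "AG")
  data.frame(site_id = st$site_id, site_type = st$site_type, key = keys,
             anchored = anchored, stringsAsFactors = FALSE)
}

#' Hexamer (k-mer) strength table
#'
#' Groups used splice-sites by their intron-anchored k-mer, averages the
#' site-level mean usage per key (sites are averaged across individuals
#' first, so coverage does not weight the key mean), and ranks keys by
#' descending mean usage. Rank ties break deterministically: larger site
#' count first, then lexicographic key order. Keys with zero sites are absent,
#' never zero-filled; non-anchored keys are excluded.
#'
#' @param sites GRanges of used splice-sites.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param site_strength named per-site mean SSE (names = site_id).
#' @param k k-mer length.
#' @param site_type "donor" or "acceptor".
#' @return data.frame with key, n_sites, mean_sse, rank (1 = strongest).
#' @export
strengthTable <- function(sites, genome, site_strength, k = 6,
                          site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  sub <- sites[S4Vectors::mcols(sites)$site_type == site_type]
  km <- siteKmers(genome, sub, k = k)
  km <- km[km$anchored, , drop = FALSE]
  s <- site_strength[km$site_id]
  ok <- !is.na(s)
  km <- km[ok, , drop = FALSE]; s <- s[ok]
  mean_sse <- tapply(s, km$key, mean)
  n_sites <- as.vector(table(km$key)[names(mean_sse)])
  tab <- data.frame(key = names(mean_sse), n_sites = n_sites,
                    mean_sse = as.vector(mean_sse), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_sse, -tab$n_sites, tab$key), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Percentage of splice-site choices explained by k-mer ranking
#'
#' For every eligible used site (no other used site of the same type within
#' \code{window} bp on the same chromosome), scans \code{window} bp either
#' side of the site on the transcribed strand for all GT (donors) or AG
#' (acceptors) occurrences, extracts each candidate's k-mer, and scores a
#' success when the best-ranked key among candidates occurs exactly once in
#' the window and is the used site's own key. Keys absent from the strength
#' table rank below all present keys. The raw success rate is adjusted by the
#' fraction of the 4^(k-2) possible keys observed in the table:
#' adjusted_percent = raw_rate x possible_fraction x 100.
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param sites GRanges of used splice-sites (all used sites of the type are
#'   also the exclusion set).
#' @param table \code{\link{strengthTable}} output for this k and type.
#' @param k k-mer length.
#' @param site_type "donor" or "acceptor".
#' @param window scan half-width in bp (100 or 200).
#' @return list with k, window, n_sites_tested, n_success, raw_rate,
#'   possible_fraction, adjusted_percent and a per-site data.frame
#'   (\code{detail}).
#' @export
choiceExplained <- function(genome, sites, table, k = 6,
                            site_type = c("donor", "acceptor"),
                            window = 100) {
  site_type <- match.arg(site_type)
  st <- siteTable(sites)
  used <- st[st$site_type == site_type, , drop = FALSE]
  rank_of <- stats::setNames(table$rank, table$key)
  anchor <- if (site_type == "donor") "GT" else "AG"
  chr <- as.character(genome)
  chr_len <- nchar(chr)

  ## proximity exclusion between used sites of the same type
  eligible <- vapply(seq_len(nrow(used)), function(i) {
    same <- used$chrom == used$chrom[i]
    d <- abs(used$position[same] - used$position[i])
    sum(d <= window) == 1  # itself only
  }, logical(1))

  res <- lapply(which(eligible), function(i) {
    pos <- used$position[i]; strand <- used$strand[i]
    ch <- used$chrom[i]
    ## transcribed-strand region covering offsets -(window+k)..(window+k)
    gs <- max(1L, pos - (window + k))
    ge <- min(chr_len[[ch]], pos + (window + k))
    region <- substring(chr[[ch]], gs, ge)
    if (strand == "-") region <- revcompChar(region)
    ## index of the site anchor within the region string
    anchor_idx <- if (strand == "+") pos - gs + 1L else ge - pos + 1L
    hits <- gregexpr(anchor, region, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    ## anchor index: donor anchors at the G (match start); acceptor anchors
    ## at the G (match start + 1)
    aidx <- if (site_type == "donor") as.integer(hits) else
      as.integer(hits) + 1L
    rel <- aidx - anchor_idx
    aidx <- aidx[abs(rel) <= window]
    ## candidate key spans within the region string
    ks <- if (site_type == "donor") aidx else aidx - (k - 1L)
    ke <- ks + k - 1L
    keep <- ks >= 1 & ke <= nchar(region)
    ks <- ks[keep]; ke <- ke[keep]; aidx <- aidx[keep]
    keys <- substring(region, ks, ke)
    ranks <- rank_of[keys]
    ranks[is.na(ranks)] <- Inf
    best <- min(ranks)
    success <- is.finite(best) && sum(ranks == best) == 1 &&
      aidx[which(ranks == best)] == anchor_idx
    data.frame(site_id = used$site_id[i], n_candidates = length(keys),
               success = success, stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, res)
  n_tested <- if (is.null(detail)) 0L else nrow(detail)
  n_success <- if (is.null(detail)) 0L else sum(detail$success)
  raw <- if (n_tested > 0) n_success / n_tested else NA_real_
  possible_fraction <- min(1, nrow(table) / 4^(k - 2))
  list(k = k, window = window, site_type = site_type,
       n_sites_tested = n_tested, n_success = n_success, raw_rate = raw,
       possible_fraction = possible_fraction,
       adjusted_percent = raw * possible_fraction * 100,
       detail = detail)
}

#' Rank correlation between two strength tables
#'
#' Spearman correlation of the two tables' mean strengths over shared keys,
#' reported as R^2 with the sign kept separately. Requires at least
#' \code{min_shared} shared keys.
#'
#' @param tableA,tableB \code{\link{strengthTable}} outputs.
#' @param min_shared minimum shared keys (default 10).
#' @return list with r2, rho, n_shared (NA with a warning when too few keys
#'   are shared).
#' @export
rankCorrelation <- function(tableA, tableB, min_shared = 10) {
  shared <- intersect(tableA$key, tableB$key)
  if (length(shared) < min_shared) {
    warning("fewer than ", min_shared, " shared keys; correlation undefined")
    return(list(r2 = NA_real_, rho = NA_real_, n_shared = length(shared)))
  }
  a <- tableA$mean_sse[match(shared, tableA$key)]
  b <- tableB$mean_sse[match(shared, tableB$key)]
  rho <- stats::cor(a, b, method = "spearman")
  list(r2 = rho^2, rho = rho, n_shared = length(shared))
}

#' Pairwise R^2 matrix over several strength tables
#'
#' @param tables named list of \code{\link{strengthTable}} outputs.
#' @param min_shared minimum shared keys per pair.
#' @return symmetric matrix of squared Spearman correlations with unit
#'   diagonal.
#' @export
rankCorrelationMatrix <- function(tables, min_shared = 10) {
  n <- length(tables)
  m <- diag(1, n)
  dimnames(m) <- list(names(tables), names(tables))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        rankCorrelation(tables[[i]], tables[[j]], min_shared)$r2
    }
  }
  m
}

#' p-distance of equal-length keys
#'
#' Proportion of mismatching positions between two equal-length sequences.
#'
#' @param a,b character sequences of equal length (vectorised over \code{a}).
#' @return numeric proportion(s) in [0, 1].
#' @export
pDistance <- function(a, b) {
  stopifnot2(all(nchar(a) == nchar(b)), "sequences must have equal length")
  bs <- strsplit(b, "")[[1]]
  vapply(strsplit(a, ""), function(x) mean(x != bs), numeric(1))
}

#' Strength profile by sequence distance from a reference hexamer
#'
#' Groups the table's keys by p-distance from a reference (e.g. the U1 snRNA
#' binding site GTAAGT for donors, or the strongest acceptor hexamer TTGCAG)
#' and reports each group's mean strength plus the correlation between group
#' distance and group mean.
#'
#' @param table a \code{\link{strengthTable}}.
#' @param reference reference key of the same length and site type.
#' @return list with \code{groups} (distance, n_keys, mean_strength) and
#'   \code{correlation} (Pearson, distance vs group mean).
#' @export
pDistanceProfile <- function(table, reference) {
  d <- pDistance(table$key, reference)
  gm <- tapply(table$mean_sse, d, mean)
  groups <- data.frame(distance = as.numeric(names(gm)),
                       n_keys = as.vector(table(d)),
                       mean_strength = as.vector(gm))
  corr <- if (nrow(groups) > 2) {
    stats::cor(groups$distance, groups$mean_strength)
  } else NA_real_
  list(groups = groups, correlation = corr)
}

#' Used vs unused k-mer occurrences in gene bodies
#'
#' Scans every gene body on its transcribed strand for GT/AG-anchored k-mers,
#' splits occurrences into used (anchored at an annotated used splice-site of
#' the matching type) and unused, and correlates each partition's occurrence
#' proportions with the strength table's mean usage.
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param genes GRanges of gene bodies (strand required).
#' @param sites GRanges of used splice-sites.
#' @param table \code{\link{strengthTable}} for the site type.
#' @param k k-mer length.
#' @param site_type "donor" or "acceptor".
#' @return list with \code{counts} (key, used, unused, used_prop,
#'   unused_prop, mean_sse), \code{cor_used}, \code{cor_unused}.
#' @export
occurrenceProfile <- function(genome, genes, sites, table, k = 6,
                              site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  anchor <- if (site_type == "donor") "GT" else "AG"
  st <- siteTable(sites)
  st <- st[st$site_type == site_type, , drop = FALSE]
  used_key <- paste(st$chrom, st$position, st$strand)
  chr <- as.character(genome)
  g <- as.data.frame(genes)
  used_counts <- list(); unused_counts <- list()
  for (i in seq_len(nrow(g))) {
    ch <- as.character(g$seqnames[i]); strand <- as.character(g$strand[i])
    region <- substring(chr[[ch]], g$start[i], g$end[i])
    if (strand == "-") region <- revcompChar(region)
    hits <- gregexpr(anchor, region, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    aidx <- if (site_type == "donor") as.integer(hits) else
      as.integer(hits) + 1L
    ## genomic position of the anchor G
    gpos <- if (strand == "+") g$start[i] + aidx - 1L else g$end[i] - aidx + 1L
    ks <- if (site_type == "donor") aidx else aidx - (k - 1L)
    ke <- ks + k - 1L
    keep <- ks >= 1 & ke <= nchar(region)
    keys <- substring(region, ks[keep], ke[keep])
    is_used <- paste(ch, gpos[keep], strand) %in% used_key
    used_counts[[i]] <- keys[is_used]
    unused_counts[[i]] <- keys[!is_used]
  }
  uk <- table(unlist(used_counts))
  nk <- table(unlist(unused_counts))
  keys <- union(names(uk), names(nk))
  counts <- data.frame(key = keys,
                       used = as.vector(uk[keys]),
                       unused = as.vector(nk[keys]),
                       stringsAsFactors = FALSE)
  counts$used[is.na(counts$used)] <- 0L
  counts$unused[is.na(counts$unused)] <- 0L
  counts$used_prop <- counts$used / max(1, sum(counts$used))
  counts$unused_prop <- counts$unused / max(1, sum(counts$unused))
  counts$mean_sse <- table$mean_sse[match(counts$key, table$key)]
  ok <- !is.na(counts$mean_sse)
  safeCor <- function(x, y) {
    if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
  }
  list(counts = counts,
       cor_used = safeCor(counts$used_prop[ok], counts$mean_sse[ok]),
       cor_unused = safeCor(counts$unused_prop[ok], counts$mean_sse[ok]))
}

#' Competing-pair analysis of a minigene library
#'
#' Each construct contributes one pair of competing donors: the winner is the
#' site with higher SSE, and the pair is "explained" when the winner's hexamer
#' has the higher mean strength in the table. The explained fraction is
#' reported overall and stratified by bins of the absolute strength
#' difference. A permutation null shuffles the strength-to-key assignment
#' \code{n_perm} times and recomputes the explained fraction; the null's
#' quantiles give the significance threshold. Pairs with tied SSE or tied key
#' strengths are excluded from numerator and denominator.
#'
#' @param pairs data.frame with key_a, key_b, sse_a, sse_b (e.g.
#'   \code{\link{simulateMinigeneLibrary}}\code{$pairs}).
#' @param table donor \code{\link{strengthTable}}.
#' @param gap_breaks breakpoints of |strength difference| bins (default
#'   separates pairs above/below 0.25).
#' @param n_perm number of permutations (default 10,000).
#' @param seed permutation seed.
#' @param upper_quantile null quantile reported as the threshold.
#' @return list with \code{overall} (n_pairs, explained_fraction,
#'   perm_threshold, perm_interval99), \code{by_gap} (per-bin fractions with
#'   per-bin permutation thresholds) and \code{null_fractions}.
#' @export
competingPairAnalysis <- function(pairs, table, gap_breaks = c(0, 0.25, 1),
                                  n_perm = 10000, seed = 1L,
                                  upper_quantile = 0.99) {
  s <- stats::setNames(table$mean_sse, table$key)
  known <- pairs$key_a %in% names(s) & pairs$key_b %in% names(s)
  p <- pairs[known, , drop = FALSE]
  no_tie_sse <- p$sse_a != p$sse_b
  p <- p[no_tie_sse, , drop = FALSE]
  win_key <- ifelse(p$sse_a > p$sse_b, p$key_a, p$key_b)
  lose_key <- ifelse(p$sse_a > p$sse_b, p$key_b, p$key_a)
  iw <- match(win_key, names(s)); il <- match(lose_key, names(s))

  n_bins <- length(gap_breaks) - 1
  bin_labels <- levels(cut(numeric(0), breaks = gap_breaks,
                           include.lowest = TRUE))
  frac <- function(strengths) {
    d <- strengths[iw] - strengths[il]
    mean(d[d != 0] > 0)
  }
  binned <- function(strengths) {
    d <- strengths[iw] - strengths[il]
    d <- d[d != 0]
    ## bin index per cut(..., include.lowest = TRUE) semantics
    bi <- pmax(1L, findInterval(abs(d), gap_breaks, left.open = TRUE,
                                rightmost.closed = TRUE))
    cnt <- tabulate(bi, n_bins)
    win <- tabulate(bi[d > 0], n_bins)
    out <- win / cnt
    out[cnt == 0] <- NA_real_
    out
  }
  obs <- frac(s)
  obs_bin <- binned(s)
  d0 <- s[iw] - s[il]
  gap0 <- abs(d0[d0 != 0])
  n_bin <- tabulate(pmax(1L, findInterval(gap0, gap_breaks, left.open = TRUE,
                                          rightmost.closed = TRUE)), n_bins)

  set.seed(seed)
  null_overall <- numeric(n_perm)
  null_bins <- matrix(NA_real_, n_perm, n_bins)
  for (b in seq_len(n_perm)) {
    sp <- stats::setNames(sample(s), names(s))
    null_overall[b] <- frac(sp)
    null_bins[b, ] <- binned(sp)
  }
  thr_bins <- apply(null_bins, 2, stats::quantile, probs = upper_quantile,
                    na.rm = TRUE)
  list(
    overall = list(
      n_pairs = sum(d0 != 0),
      explained_fraction = obs,
      perm_threshold = stats::quantile(null_overall, upper_quantile,
                                       names = FALSE),
      perm_interval99 = stats::quantile(null_overall, c(0.005, 0.995),
                                        names = FALSE)),
    by_gap = data.frame(bin = bin_labels, n_pairs = n_bin,
                        explained_fraction = obs_bin,
                        perm_threshold = as.vector(thr_bins),
                        stringsAsFactors = FALSE),
    null_fractions = null_overall)
}
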