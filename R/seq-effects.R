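## transcribed-strand bases around site anchors: sites x offsets matrix.
## Offsets follow the site axis (0 = intron-terminal G; donors: intronic
## positive; acceptors: intronic negative). Sites whose window leaves the
## contig are dropped with a message.
siteWindowBases <- function(genome, sites, lo, hi) {
  st <- siteTable(sites)
  chr_len <- Biostrings::width(genome)
  names(chr_len) <- names(genome)
  gstart <- ifelse(st$strand == "+", st$position + lo, st$position - hi)
  gend <- gstart + (hi - lo)
  ok <- gstart >= 1 & gend <= chr_len[st$chrom]
  if (any(!ok)) {
    message(sum(!ok), " site(s) skipped: window extends past contig end")
  }
  st <- st[ok, , drop = FALSE]
  seqs <- character(nrow(st))
  for (ch in unique(st$chrom)) {
    i <- st$chrom == ch
    seqs[i] <- substring(as.character(genome[[ch]]), gstart[ok][i],
                         gend[ok][i])
  }
  minus <- st$strand == "-"
  if (any(minus)) seqs[minus] <- revcompChar(seqs[minus])
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- st$site_id
  colnames(m) <- as.character(lo:hi)
  m
}

#' Proportion of usage variance explained by a grouping
#'
#' (TSS - RSS) / TSS, where TSS is the total sum of squares of the values
#' about the grand mean and RSS is the pooled within-group sum of squares.
#' Returns 0 by convention when TSS is 0.
#'
#' @param values numeric vector (e.g. site-level mean SSE).
#' @param groups grouping factor (e.g. the base at one position).
#' @return proportion in [0, 1].
#' @export
proportionOfVariance <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tss <- sum((values - mean(values))^2)
  if (tss == 0) return(0)
  gm <- tapply(values, groups, mean)
  rss <- sum((values - gm[groups])^2)
  (tss - rss) / tss
}

#' Position-wise nucleotide effects on splice-site usage
#'
#' For each relative position around the splice-site (default donor -3..+7,
#' acceptor -7..+3, on the transcribed strand) and each base, the mean of
#' site-level usage across sites carrying that base, the site counts, the best
#' base (highest mean) and the proportion of usage variance explained by the
#' position.
#'
#' @param sites GRanges of splice-sites.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param site_strength named numeric of per-site mean SSE (names = site_id).
#' @param donor_window,acceptor_window c(lo, hi) relative windows.
#' @return named list (donor, acceptor); each element has \code{stats}
#'   (position, base, mean_sse, n), \code{best} / \code{worst} (named base per
#'   position), \code{prop_var} (position, proportion_of_variance) and
#'   \code{base_matrix} (sites x positions, for interaction analysis).
#' @export
positionNucleotideMeans <- function(sites, genome, site_strength,
                                    donor_window = c(-3, 7),
                                    acceptor_window = c(-7, 3)) {
  out <- list()
  for (type in c("donor", "acceptor")) {
    w <- if (type == "donor") donor_window else acceptor_window
    sub <- sites[S4Vectors::mcols(sites)$site_type == type]
    if (length(sub) == 0) next
    bm <- siteWindowBases(genome, sub, w[1], w[2])
    s <- site_strength[rownames(bm)]
    keep <- !is.na(s)
    bm <- bm[keep, , drop = FALSE]; s <- s[keep]
    stats_rows <- list(); best <- character(0); worst <- character(0)
    pv <- numeric(0)
    for (p in colnames(bm)) {
      means <- tapply(s, bm[, p], mean)
      ns <- table(bm[, p])
      stats_rows[[p]] <- data.frame(position = as.integer(p),
                                    base = names(means),
                                    mean_sse = as.vector(means),
                                    n = as.vector(ns[names(means)]),
                                    stringsAsFactors = FALSE)
      best[p] <- names(means)[which.max(means)]
      worst[p] <- names(means)[which.min(means)]
      pv[p] <- proportionOfVariance(s, bm[, p])
    }
    out[[type]] <- list(
      stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
      best = best, worst = worst,
      prop_var = data.frame(position = as.integer(names(pv)),
                            proportion_of_variance = unname(pv)),
      base_matrix = bm, site_strength = s)
  }
  out
}

#' Pairwise nucleotide interactions around splice-sites
#'
#' For every pair of positions and bases, compares the observed mean usage of
#' sites carrying both bases with a naive additive expectation: the grand mean
#' plus each base's marginal deviation, capped so the expectation stays within
#' [0, 1]. The deviation (observed - expectation) measures second-order
#' (epistatic) structure. Site/position-pair combinations can be down-sampled
#' to a cap with a seeded uniform sample.
#'
#' @param base_matrix sites x positions base matrix (from
#'   \code{\link{positionNucleotideMeans}}).
#' @param site_strength per-site mean SSE aligned with base_matrix rows.
#' @param cap maximum site x position-pair combinations scored.
#' @param seed seed for the down-sampling draw.
#' @return data.frame with position1, base1, position2, base2, n_sites,
#'   expectation, observed, deviation.
#' @export
pairwiseInteractions <- function(base_matrix, site_strength, cap = 2e6,
                                 seed = 1L) {
  positions <- colnames(base_matrix)
  np <- length(positions)
  n_pairs <- np * (np - 1) / 2
  if (nrow(base_matrix) * n_pairs > cap) {
    set.seed(seed)
    keep <- sort(sample(nrow(base_matrix), floor(cap / n_pairs)))
    base_matrix <- base_matrix[keep, , drop = FALSE]
    site_strength <- site_strength[keep]
  }
  grand <- mean(site_strength)
  marg <- lapply(positions, function(p) {
    tapply(site_strength, base_matrix[, p], mean)
  })
  names(marg) <- positions
  rows <- list()
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      p1 <- positions[i]; p2 <- positions[j]
      key <- paste(base_matrix[, p1], base_matrix[, p2])
      obs <- tapply(site_strength, key, mean)
      ns <- table(key)
      for (k in names(obs)) {
        b <- strsplit(k, " ")[[1]]
        expct <- clamp01(grand + (marg[[p1]][b[1]] - grand) +
                           (marg[[p2]][b[2]] - grand))
        rows[[length(rows) + 1L]] <- data.frame(
          position1 = as.integer(p1), base1 = b[1],
          position2 = as.integer(p2), base2 = b[2],
          n_sites = as.integer(ns[k]), expectation = unname(expct),
          observed = unname(obs[k]),
          deviation = unname(obs[k] - expct), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Elbow-based outlier detection on sorted interaction deviations
#'
#' The deviations are sorted and plotted on rank-vs-value axes normalised to
#' [0, 1]. For each tail, a line is drawn from the midpoint of the sorted
#' profile to that extreme; the elbow is the point of maximum perpendicular
#' distance from the line. The outlier threshold is the elbow's deviation
#' value moved outward by a conservative buffer (default 0.1, i.e. 10% usage
#' change beyond the elbow); points beyond the threshold are flagged.
#'
#' @param deviations numeric vector of interaction deviations.
#' @param buffer additional margin beyond the elbow value.
#' @return list with \code{outlier} (logical, input order), \code{lower} /
#'   \code{upper} thresholds and the elbow values.
#' @export
elbowOutliers <- function(deviations, buffer = 0.1) {
  n <- length(deviations)
  stopifnot2(n >= 3, "need at least 3 deviations")
  s <- sort(deviations)
  if (max(s) == min(s)) {
    return(list(outlier = rep(FALSE, n), lower = -Inf, upper = Inf,
                elbow_low = NA_real_, elbow_high = NA_real_))
  }
  u <- (seq_len(n) - 1) / (n - 1)
  v <- (s - min(s)) / (max(s) - min(s))
  mid <- floor((n + 1) / 2)
  perp <- function(idx) {
    a <- c(u[idx[1]], v[idx[1]]); b <- c(u[idx[length(idx)]],
                                         v[idx[length(idx)]])
    ab <- b - a
    len <- sqrt(sum(ab^2))
    vapply(idx, function(i) {
      abs(ab[1] * (v[i] - a[2]) - ab[2] * (u[i] - a[1])) / len
    }, numeric(1))
  }
  hi_idx <- mid:n
  elbow_hi <- hi_idx[which.max(perp(hi_idx))]
  lo_idx <- 1:mid
  elbow_lo <- lo_idx[which.max(perp(lo_idx))]
  upper <- s[elbow_hi] + buffer
  lower <- s[elbow_lo] - buffer
  list(outlier = deviations > upper | deviations < lower,
       lower = lower, upper = upper,
       elbow_low = s[elbow_lo], elbow_high = s[elbow_hi])
}

#' Infer splice-promoting and splice-reducing nucleotides from associations
#'
#' Restricts the top-association table to sites whose top SNP lies within
#' \code{max_dist} bp of the splice-site, assigns every SNP to its single
#' closest site (ties: donor before acceptor, then lower site coordinate),
#' and, per association, calls the allele whose carriers have higher mean
#' usage "promoting" and the other "reducing", on the transcribed strand of
#' the site. Per site type and relative position, the modal promoting and
#' reducing bases are reported.
#'
#' @param top_assoc output of \code{\link{topAssociations}}.
#' @param variants variant table (variant_id, ref, alt).
#' @param dosages variants x genotypes matrix (to orient minor/major).
#' @param max_dist maximum |relative distance| in bp (default 100).
#' @return list with \code{profile} (site_type, position, promoting,
#'   reducing, n_associations) and \code{details} (one row per retained
#'   association).
#' @export
inferPromotingNucleotides <- function(top_assoc, variants, dosages,
                                      max_dist = 100) {
  ta <- top_assoc[!is.na(top_assoc$relative_distance) &
                    abs(top_assoc$relative_distance) <= max_dist, ,
                  drop = FALSE]
  if (nrow(ta) == 0) {
    return(list(profile = data.frame(), details = data.frame()))
  }
  ## one site per SNP: closest; ties donor first, then lower coordinate
  ta$type_rank <- ifelse(ta$site_type == "donor", 0L, 1L)
  ta <- ta[order(ta$top_snp, abs(ta$relative_distance), ta$type_rank,
                 ta$site_pos), ]
  ta <- ta[!duplicated(ta$top_snp), , drop = FALSE]
  ploidy <- max(1, max(dosages, na.rm = TRUE))
  det <- lapply(seq_len(nrow(ta)), function(i) {
    r <- ta[i, ]
    v <- variants[variants$variant_id == r$top_snp, ]
    f_alt <- mean(dosages[r$top_snp, ], na.rm = TRUE) / ploidy
    minor_is_alt <- f_alt <= 0.5
    ## delta_sse = mean(minor) - mean(major); positive => minor promotes
    minor_base <- if (minor_is_alt) v$alt else v$ref
    major_base <- if (minor_is_alt) v$ref else v$alt
    promoting_fwd <- if (r$delta_sse > 0) minor_base else major_base
    reducing_fwd <- if (r$delta_sse > 0) major_base else minor_base
    flip <- r$strand == "-"
    data.frame(site_id = r$site_id, site_type = r$site_type,
               position = r$relative_distance,
               promoting = if (flip) compChar(promoting_fwd) else
                 promoting_fwd,
               reducing = if (flip) compChar(reducing_fwd) else reducing_fwd,
               stringsAsFactors = FALSE)
  })
  det <- do.call(rbind, det)
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  prof <- do.call(rbind, lapply(
    split(det, list(det$site_type, det$position), drop = TRUE),
    function(d) data.frame(site_type = d$site_type[1],
                           position = d$position[1],
                           promoting = modal(d$promoting),
                           reducing = modal(d$reducing),
                           n_associations = nrow(d),
                           stringsAsFactors = FALSE)))
  prof <- prof[order(prof$site_type, prof$position), ]
  rownames(prof) <- NULL
  list(profile = prof, details = det)
}

#' Build a 100 bp synthetic intron from inferred nucleotide profiles
#'
#' Concatenates a donor-side segment (relative positions 0..+49) and an
#' acceptor-side segment (-49..0): the donor GT and acceptor AG are forced and
#' a branch-point adenosine is always present. Interior positions are filled
#' from the promoting (best) or reducing (worst) profile where supported, then
#' from the per-position mean-usage best/worst bases, then from a default
#' fill base. Optional modifications rewrite the 3' region with a
#' polypyrimidine tract and/or a consensus branch point, or replace the
#' terminal hexamers with the top-ranked entries of supplied strength tables.
#'
#' @param profile promoting-nucleotide profile
#'   (\code{\link{inferPromotingNucleotides}}\code{$profile}).
#' @param variant "best" (promoting bases) or "worst" (reducing bases).
#' @param position_means optional \code{\link{positionNucleotideMeans}}
#'   output used to fill positions absent from the profile.
#' @param modifications character subset of c("ppt", "branchpoint",
#'   "strong_hexamers").
#' @param strength_tables list with donor/acceptor
#'   \code{\link{strengthTable}} outputs (required for "strong_hexamers").
#' @param fill_base default fill where no information is available ("T" for
#'   best, "G" for worst if NULL).
#' @return a 100-character intron sequence starting GT and ending AG.
#' @export
buildSyntheticIntron <- function(profile, variant = c("best", "worst"),
                                 position_means = NULL,
                                 modifications = character(0),
                                 strength_tables = NULL, fill_base = NULL) {
  variant <- match.arg(variant)
  bad <- setdiff(modifications, c("ppt", "branchpoint", "strong_hexamers"))
  stopifnot2(length(bad) == 0,
             paste("unknown modification:", paste(bad, collapse = ", ")))
  if (is.null(fill_base)) fill_base <- if (variant == "best") "T" else "G"
  col <- if (variant == "best") "promoting" else "reducing"
  pm_col <- if (variant == "best") "best" else "worst"
  lookup <- function(type, pos) {
    if (nrow(profile) > 0) {
      hit <- profile[profile$site_type == type & profile$position == pos, ]
      if (nrow(hit) == 1 && !is.na(hit[[col]])) return(hit[[col]])
    }
    if (!is.null(position_means) && !is.null(position_means[[type]])) {
      b <- position_means[[type]][[pm_col]]
      if (as.character(pos) %in% names(b)) return(b[[as.character(pos)]])
    }
    fill_base
  }
  seq <- character(100)
  for (i in 1:50) seq[i] <- lookup("donor", i - 1L)       # donor offsets 0..49
  for (i in 51:100) seq[i] <- lookup("acceptor", i - 100L) # -49..0
  seq[1:2] <- c("G", "T")
  seq[99:100] <- c("A", "G")
  seq[75] <- "A"  # branch-point adenosine, always present
  if ("branchpoint" %in% modifications) {
    seq[72:76] <- c("C", "T", "A", "A", "C")  # consensus, branch A at 75
  }
  if ("ppt" %in% modifications) {
    seq[81:96] <- rep(c("T", "T", "C", "T"), 4)
  }
  if ("strong_hexamers" %in% modifications) {
    stopifnot2(!is.null(strength_tables),
               "strong_hexamers requires strength_tables")
    top_d <- strength_tables$donor$key[strength_tables$donor$rank == 1]
    top_a <- strength_tables$acceptor$key[strength_tables$acceptor$rank == 1]
    if (substr(top_d, 1, 2) != "GT" ||
        substr(top_a, nchar(top_a) - 1, nchar(top_a)) != "AG") {
      stop("modification conflicts with forced GT/AG anchors", call. = FALSE)
    }
    seq[1:6] <- strsplit(top_d, "")[[1]]
    seq[95:100] <- strsplit(top_a, "")[[1]]
  }
  paste(seq, collapse = "")
}
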