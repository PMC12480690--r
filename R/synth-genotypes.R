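#' Simulate biallelic genotypes with causal hexamer SNPs
#'
#' Places a strength-altering SNP inside the hexamer of a configured fraction
#' of splice-sites (only within the four variable bases, never disturbing the
#' GT/AG anchor), plus neutral background variants elsewhere in gene bodies.
#' Alleles are coded on the forward genomic strand; dosages are 0/1 for inbred
#' panels or 0/1/2 for diploid cohorts, drawn at a minor-allele frequency
#' sampled from the configured range.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param synth output of \code{\link{generateGenome}} (genome + sites +
#'   genes).
#' @param model the \linkS4class{TrueStrengthModel} used to generate the
#'   genome.
#' @param diploid if TRUE dosages are 0/1/2, otherwise inbred 0/1.
#' @param effect_mode "max" plants, among all single-base changes of the
#'   variable hexamer positions, the one whose strength differs most from the
#'   reference hexamer's (a large-effect splice-site mutation); "random"
#'   picks a uniformly random position and alternate base.
#' @param background_per_gene neutral (non-hexamer) variants per gene.
#' @return list with \code{variants} (data.frame: variant_id, chrom, pos, ref,
#'   alt, maf, causal, site_id, ref_strength, alt_strength) and \code{dosages}
#'   (variants x genotypes integer matrix).
#' @export
simulateGenotypes <- function(config, synth, model, diploid = FALSE,
                              effect_mode = c("max", "random"),
                              background_per_gene = 5L) {
  effect_mode <- match.arg(effect_mode)
  set.seed(config@seed + 1L)
  sites <- siteTable(synth$sites)
  genome_chr <- as.character(synth$genome)
  ploidy <- if (diploid) 2L else 1L
  nG <- config@n_genotypes
  geno_ids <- sprintf("g%04d", seq_len(nG))

  n_causal <- round(config@causal_fraction * nrow(sites))
  causal_idx <- if (n_causal > 0) sort(sample(nrow(sites), n_causal)) else
    integer(0)

  rows <- list(); dos <- list()
  for (i in causal_idx) {
    st <- sites[i, ]
    hex <- st$hexamer
    var_pos_in_hex <- if (st$site_type == "donor") 3:6 else 1:4
    smap <- strengthMap(model, st$site_type)
    ## all single-base changes of the variable positions
    cand <- do.call(rbind, lapply(var_pos_in_hex, function(h) {
      ref_b <- substr(hex, h, h)
      alts <- setdiff(DNA_BASES, ref_b)
      hx <- vapply(alts, function(b) { x <- hex; substr(x, h, h) <- b; x },
                   character(1))
      data.frame(h = h, alt = alts, alt_hex = hx,
                 gap = abs(unname(smap[hx] - smap[hex])),
                 stringsAsFactors = FALSE)
    }))
    pick <- if (effect_mode == "max") which.max(cand$gap) else
      sample(nrow(cand), 1)
    h <- cand$h[pick]
    ref_b <- substr(hex, h, h)
    alt_b <- cand$alt[pick]
    alt_hex_chosen <- cand$alt_hex[pick]
    off <- if (st$site_type == "donor") h - 1L else h - 6L
    gpos <- genomicAt(st$position, st$strand, off)
    fwd_ref <- substring(genome_chr[[st$chrom]], gpos, gpos)
    want <- if (st$strand == "-") compChar(ref_b) else ref_b
    if (!identical(fwd_ref, want)) {
      stop("internal generator error: hexamer base does not match genome at ",
           st$chrom, ":", gpos, call. = FALSE)
    }
    fwd_alt <- if (st$strand == "-") compChar(alt_b) else alt_b
    maf <- stats::runif(1, config@causal_maf_range[1],
                        config@causal_maf_range[2])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = st$chrom, pos = gpos, ref = fwd_ref, alt = fwd_alt, maf = maf,
      causal = TRUE, site_id = st$site_id,
      ref_strength = unname(smap[hex]),
      alt_strength = unname(smap[alt_hex_chosen]),
      stringsAsFactors = FALSE)
    dos[[length(dos) + 1L]] <- stats::rbinom(nG, ploidy, maf)
  }

  ## neutral background variants outside any hexamer
  hex_spans <- hexamerSpans(synth$sites)
  genes <- as.data.frame(synth$genes)
  for (g in seq_len(nrow(genes))) {
    chrom <- as.character(genes$seqnames[g])
    cand <- setdiff(seq(genes$start[g], genes$end[g]),
                    hex_spans[[chrom]])
    if (length(cand) < background_per_gene) next
    for (p in sample(cand, background_per_gene)) {
      ref <- substring(genome_chr[[chrom]], p, p)
      alt <- sample(setdiff(DNA_BASES, ref), 1)
      maf <- stats::runif(1, 0.05, 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = p, ref = ref, alt = alt, maf = maf,
        causal = FALSE, site_id = NA_character_, ref_strength = NA_real_,
        alt_strength = NA_real_, stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- stats::rbinom(nG, ploidy, maf)
    }
  }

  variants <- do.call(rbind, rows)
  dosages <- do.call(rbind, dos)
  keep <- !duplicated(variants[, c("chrom", "pos")])
  variants <- variants[keep, , drop = FALSE]
  dosages <- dosages[keep, , drop = FALSE]
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosages <- dosages[o, , drop = FALSE]
  variants$variant_id <- sprintf("v%05d", seq_len(nrow(variants)))
  f <- rowMeans(dosages) / ploidy
  variants$maf_realized <- pmin(f, 1 - f)
  rownames(dosages) <- variants$variant_id
  colnames(dosages) <- geno_ids
  rownames(variants) <- NULL
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt", "maf",
                           "maf_realized", "causal", "site_id",
                           "ref_strength", "alt_strength")]
  list(variants = variants, dosages = dosages, ploidy = ploidy)
}

## genomic positions covered by any site hexamer, per chromosome
hexamerSpans <- function(site_gr) {
  st <- siteTable(site_gr)
  span <- function(pos, strand, type) {
    offs <- if (type == "donor") 0:5 else -5:0
    genomicAt(pos, strand, if (strand == "+") offs else offs)
  }
  out <- list()
  for (i in seq_len(nrow(st))) {
    p <- sort(span(st$position[i], st$strand[i], st$site_type[i]))
    out[[st$chrom[i]]] <- c(out[[st$chrom[i]]], seq(min(p), max(p)))
  }
  lapply(out, unique)
}

## GRanges of sites -> plain data.frame used internally
siteTable <- function(site_gr) {
  data.frame(site_id = S4Vectors::mcols(site_gr)$site_id,
             chrom = as.character(GenomicRanges::seqnames(site_gr)),
             position = GenomicRanges::start(site_gr),
             strand = as.character(GenomicRanges::strand(site_gr)),
             site_type = S4Vectors::mcols(site_gr)$site_type,
             gene_id = S4Vectors::mcols(site_gr)$gene_id,
             hexamer = if (!is.null(S4Vectors::mcols(site_gr)$hexamer))
               S4Vectors::mcols(site_gr)$hexamer else NA_character_,
             true_strength =
               if (!is.null(S4Vectors::mcols(site_gr)$true_strength))
                 S4Vectors::mcols(site_gr)$true_strength else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-individual true site usage implied by genotypes
#'
#' For every site and individual, substitutes the individual's alternate
#' alleles into the site hexamer and looks up the resulting strength in the
#' model. Diploid dosages act additively on the probability scale
#' (dose/2 weighting of the alternate hexamer's strength). Trans effects in
#' the model multiply the usage of their target sites in carriers, clamped to
#' [0, 1].
#'
#' @param synth output of \code{\link{generateGenome}}.
#' @param geno output of \code{\link{simulateGenotypes}}.
#' @param model the \linkS4class{TrueStrengthModel}.
#' @return numeric matrix sites x genotypes of true SSE values in [0, 1].
#' @export
trueSSETable <- function(synth, geno, model) {
  st <- siteTable(synth$sites)
  nG <- ncol(geno$dosages)
  truth <- matrix(rep(st$true_strength, nG), nrow = nrow(st),
                  dimnames = list(st$site_id, colnames(geno$dosages)))
  cv <- geno$variants[geno$variants$causal, , drop = FALSE]
  for (i in seq_len(nrow(cv))) {
    d <- geno$dosages[cv$variant_id[i], ]
    w <- d / geno$ploidy
    sid <- cv$site_id[i]
    truth[sid, ] <- (1 - w) * cv$ref_strength[i] + w * cv$alt_strength[i]
  }
  for (te in model@trans_effects) {
    carriers <- geno$dosages[te$variant_id, ] > 0
    truth[te$site_ids, carriers] <-
      clamp01(truth[te$site_ids, carriers] * te$effect)
  }
  truth
}
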