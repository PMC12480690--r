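#' Generate a synthetic genome with hexamer-determined splice-sites
#'
#' Builds random-background chromosomes carrying gene models (alternating
#' exons and introns on randomly chosen strands). Every intron starts with a
#' donor hexamer (GT[N]4) and ends with an acceptor hexamer ([N]4AG) drawn
#' from the supplied strength model, so each site's true usage is an exact
#' function of its hexamer. Minus-strand genes are reverse-complemented into
#' the forward-strand sequence; all returned coordinates are 1-based genomic.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param model a \linkS4class{TrueStrengthModel}.
#' @param hexamer_weighting "strength" (sampling probability proportional to
#'   true strength, mirroring the observed strength-frequency association) or
#'   "uniform".
#' @param exon_length_range min/max exon length (bp).
#' @param genes_per_chrom genes placed per chromosome.
#' @return list with \code{genome} (\link[Biostrings]{DNAStringSet}),
#'   \code{sites} (GRanges of 1-bp anchors with site_id, site_type, gene_id,
#'   hexamer, true_strength) and \code{genes} (GRanges of gene bodies).
#' @export
generateGenome <- function(config, model,
                           hexamer_weighting = c("strength", "uniform"),
                           exon_length_range = c(80L, 160L),
                           genes_per_chrom = 20L) {
  hexamer_weighting <- match.arg(hexamer_weighting)
  methods::validObject(config)
  methods::validObject(model)
  if (config@intron_length_range[1] < 20) {
    stop("intron_length_range too small: introns must hold two hexamers ",
         "plus interior clearance (>= 20 bp)", call. = FALSE)
  }
  set.seed(config@seed)
  dmap <- strengthMap(model, "donor")
  amap <- strengthMap(model, "acceptor")
  wt <- function(m) if (hexamer_weighting == "strength") m + 0.02 else
    rep(1, length(m))

  n_genes <- config@n_genes
  n_int <- config@introns_per_gene
  gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  chrom_of <- paste0("chr", (seq_len(n_genes) - 1) %/% genes_per_chrom + 1)

  site_rows <- vector("list", n_genes)
  gene_rows <- vector("list", n_genes)
  chrom_parts <- split(vector("list", 0), NULL)
  chrom_seq <- list()
  chrom_cursor <- list()

  for (g in seq_len(n_genes)) {
    ex_len <- sample(seq(exon_length_range[1], exon_length_range[2]),
                     n_int + 1, replace = TRUE)
    in_len <- sample(seq(config@intron_length_range[1],
                         config@intron_length_range[2]),
                     n_int, replace = TRUE)
    L <- sum(ex_len) + sum(in_len)
    seq_t <- randomBases(L)                       # transcribed orientation
    don_hex <- sample(names(dmap), n_int, replace = TRUE, prob = wt(dmap))
    acc_hex <- sample(names(amap), n_int, replace = TRUE, prob = wt(amap))
    don_off <- integer(n_int); acc_off <- integer(n_int)
    cursor <- 0L
    for (i in seq_len(n_int)) {
      cursor <- cursor + ex_len[i]
      s <- cursor + 1L; e <- cursor + in_len[i]
      seq_t[s:(s + 5L)] <- strsplit(don_hex[i], "")[[1]]
      seq_t[(e - 5L):e] <- strsplit(acc_hex[i], "")[[1]]
      don_off[i] <- s; acc_off[i] <- e
      cursor <- e
    }
    chrom <- chrom_of[g]
    if (is.null(chrom_cursor[[chrom]])) {
      chrom_cursor[[chrom]] <- 100L
      chrom_seq[[chrom]] <- list(paste(randomBases(100L), collapse = ""))
    }
    gene_start <- chrom_cursor[[chrom]] + 1L
    strand <- gene_strand[g]
    ins <- paste(seq_t, collapse = "")
    if (strand == "-") ins <- revcompChar(ins)
    gap <- paste(randomBases(200L), collapse = "")
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]], list(ins, gap))
    chrom_cursor[[chrom]] <- chrom_cursor[[chrom]] + L + 200L
    ## transcribed offset o (1-based) -> genomic position
    g_of <- function(o) if (strand == "+") gene_start + o - 1L else
      gene_start + L - o
    gene_id <- sprintf("gene%04d", g)
    site_rows[[g]] <- data.frame(
      chrom = chrom,
      position = c(vapply(don_off, g_of, integer(1)),
                   vapply(acc_off, g_of, integer(1))),
      strand = strand,
      site_type = rep(c("donor", "acceptor"), each = n_int),
      gene_id = gene_id,
      hexamer = c(don_hex, acc_hex),
      true_strength = c(unname(dmap[don_hex]), unname(amap[acc_hex])),
      stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(chrom = chrom, start = gene_start,
                                 end = gene_start + L - 1L, strand = strand,
                                 gene_id = gene_id, stringsAsFactors = FALSE)
  }

  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$position), ]
  sites$site_id <- sprintf("s%05d", seq_len(nrow(sites)))
  genes <- do.call(rbind, gene_rows)

  genome <- Biostrings::DNAStringSet(vapply(
    chrom_seq, function(p) paste(unlist(p), collapse = ""), character(1)))
  names(genome) <- names(chrom_seq)

  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position, width = 1L),
    strand = sites$strand,
    site_id = sites$site_id, site_type = sites$site_type,
    gene_id = sites$gene_id, hexamer = sites$hexamer,
    true_strength = sites$true_strength)
  names(site_gr) <- sites$site_id
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand, gene_id = genes$gene_id)
  names(gene_gr) <- genes$gene_id

  list(genome = genome, sites = site_gr, genes = gene_gr)
}
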