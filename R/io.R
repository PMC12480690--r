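## BED (0-based half-open) <-> 1-based intron coordinates.
## A junction record [start, end) covers the intron whose first base is
## start+1 and last base is end (1-based).
bedToIntron <- function(start0, end0) {
  cbind(first = start0 + 1L, last = end0)
}
intronToBed <- function(first1, last1) {
  cbind(start = first1 - 1L, end = last1)
}

#' Read a splice-junction BED file
#'
#' Parses 6+-column BED junction records (0-based half-open) into 1-based
#' intron coordinates: the donor-adjacent (first) and acceptor-adjacent
#' (last) intron bases. BED12 junction dialects where the two block sizes
#' encode anchor lengths around the gap (regtools-style) are recognised and
#' the blocks are subtracted. Malformed lines (non-numeric count,
#' start >= end, bad strand) are reported with their line number; in strict
#' mode the first error aborts, otherwise bad lines are skipped with a
#' warning.
#'
#' @param path BED file path.
#' @param strict abort on the first malformed line (default TRUE).
#' @return data.frame with chrom, donor_adjacent, acceptor_adjacent, name,
#'   count, strand.
#' @export
readJunctionBed <- function(path, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- function(ln, why) {
    msg <- sprintf("line %d: %s", ln, why)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    NULL
  }
  rows <- lapply(seq_along(fields), function(ln) {
    f <- fields[[ln]]
    if (length(f) < 6) return(bad(ln, "fewer than 6 columns"))
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    count <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start0) || is.na(end0)) return(bad(ln, "non-numeric coordinate"))
    if (is.na(count)) return(bad(ln, "non-numeric count"))
    if (start0 >= end0) return(bad(ln, "start >= end"))
    if (!f[6] %in% c("+", "-", ".")) return(bad(ln, "invalid strand"))
    if (length(f) >= 12) {
      sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
      if (length(sizes) == 2 && !anyNA(sizes)) {
        start0 <- start0 + sizes[1]
        end0 <- end0 - sizes[2]
        if (start0 >= end0) return(bad(ln, "blocks leave an empty gap"))
      }
    }
    iv <- bedToIntron(start0, end0)
    data.frame(chrom = f[1], donor_adjacent = iv[, "first"],
               acceptor_adjacent = iv[, "last"], name = f[4], count = count,
               strand = f[6], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), donor_adjacent = integer(0),
                      acceptor_adjacent = integer(0), name = character(0),
                      count = numeric(0), strand = character(0))
  }
  out
}

#' Write splice-junction records as 6-column BED
#'
#' The inverse of \code{\link{readJunctionBed}}: 1-based intron coordinates
#' become 0-based half-open BED intervals.
#'
#' @param junctions data.frame with chrom, donor_adjacent, acceptor_adjacent,
#'   name, count, strand.
#' @param path output file.
#' @export
writeJunctionBed <- function(junctions, path) {
  iv <- intronToBed(junctions$donor_adjacent, junctions$acceptor_adjacent)
  writeLines(paste(junctions$chrom, iv[, "start"], iv[, "end"],
                   junctions$name, junctions$count, junctions$strand,
                   sep = "\t"), path)
}

#' Schema-checked TSV writing and reading
#'
#' TSVs with a header row, UTF-8, "." decimal separator and stable column
#' order. On read, mandatory columns are checked by name (a missing column is
#' an error naming it); unknown extra columns are preserved with a warning.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
writeTableChecked <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' @rdname writeTableChecked
#' @param required character vector of mandatory column names.
#' @param col_classes optional named vector of column classes to enforce.
#' @return the data.frame read from \code{path}.
#' @export
readTableChecked <- function(path, required = character(0),
                             col_classes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(colnames(df), required)
  if (length(required) > 0 && length(extra) > 0) {
    warning("extra column(s) preserved: ", paste(extra, collapse = ", "))
  }
  if (!is.null(col_classes)) {
    for (nm in names(col_classes)) {
      df[[nm]] <- methods::as(df[[nm]], col_classes[[nm]])
    }
  }
  df
}

#' Write simulated variants as VCF v4.2
#'
#' Minimal biallelic SNP VCF with GT genotypes: haploid "0"/"1" for inbred
#' panels, diploid "0/0"/"0/1"/"1/1" otherwise.
#'
#' @param variants variant table from \code{\link{simulateGenotypes}}.
#' @param dosages variants x genotypes dosage matrix.
#' @param ploidy 1 (inbred) or 2 (diploid).
#' @param path output VCF path.
#' @export
writeVcf42 <- function(variants, dosages, ploidy, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=splicehex-synthio",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(dosages)), collapse = "\t"))
  gt <- if (ploidy == 1) {
    matrix(as.character(dosages), nrow(dosages))
  } else {
    matrix(c("0/0", "0/1", "1/1")[dosages + 1L], nrow(dosages))
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS",
            sprintf("AF=%.4f", variants$maf[i]), "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' Write a full synthetic data bundle to disk
#'
#' Emits the genome FASTA, site annotation TSV (1-based positions), gene TSV,
#' VCF v4.2, a per-site crossing-count TSV (long format) and one junction BED
#' per sample (introns as 0-based half-open intervals; the junction count is
#' the donor's supporting count).
#'
#' @param synth \code{\link{generateGenome}} output.
#' @param geno \code{\link{simulateGenotypes}} output.
#' @param sse an \linkS4class{SSEExperiment}.
#' @param dir output directory (created).
#' @return invisible character vector of written paths.
#' @export
writeSynthBundle <- function(synth, geno, sse, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "junctions"), showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "sites.tsv"),
             genes = file.path(dir, "genes.tsv"),
             vcf = file.path(dir, "variants.vcf"),
             crossing = file.path(dir, "crossing_counts.tsv"))
  Biostrings::writeXStringSet(synth$genome, paths["genome"])
  writeTableChecked(siteTable(synth$sites), paths["annotation"])
  g <- as.data.frame(synth$genes)
  writeTableChecked(data.frame(gene_id = g$gene_id,
                               chrom = as.character(g$seqnames),
                               start = g$start, end = g$end,
                               strand = as.character(g$strand)),
                    paths["genes"])
  writeVcf42(geno$variants, geno$dosages, geno$ploidy, paths["vcf"])
  al <- alphaCounts(sse); be <- betaCounts(sse)
  long <- data.frame(site_id = rep(rownames(al), ncol(al)),
                     sample = rep(colnames(al), each = nrow(al)),
                     alpha = as.vector(al), beta = as.vector(be))
  writeTableChecked(long, paths["crossing"])
  ## per-sample junction BEDs: one record per intron, donor-supporting count
  st <- siteTable(SummarizedExperiment::rowRanges(sse))
  don <- st[st$site_type == "donor", ]
  acc <- st[st$site_type == "acceptor", ]
  don <- don[order(don$gene_id, ifelse(don$strand == "+", 1, -1) *
                     don$position), ]
  acc <- acc[order(acc$gene_id, ifelse(acc$strand == "+", 1, -1) *
                     acc$position), ]
  ## introns pair in transcribed order within each gene
  first <- ifelse(don$strand == "+", don$position, acc$position)
  last <- ifelse(don$strand == "+", acc$position, don$position)
  for (smp in colnames(al)) {
    jx <- data.frame(chrom = don$chrom, donor_adjacent = first,
                     acceptor_adjacent = last,
                     name = paste0(don$gene_id, "_i",
                                   ave(don$position, don$gene_id,
                                       FUN = seq_along)),
                     count = al[don$site_id, smp], strand = don$strand)
    writeJunctionBed(jx, file.path(dir, "junctions", paste0(smp, ".bed")))
  }
  invisible(paths)
}
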