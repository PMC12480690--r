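#' SSEExperiment: splice-site usage counts and estimates
#'
#' An S4 container for per-site, per-sample splice-site usage data. It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are individual splice-sites
#' (1-bp anchors: the intron-terminal "G" of the donor GT or acceptor AG),
#' columns are RNA-seq samples. Two assays are mandatory: \code{alpha}
#' (junction reads that use the site) and \code{beta} (reads crossing the site
#' position without using it). The splice-site strength estimate is
#' SSE = alpha / (alpha + beta), undefined where no read crosses the site.
#'
#' Column data must carry \code{genotype} and \code{replicate}; an optional
#' \code{stratum} column (e.g. sex or tissue) splits downstream averaging.
#' Row ranges must carry \code{site_id} (unique), \code{site_type}
#' ("donor"/"acceptor") and \code{gene_id}.
#'
#' @aliases SSEExperiment-class
#' @exportClass SSEExperiment
setClass("SSEExperiment", contains = "RangedSummarizedExperiment")

setValidity("SSEExperiment", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("alpha", "beta") %in% a)) {
    return("assays 'alpha' and 'beta' are required")
  }
  al <- SummarizedExperiment::assay(object, "alpha")
  be <- SummarizedExperiment::assay(object, "beta")
  if (anyNA(al) || anyNA(be)) return("count assays must not contain NA")
  if (any(al < 0) || any(be < 0)) return("counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("genotype", "replicate") %in% colnames(cd))) {
    return("colData must have 'genotype' and 'replicate'")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("site_id", "site_type", "gene_id") %in% colnames(mc))) {
    return("rowRanges mcols must have site_id, site_type, gene_id")
  }
  if (anyDuplicated(mc$site_id)) return("site_id values must be unique")
  if (!all(mc$site_type %in% c("donor", "acceptor"))) {
    return("site_type must be 'donor' or 'acceptor'")
  }
  TRUE
})

#' Construct an SSEExperiment
#'
#' @param alpha integer matrix of junction (supporting) read counts,
#'   sites x samples.
#' @param beta integer matrix of non-supporting crossing read counts, same
#'   dimensions as \code{alpha}.
#' @param sites \link[GenomicRanges]{GRanges} of 1-bp site anchors with mcols
#'   \code{site_id}, \code{site_type}, \code{gene_id} (one row per row of
#'   \code{alpha}).
#' @param genotype,replicate character/integer vectors, one entry per sample
#'   column.
#' @param stratum optional per-sample stratum labels (sex, tissue).
#' @return An \linkS4class{SSEExperiment}.
#' @export
SSEExperiment <- function(alpha, beta, sites, genotype, replicate,
                          stratum = NULL) {
  stopifnot2(all(dim(alpha) == dim(beta)),
             "alpha and beta must have identical dimensions")
  stopifnot2(length(sites) == nrow(alpha),
             "one site per row of the count matrices is required")
  cd <- S4Vectors::DataFrame(genotype = as.character(genotype),
                             replicate = as.character(replicate))
  if (!is.null(stratum)) cd$stratum <- as.character(stratum)
  if (is.null(colnames(alpha))) {
    colnames(alpha) <- colnames(beta) <-
      paste(cd$genotype, cd$replicate, sep = ".")
  }
  names(sites) <- S4Vectors::mcols(sites)$site_id
  rownames(alpha) <- rownames(beta) <- names(sites)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alpha = alpha, beta = beta),
    rowRanges = sites, colData = cd)
  methods::new("SSEExperiment", se)
}

#' @describeIn SSEExperiment junction-read (supporting) count matrix
#' @param x an SSEExperiment
#' @export
alphaCounts <- function(x) SummarizedExperiment::assay(x, "alpha")

#' @describeIn SSEExperiment non-supporting crossing-read count matrix
#' @export
betaCounts <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn SSEExperiment total crossing reads (alpha + beta)
#' @export
crossingTotals <- function(x) alphaCounts(x) + betaCounts(x)

#' @describeIn SSEExperiment per-site, per-sample SSE matrix; NA where the
#'   crossing total is zero
#' @export
sseValues <- function(x) computeSSE(alphaCounts(x), betaCounts(x))

#' @describeIn SSEExperiment site annotation as a data.frame (site_id, chrom,
#'   position, strand, site_type, gene_id, plus any generator truth columns)
#' @export
siteData <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  df <- data.frame(site_id = S4Vectors::mcols(rr)$site_id,
                   chrom = as.character(GenomicRanges::seqnames(rr)),
                   position = GenomicRanges::start(rr),
                   strand = as.character(GenomicRanges::strand(rr)),
                   stringsAsFactors = FALSE)
  extra <- as.data.frame(S4Vectors::mcols(rr))
  cbind(df, extra[, setdiff(colnames(extra), "site_id"), drop = FALSE])
}

#' @describeIn SSEExperiment genotype label of each sample column
#' @export
genotypeIds <- function(x) SummarizedExperiment::colData(x)$genotype

setMethod("show", "SSEExperiment", function(object) {
  st <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$site_type
  cat("SSEExperiment:", nrow(object), "splice-sites (",
      sum(st == "donor"), "donors,", sum(st == "acceptor"), "acceptors ) x",
      ncol(object), "samples\n")
  cat("  genotypes:", length(unique(genotypeIds(object))),
      " assays: alpha, beta\n")
  tot <- crossingTotals(object)
  cat("  median crossing depth:", stats::median(tot), "; zero-coverage cells:",
      sum(tot == 0), "\n")
  invisible(NULL)
})

#' Compute the splice-site strength estimate from a count pair
#'
#' SSE = alpha / (alpha + beta): the fraction of reads crossing a splice-site
#' position that are spliced at it. Vectorised; returns NA (never 0/0) where
#' alpha + beta is zero.
#'
#' @param alpha supporting junction read count(s).
#' @param beta non-supporting crossing read count(s).
#' @return numeric in [0, 1], NA where total coverage is zero.
#' @examples
#' computeSSE(7, 3)   # 0.7
#' computeSSE(0, 0)   # NA
#' @export
computeSSE <- function(alpha, beta) {
  stopifnot2(all(alpha >= 0) && all(beta >= 0), "counts must be non-negative")
  tot <- alpha + beta
  out <- alpha / tot
  out[tot == 0] <- NA_real_
  out
}
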