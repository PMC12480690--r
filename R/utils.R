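DNA_BASES <- c("A", "C", "G", "T")

clamp01 <- function(x) pmin(1, pmax(0, x))

compChar <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

## reverse-complement plain character vectors (Biostrings objects use
## reverseComplement() directly)
revcompChar <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(compChar(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

randomBases <- function(n) sample(DNA_BASES, n, replace = TRUE)

## genomic coordinate of a transcribed-strand offset relative to an anchor
genomicAt <- function(pos, strand, offset) {
  ifelse(strand == "+", pos + offset, pos - offset)
}

## transcribed-strand base(s) at given genomic positions of one chromosome
## sequence (character); complements on the minus strand
transcribedBase <- function(chromSeq, pos, strand) {
  b <- substring(chromSeq, pos, pos)
  ifelse(strand == "-", compChar(b), b)
}

harmonicMean <- function(x) length(x) / sum(1 / x)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
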