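## Independent brute-force oracles, deliberately written with naive loops and
## base-by-base string handling so they share no code path with the package.

## two-pass sums-of-squares proportion of variance
oraclePropVar <- function(values, groups) {
  gmean <- sum(values) / length(values)
  tss <- 0
  for (v in values) tss <- tss + (v - gmean)^2
  if (tss == 0) return(0)
  rss <- 0
  for (g in unique(groups)) {
    vg <- values[groups == g]
    mg <- sum(vg) / length(vg)
    for (v in vg) rss <- rss + (v - mg)^2
  }
  (tss - rss) / tss
}

## naive window enumerator for the choice-explanation statistic
oracleChoiceExplained <- function(genome, sites, table, k, site_type,
                                  window) {
  chr <- as.character(genome)
  st <- as.data.frame(sites)
  st <- data.frame(site_id = st$site_id,
                   chrom = as.character(st$seqnames), position = st$start,
                   strand = as.character(st$strand),
                   site_type = st$site_type, stringsAsFactors = FALSE)
  used <- st[st$site_type == site_type, ]
  baseAt <- function(ch, pos, strand) {
    if (pos < 1 || pos > nchar(chr[[ch]])) return(NA_character_)
    b <- substr(chr[[ch]], pos, pos)
    if (strand == "-") c(A = "T", C = "G", G = "C", T = "A")[[b]] else b
  }
  ## transcribed-strand key anchored at genomic position gpos
  keyAt <- function(ch, gpos, strand, type) {
    offs <- if (type == "donor") 0:(k - 1) else -(k - 1):0
    out <- character(length(offs))
    for (i in seq_along(offs)) {
      p <- if (strand == "+") gpos + offs[i] else gpos - offs[i]
      b <- baseAt(ch, p, strand)
      if (is.na(b)) return(NA_character_)
      out[i] <- b
    }
    paste(out, collapse = "")
  }
  results <- data.frame()
  for (i in seq_len(nrow(used))) {
    ## proximity exclusion among used sites of the same type
    excluded <- FALSE
    for (j in seq_len(nrow(used))) {
      if (j == i) next
      if (used$chrom[j] == used$chrom[i] &&
          abs(used$position[j] - used$position[i]) <= window) {
        excluded <- TRUE; break
      }
    }
    if (excluded) next
    ch <- used$chrom[i]; pos <- used$position[i]; strand <- used$strand[i]
    cand_pos <- integer(0); cand_key <- character(0)
    tbase <- function(rel_off) {  # transcribed base at site-relative offset
      baseAt(ch, if (strand == "+") pos + rel_off else pos - rel_off, strand)
    }
    for (rel in -window:window) {
      ## donor anchor: G of GT (offsets rel, rel+1); acceptor anchor: G of AG
      ## (offsets rel-1, rel), both on the transcribed strand
      if (site_type == "donor") {
        if (!identical(tbase(rel), "G") ||
            !identical(tbase(rel + 1), "T")) next
      } else {
        if (!identical(tbase(rel - 1), "A") ||
            !identical(tbase(rel), "G")) next
      }
      gpos <- if (strand == "+") pos + rel else pos - rel
      key <- keyAt(ch, gpos, strand, site_type)
      if (is.na(key)) next
      cand_pos <- c(cand_pos, rel); cand_key <- c(cand_key, key)
    }
    ranks <- numeric(length(cand_key))
    for (m in seq_along(cand_key)) {
      hit <- which(table$key == cand_key[m])
      ranks[m] <- if (length(hit) == 1) table$rank[hit] else Inf
    }
    best <- min(ranks)
    success <- is.finite(best) && sum(ranks == best) == 1 &&
      cand_pos[which(ranks == best)] == 0
    results <- rbind(results,
                     data.frame(site_id = used$site_id[i],
                                n_candidates = length(cand_key),
                                success = success,
                                stringsAsFactors = FALSE))
  }
  raw <- if (nrow(results) > 0) sum(results$success) / nrow(results) else
    NA_real_
  list(n_sites_tested = nrow(results), n_success = sum(results$success),
       raw_rate = raw,
       possible_fraction = min(1, nrow(table) / 4^(k - 2)),
       adjusted_percent = raw * min(1, nrow(table) / 4^(k - 2)) * 100,
       detail = results)
}
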