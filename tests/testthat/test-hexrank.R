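test_that("possible key enumeration is 4^(k-2) with fixed anchors", {
  expect_length(possibleKeys("donor", 4), 16)
  expect_length(possibleKeys("donor", 6), 256)
  expect_length(possibleKeys("donor", 8), 4096)
  expect_length(possibleKeys("acceptor", 6), 256)
  expect_true(all(startsWith(possibleKeys("donor", 6), "GT")))
  expect_true(all(endsWith(possibleKeys("acceptor", 6), "AG")))
  expect_false(anyDuplicated(possibleKeys("donor", 8)) > 0)
})

test_that("site k-mers are extracted strand-aware with substitutions", {
  ## + strand donor: context ...CAG|GTAAGC... read off directly
  genome <- mkGenome(chr1 = paste0(strrep("A", 17), "CAGGTAAGC",
                                   strrep("A", 14)))
  site <- mkSites("chr1", 21, "+", "donor", site_id = "d1")
  expect_equal(siteKmers(genome, site, 6)$key, "GTAAGC")
  ## - strand donor whose forward context reads ...GCTTAC|CTG...
  genome2 <- mkGenome(chr1 = paste0(strrep("A", 10), "GCTTACCTG",
                                    strrep("A", 10)))
  site2 <- mkSites("chr1", 16, "-", "donor", site_id = "d2")
  expect_equal(siteKmers(genome2, site2, 6)$key, "GTAAGC")
  ## SNP at donor offset +2 (A -> C) turns GTAAGC into GTCAGC
  sub <- data.frame(chrom = "chr1", pos = 23, alt = "C")
  expect_equal(siteKmers(genome, site, 6, substitutions = sub)$key, "GTCAGC")
  ## acceptor anchored at the G of AG
  genome3 <- mkGenome(chr1 = paste0(strrep("C", 10), "TTGCAG", strrep("C", 10)))
  site3 <- mkSites("chr1", 16, "+", "acceptor", site_id = "a1")
  expect_equal(siteKmers(genome3, site3, 6)$key, "TTGCAG")
  ## annotation/genome mismatch is flagged, not silently kept
  site_bad <- mkSites("chr1", 5, "+", "donor", site_id = "bad")
  expect_false(siteKmers(genome, site_bad, 6)$anchored)
})

test_that("strength tables average site strengths and rank deterministically", {
  genome <- mkGenome(chr1 = paste0(
    strrep("C", 20), "GTAAGT", strrep("C", 50), "GTAAGT",
    strrep("C", 50), "GTCCGA", strrep("C", 20)))
  sites <- mkSites("chr1", c(21, 77, 133), "+", "donor",
                   site_id = c("s1", "s2", "s3"))
  strength <- c(s1 = 0.6, s2 = 0.8, s3 = 0.2)
  tab <- strengthTable(sites, genome, strength, 6, "donor")
  expect_equal(tab$mean_sse[tab$key == "GTAAGT"], 0.7)
  expect_equal(tab$n_sites[tab$key == "GTAAGT"], 2)
  expect_equal(tab$rank[tab$key == "GTAAGT"], 1)
  expect_lte(nrow(tab), 256)
  ## ties break by larger n_sites then lexicographic key
  tie <- strengthTable(
    mkSites("chr1", c(21, 77, 133), "+", "donor",
            site_id = c("s1", "s2", "s3")),
    genome, c(s1 = 0.5, s2 = 0.5, s3 = 0.5), 6, "donor")
  expect_equal(tie$key[tie$rank == 1], "GTAAGT")  # n = 2 beats n = 1
})

test_that("choice explanation scores unique best-ranked keys only", {
  ## background alternating AC cannot create spurious GT/AG
  bg <- function(n) strrep("AC", ceiling(n / 2))
  ## used donor GTAAAA at 151; competing GT with weaker key at 101
  chrom <- paste0(substr(bg(100), 1, 100), "GTCCCC",
                  substr(bg(44), 1, 44), "GTAAAA", substr(bg(150), 1, 150))
  genome <- mkGenome(chr1 = chrom)
  sites <- mkSites("chr1", 151, "+", "donor", site_id = "u1")
  tab <- data.frame(key = c("GTAAAA", "GTCCCC"), n_sites = c(5, 5),
                    mean_sse = c(0.9, 0.2), rank = c(1, 2))
  ce <- choiceExplained(genome, sites, tab, k = 6, site_type = "donor",
                        window = 100)
  expect_equal(ce$n_sites_tested, 1)
  expect_equal(ce$n_success, 1)
  ## same key at a second GT in the window: uniqueness fails
  chrom2 <- paste0(substr(bg(100), 1, 100), "GTAAAA",
                   substr(bg(44), 1, 44), "GTAAAA", substr(bg(150), 1, 150))
  ce2 <- choiceExplained(mkGenome(chr1 = chrom2), sites, tab, k = 6,
                         site_type = "donor", window = 100)
  expect_equal(ce2$n_success, 0)
  ## the used site's key ranked below a competitor: failure
  tab_rev <- tab; tab_rev$rank <- c(2, 1)
  ce3 <- choiceExplained(genome, sites, tab_rev, k = 6,
                         site_type = "donor", window = 100)
  expect_equal(ce3$n_success, 0)
  ## two used donors within the window exclude each other
  sites2 <- mkSites("chr1", c(101, 151), "+", "donor",
                    site_id = c("u0", "u1"))
  ce4 <- choiceExplained(genome, sites2, tab, k = 6, site_type = "donor",
                         window = 100)
  expect_equal(ce4$n_sites_tested, 0)
})

test_that("choice explanation equals the naive enumerator on synthetic data", {
  dat <- synthSmall()
  strength <- setNames(as.data.frame(dat$synth$sites)$true_strength,
                       names(dat$synth$sites))
  for (type in c("donor", "acceptor")) {
    tab <- strengthTable(dat$synth$sites, dat$synth$genome, strength, 6, type)
    ce <- choiceExplained(dat$synth$genome, dat$synth$sites, tab, 6, type, 100)
    oc <- oracleChoiceExplained(dat$synth$genome, dat$synth$sites, tab, 6,
                                type, 100)
    expect_identical(ce$detail, oc$detail)
    expect_identical(ce$raw_rate, oc$raw_rate)
    expect_identical(ce$adjusted_percent, oc$adjusted_percent)
  }
})

test_that("rank correlations square the Spearman coefficient", {
  tabA <- data.frame(key = possibleKeys("donor", 4), n_sites = 1,
                     mean_sse = seq(0.9, 0.1, length.out = 16))
  tabA$rank <- rank(-tabA$mean_sse)
  expect_equal(rankCorrelation(tabA, tabA)$r2, 1)
  ## reversed ranking: R^2 = 1 with negative underlying correlation
  tabB <- tabA; tabB$mean_sse <- rev(tabB$mean_sse)
  rc <- rankCorrelation(tabA, tabB)
  expect_equal(rc$r2, 1)
  expect_equal(rc$rho, -1)
  ## too few shared keys
  expect_warning(rc2 <- rankCorrelation(tabA[1:3, ], tabA[1:3, ]),
                 "shared keys")
  expect_true(is.na(rc2$r2))
  ## matrix form is symmetric with unit diagonal
  m <- rankCorrelationMatrix(list(a = tabA, b = tabB))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m["a", "b"], m["b", "a"])
})

test_that("p-distance is a metric and profiles recover planted decay", {
  expect_equal(pDistance("GTAAGT", "GTAAGT"), 0)
  expect_equal(pDistance("GTCAGT", "GTAAGT"), 1 / 6)
  keys <- possibleKeys("donor", 6)
  set.seed(19)
  for (i in 1:200) {
    tri <- sample(keys, 3)
    d12 <- pDistance(tri[1], tri[2]); d13 <- pDistance(tri[1], tri[3])
    d23 <- pDistance(tri[2], tri[3])
    expect_equal(d12, pDistance(tri[2], tri[1]))      # symmetric
    expect_lte(d13, d12 + d23)                        # triangle
    expect_equal(d12 == 0, tri[1] == tri[2])          # identity
  }
  ## the default model's strength decays with distance from the consensus
  dm <- strengthMap(defaultStrengthModel(3), "donor")
  tab <- data.frame(key = names(dm), n_sites = 1, mean_sse = unname(dm))
  tab$rank <- rank(-tab$mean_sse)
  prof <- pDistanceProfile(tab, "GTAAGT")
  expect_lt(prof$correlation, -0.9)
  expect_equal(prof$groups$distance[1], 0)
})

test_that("occurrence profiling splits used from unused occurrences", {
  ## gene where the only GT occurrences are used donors
  bg <- function(n) substr(strrep("AC", n), 1, n)
  chrom <- paste0(bg(100), "GTAAAA", bg(100), "GTCCCC", bg(100))
  genome <- mkGenome(chr1 = chrom)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, nchar(chrom)),
                                  strand = "+", gene_id = "g1")
  sites <- mkSites("chr1", c(101, 207), "+", "donor",
                   site_id = c("s1", "s2"))
  tab <- data.frame(key = c("GTAAAA", "GTCCCC"), n_sites = 1,
                    mean_sse = c(0.8, 0.3), rank = 1:2)
  op <- occurrenceProfile(genome, genes, sites, tab, 6, "donor")
  expect_equal(sum(op$counts$unused), 0)
  expect_equal(sum(op$counts$used), 2)
  ## synthetic transcriptome: used-occurrence proportions track strength,
  ## unused occurrences do not
  dat <- synthSmall()
  strength <- setNames(as.data.frame(dat$synth$sites)$true_strength,
                       names(dat$synth$sites))
  tab2 <- strengthTable(dat$synth$sites, dat$synth$genome, strength, 6,
                        "donor")
  op2 <- occurrenceProfile(dat$synth$genome, dat$synth$genes,
                           dat$synth$sites, tab2, 6, "donor")
  expect_gt(op2$cor_used, op2$cor_unused)
})

test_that("competing pairs are explained by concordant strength tables", {
  tab <- data.frame(key = c("GTAAAA", "GTCCCC"), n_sites = 5,
                    mean_sse = c(0.7, 0.2), rank = 1:2)
  pairs <- data.frame(construct_id = c("c1", "c2"),
                      key_a = "GTAAAA", key_b = "GTCCCC",
                      sse_a = c(0.9, 0.1), sse_b = c(0.1, 0.9))
  cp <- competingPairAnalysis(pairs, tab, n_perm = 100, seed = 1)
  ## c1 concordant (winner has stronger key), c2 discordant
  expect_equal(cp$overall$explained_fraction, 0.5)
  expect_equal(cp$overall$n_pairs, 2)
  ## ties are excluded from numerator and denominator
  pairs2 <- rbind(pairs, data.frame(construct_id = "c3", key_a = "GTAAAA",
                                    key_b = "GTCCCC", sse_a = 0.5,
                                    sse_b = 0.5))
  cp2 <- competingPairAnalysis(pairs2, tab, n_perm = 100, seed = 1)
  expect_equal(cp2$overall$n_pairs, 2)
  ## permutation threshold is bit-reproducible under a fixed seed
  dat <- synthSmall()
  lib <- simulateMinigeneLibrary(dat$model, n_constructs = 400, seed = 3)
  dtab <- data.frame(key = names(strengthMap(dat$model, "donor")),
                     n_sites = 1,
                     mean_sse = unname(strengthMap(dat$model, "donor")))
  dtab <- dtab[order(-dtab$mean_sse), ]; dtab$rank <- seq_len(nrow(dtab))
  a <- competingPairAnalysis(lib$pairs, dtab, n_perm = 500, seed = 11)
  b <- competingPairAnalysis(lib$pairs, dtab, n_perm = 500, seed = 11)
  expect_identical(a$overall$perm_threshold, b$overall$perm_threshold)
  expect_identical(a$null_fractions, b$null_fractions)
  ## with the true table, most pairs are explained, more so at large gaps
  expect_gt(a$overall$explained_fraction, 0.6)
  big <- a$by_gap$explained_fraction[a$by_gap$bin == "(0.25,1]"]
  small <- a$by_gap$explained_fraction[a$by_gap$bin == "[0,0.25]"]
  expect_gt(big, small)
})
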