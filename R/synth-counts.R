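#' Simulate replicated junction/crossing counts from true usage
#'
#' For each site, genotype and replicate the crossing total n is drawn from a
#' negative binomial with mean \code{read_depth_mean} (Poisson when the
#' dispersion is 0); the supporting count alpha ~ Binomial(n, p) with
#' p = clamp(truth + genotype effect + replicate noise, 0, 1). The genotype
#' effect is drawn once per site x genotype and shared across that genotype's
#' replicates, which is what generates broad-sense heritability downstream;
#' replicate noise is drawn independently per sample.
#'
#' @param truth sites x genotypes matrix of true SSE (e.g.
#'   \code{\link{trueSSETable}}).
#' @param config a \linkS4class{SynthConfig}.
#' @param sites GRanges of the sites (rows of \code{truth}).
#' @return An \linkS4class{SSEExperiment} with
#'   \code{n_genotypes * replicates_per_genotype} sample columns.
#' @export
simulateJunctionCounts <- function(truth, config, sites) {
  stopifnot2(all(truth >= 0 & truth <= 1), "truth values must be in [0, 1]")
  set.seed(config@seed + 2L)
  nS <- nrow(truth); nG <- ncol(truth)
  reps <- config@replicates_per_genotype
  g_eff <- matrix(stats::rnorm(nS * nG, 0, config@genotype_sd), nS, nG)
  idx <- rep(seq_len(nG), each = reps)
  P <- truth[, idx, drop = FALSE] + g_eff[, idx, drop = FALSE] +
    matrix(stats::rnorm(nS * nG * reps, 0, config@residual_sd), nS)
  P <- clamp01(P)
  ncell <- length(P)
  N <- if (config@depth_dispersion > 0) {
    stats::rnbinom(ncell, mu = config@read_depth_mean,
                   size = 1 / config@depth_dispersion)
  } else {
    stats::rpois(ncell, config@read_depth_mean)
  }
  N <- matrix(N, nS)
  alpha <- matrix(stats::rbinom(ncell, as.vector(N), as.vector(P)), nS)
  beta <- N - alpha
  genotype <- colnames(truth)[idx]
  replicate <- rep(seq_len(reps), times = nG)
  colnames(alpha) <- colnames(beta) <- paste(genotype, replicate, sep = ".r")
  SSEExperiment(alpha, beta, sites, genotype = genotype,
                replicate = replicate)
}

#' Simulate a minigene library with two competing donor sites
#'
#' Each construct is one reporter intron carrying two candidate donors with
#' hexamers drawn from a pool; a single shared acceptor closes the intron.
#' Reads split between the two donor junctions in proportion to a logistic
#' contrast of the donors' true strengths, with optional Gaussian noise on the
#' logit scale, so with no noise the stronger donor wins every construct and
#' equal strengths split reads 50/50.
#'
#' @param model a \linkS4class{TrueStrengthModel}.
#' @param n_constructs number of constructs.
#' @param hexamer_pool donor hexamers to draw from (default: all 256).
#' @param noise_sd logit-scale noise standard deviation.
#' @param depth crossing reads per construct.
#' @param scale logistic slope applied to the strength difference.
#' @param donor_spacing bp between the two donor anchors (must exceed the
#'   hexamer span).
#' @param seed integer seed.
#' @return list with \code{constructs} (\link[Biostrings]{DNAStringSet}) and
#'   \code{pairs}: one row per construct with key_a/key_b, the planted
#'   strengths, read counts and the two sites' SSE values.
#' @export
simulateMinigeneLibrary <- function(model, n_constructs = 500L,
                                    hexamer_pool = NULL, noise_sd = 0.3,
                                    depth = 100L, scale = 6,
                                    donor_spacing = 40L, seed = 1L) {
  if (donor_spacing < 6L) {
    stop("competing donors closer than the hexamer span are rejected",
         call. = FALSE)
  }
  set.seed(seed)
  dmap <- strengthMap(model, "donor")
  if (is.null(hexamer_pool)) hexamer_pool <- names(dmap)
  stopifnot2(all(hexamer_pool %in% names(dmap)),
             "hexamer_pool entries must be donor hexamers (GT....)")
  exon1 <- 50L; intron_tail <- 60L
  pos_a <- exon1 + 1L
  pos_b <- pos_a + donor_spacing
  total_len <- pos_b + 5L + intron_tail + 30L
  key_a <- sample(hexamer_pool, n_constructs, replace = TRUE)
  key_b <- sample(hexamer_pool, n_constructs, replace = TRUE)
  s_a <- unname(dmap[key_a]); s_b <- unname(dmap[key_b])
  eta <- scale * (s_a - s_b) +
    if (noise_sd > 0) stats::rnorm(n_constructs, 0, noise_sd) else 0
  p_a <- stats::plogis(eta)
  alpha_a <- round(depth * p_a)
  alpha_b <- depth - alpha_a
  seqs <- vapply(seq_len(n_constructs), function(i) {
    s <- randomBases(total_len)
    s[pos_a:(pos_a + 5L)] <- strsplit(key_a[i], "")[[1]]
    s[pos_b:(pos_b + 5L)] <- strsplit(key_b[i], "")[[1]]
    acc_end <- pos_b + 5L + intron_tail
    s[(acc_end - 1L):acc_end] <- c("A", "G")
    paste(s, collapse = "")
  }, character(1))
  constructs <- Biostrings::DNAStringSet(seqs)
  names(constructs) <- sprintf("construct%05d", seq_len(n_constructs))
  pairs <- data.frame(
    construct_id = names(constructs),
    key_a = key_a, key_b = key_b,
    true_a = s_a, true_b = s_b,
    alpha_a = alpha_a, alpha_b = alpha_b,
    sse_a = alpha_a / depth, sse_b = alpha_b / depth,
    stringsAsFactors = FALSE)
  list(constructs = constructs, pairs = pairs)
}
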