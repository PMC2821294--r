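# Independent oracles and small fixture builders used across the suite.

# Exhaustive local-alignment oracle: enumerates every monotone set of
# aligned residue pairs (the combinatorial definition of an alignment) and
# scores it with the minimal affine arrangement of the unaligned residues
# between consecutive pairs (a gap of length L costs open + ext * L; the
# empty alignment scores 0). Independent of the dynamic-programming
# recurrence used by smithWaterman().
bruteForceLocalScore <- function(a, b, S, open = 11, ext = 1) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  gapcost <- function(d) ifelse(d > 0, open + ext * d, 0)
  best <- 0
  for (k in seq_len(min(n, m))) {
    A <- combn(n, k); B <- combn(m, k)
    if (k == 1L) { A <- matrix(A, 1L); B <- matrix(B, 1L) }
    gb <- apply(B, 2, function(j) sum(gapcost(diff(j) - 1L)))
    for (ia in seq_len(ncol(A))) {
      ai <- A[, ia]
      ga <- sum(gapcost(diff(ai) - 1L))
      vals <- S[cbind(rep(ra[ai], ncol(B)), rb[as.vector(B)])]
      msum <- colSums(matrix(vals, nrow = k))
      cand <- max(msum - gb) - ga
      if (cand > best) best <- cand
    }
  }
  best
}

# R-side JTT pairwise log-likelihood (uses jttTransition, not the C++
# distance path) over pairwise-complete columns
jttPairLoglik <- function(a, b, t) {
  codes <- setNames(seq_len(20L), aminoAcids())
  ea <- codes[strsplit(a, "")[[1]]]; eb <- codes[strsplit(b, "")[[1]]]
  keep <- !is.na(ea) & !is.na(eb)
  P <- jttTransition(t)
  pi <- jttFrequencies()
  sum(log(pi[ea[keep]] * P[cbind(ea[keep], eb[keep])]))
}

# dense grid evaluation of the same likelihood: coarse bracket over the
# full range then a 1e-4 grid around the bracket optimum
gridSearchJttDistance <- function(a, b, lower = 1e-6, upper = 10) {
  coarse <- seq(lower, upper, by = 0.01)
  lc <- vapply(coarse, function(t) jttPairLoglik(a, b, t), 1)
  t0 <- coarse[which.max(lc)]
  fine <- seq(max(lower, t0 - 0.02), min(upper, t0 + 0.02), by = 1e-4)
  lf <- vapply(fine, function(t) jttPairLoglik(a, b, t), 1)
  fine[which.max(lf)]
}

# random protein string over an alphabet
randomProtein <- function(n, alphabet = aminoAcids()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small in-code Genome: genes at given starts (width 300) on one replicon
toyGenome <- function(starts, strands = rep("+", length(starts)),
                      proteins = NULL, replicon = "chr", len = NULL,
                      circular = FALSE, id = "toy",
                      width = rep(300L, length(starts))) {
  n <- length(starts)
  ids <- sprintf("g%02d", seq_len(n))
  if (is.null(proteins)) proteins <- vapply(seq_len(n), function(i)
    randomProtein(100), "")
  names(proteins) <- ids
  gr <- GenomicRanges::GRanges(replicon,
    IRanges::IRanges(starts, width = width), strands, gene_id = ids)
  if (is.null(len)) len <- max(starts + width) + 1000L
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(replicon,
    seqlengths = len, isCircular = circular)
  Genome(id, gr, proteins)
}

# assignment table stub for toy genomes (bypasses alignment); "decoy"
# entries become "none" as assignFamilies would emit
stubAssignments <- function(genome, families) {
  ids <- S4Vectors::mcols(genes(genome))$gene_id
  families[families == "decoy"] <- "none"
  S4Vectors::DataFrame(genome_id = genomeId(genome), gene_id = ids,
                       family = families, reference_id = NA_character_,
                       score = 0, identity = 0, coverage = 0, flags = "")
}

# deterministic per-genome family table in the supplement dialect:
# n_both genomes split 62/120/18 into the three arrangement categories,
# n_onlyA genomes with yjeA alone, the rest with neither
writeSupplementTable <- function(path, n_both = 200L, n_operon = 62L,
                                 n_pairwise = 120L, n_none = 18L,
                                 n_onlyA = 2L, n_total = 725L) {
  n_neither <- n_total - n_both - n_onlyA
  acc <- function(pref, n) sprintf("%s_%04d", pref, seq_len(n))
  rows <- data.frame(
    genome_id = sprintf("ORG%04d", seq_len(n_total)),
    efp = acc("EFP", n_total),
    yjeA = c(acc("YJEA", n_both + n_onlyA), rep("", n_neither)),
    yjeK = c(acc("YJEK", n_both), rep("", n_onlyA + n_neither)),
    ablA = "", ablB = "",
    clustering = c(rep("three_gene_operon", n_operon),
                   rep("pairwise_cluster", n_pairwise),
                   rep("no_cluster", n_none),
                   rep("incomplete", n_onlyA + n_neither)),
    stringsAsFactors = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# pull the planted EF-P sequences of a simulation, split by stratum
plantedEfpByStratum <- function(sim) {
  fams <- attr(sim$truth, "gene_families")
  efp_ids <- names(fams)[fams == "efp"]
  gid_of <- sub("_g[0-9]+$", "", efp_ids)
  with_ids <- sim$truth$genome_id[sim$truth$presence_class == "both"]
  seqs <- unlist(lapply(sim$genomes, function(g)
    as.character(proteins(g))), use.names = TRUE)
  names(seqs) <- sub("^.*\\.", "", names(seqs))
  list(with = seqs[efp_ids[gid_of %in% with_ids]],
       without = seqs[efp_ids[!gid_of %in% with_ids]])
}
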