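# Synthetic annotated genomes and evolved protein families with known
# ground truth, so that every pipeline stage can be exercised end-to-end
# without any external downloads. The generator's defaults reproduce the
# study conditions of the comparative survey the package emulates: 725
# genomes, both-yjeA/yjeK fraction 200/725, clustering mix 31/60/9 among
# the with-both genomes, Lys at the anchored EF-P position in 97% of
# with-both genomes (the exceptions being efp paralog pairs carrying
# Ala/His second copies), and a 70/24.1/3.4/2.2/0.3 K/R/M/N/Q mix in the
# without stratum.

.REF_SEED <- 902210L

.randProtein <- function(n) {
  .aaDecode(sample.int(20L, n, replace = TRUE, prob = unname(.JTT_FREQ)))
}

#' Synthetic reference sequences for the five tracked families
#'
#' Deterministically generated stand-ins for curated family references
#' (synthetic: residues drawn from the JTT stationary distribution). The
#' efp reference carries the PGKG anchoring motif at positions 32-35 so
#' that the focal lysine lands at position 34; yjeK and ablA share a
#' common N-terminal aminomutase core (ablA additionally carries a
#' C-terminal extension, mirroring the domain difference between the
#' truncated and canonical enzymes).
#'
#' @return Named list of single-sequence \code{AAStringSet}s for families
#'   \code{efp}, \code{yjeA}, \code{yjeK}, \code{ablA}, \code{ablB}.
#' @export
referenceFamilies <- function() {
  if (!is.null(.efp_cache$references)) return(.efp_cache$references)
  refs <- .withSeed(.REF_SEED, {
    efp <- .randProtein(188L)
    substr(efp, 32L, 35L) <- "PGKG"
    core <- .randProtein(300L)
    core_states <- .aaEncode(core)[[1L]]
    P <- jttTransition(0.5)
    yjeK <- .aaDecode(.evolveStates(core_states, 0.5, P))
    ablA <- paste0(.aaDecode(.evolveStates(core_states, 0.5, P)),
                   .randProtein(130L))
    list(efp = AAStringSet(c(efp_ref = efp)),
         yjeA = AAStringSet(c(yjeA_ref = .randProtein(325L))),
         yjeK = AAStringSet(c(yjeK_ref = yjeK)),
         ablA = AAStringSet(c(ablA_ref = ablA)),
         ablB = AAStringSet(c(ablB_ref = .randProtein(210L))))
  })
  .efp_cache$references <- refs
  refs
}

#' Simulation parameters
#'
#' Defaults encode the emulated survey's conditions; see the package
#' vignette for the rationale behind the remaining realism choices. All
#' proportions are realized as exact cohort compositions (to within one
#' genome, by deterministic quota assignment over genome indices) rather
#' than independent draws: the survey being emulated is a fixed cohort,
#' and randomness is reserved for gene layout and sequence evolution.
#'
#' @param n_genomes Number of genomes (default 725).
#' @param p_both,p_onlyA,p_onlyB,p_neither Proportions of the four
#'   yjeA/yjeK presence classes (must sum to 1; defaults 200/725, 2/725,
#'   0 and the remainder; every genome carries efp).
#' @param clustering_mix Named proportions (\code{operon},
#'   \code{pairwise}, \code{none}) of arrangements among with-both genomes
#'   (default 0.31/0.60/0.09).
#' @param pair_mix Proportions of the clustered pair among pairwise
#'   genomes (default uniform over efp_yjeA, efp_yjeK, yjeA_yjeK).
#' @param p_lys_given_both Fraction of with-both genomes carrying a
#'   single efp with the anchored lysine (default 0.97); the remainder get
#'   an efp paralog pair, one copy with Lys and one with a residue from
#'   \code{alt_residues_with}.
#' @param alt_residues_with Replacement-residue mix for the non-Lys
#'   paralog copy (default Ala/His 50/50).
#' @param residue_mix_without Anchored-residue mix for genomes outside the
#'   with-both stratum (default K/R/M/N/Q = 0.70/0.241/0.034/0.022/0.003).
#' @param p_abl Probability that a genome carries an adjacent ablA/ablB
#'   lysine-catabolism pair (default 0.25; the survey does not quantify
#'   this, it only needs to be common enough to exercise the context
#'   split).
#' @param mutation_distance JTT distance between planted family members
#'   and their reference (default 0.3).
#' @param n_decoys Integer range (min, max) of decoy genes per genome
#'   (default 20-60); decoy residues are drawn from the JTT stationary
#'   distribution so they fail family thresholds.
#' @param decoy_length Integer range of decoy protein lengths (default
#'   120-400).
#' @return Named list of validated parameters.
#' @export
simulationConfig <- function(n_genomes = 725L,
                             p_both = 200 / 725, p_onlyA = 2 / 725,
                             p_onlyB = 0, p_neither = NULL,
                             clustering_mix = c(operon = 0.31,
                                                pairwise = 0.60,
                                                none = 0.09),
                             pair_mix = c(efp_yjeA = 1 / 3,
                                          efp_yjeK = 1 / 3,
                                          yjeA_yjeK = 1 / 3),
                             p_lys_given_both = 0.97,
                             alt_residues_with = c(A = 0.5, H = 0.5),
                             residue_mix_without = c(K = 0.70, R = 0.241,
                                                     M = 0.034, N = 0.022,
                                                     Q = 0.003),
                             p_abl = 0.25, mutation_distance = 0.3,
                             n_decoys = c(20L, 60L),
                             decoy_length = c(120L, 400L)) {
  if (is.null(p_neither)) p_neither <- 1 - p_both - p_onlyA - p_onlyB
  pres <- c(both = p_both, onlyA = p_onlyA, onlyB = p_onlyB,
            neither = p_neither)
  chk <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("inconsistent probabilities: '", what,
           "' must be non-negative and sum to 1")
    p
  }
  cfg <- list(n_genomes = as.integer(n_genomes),
              presence_mix = chk(pres, "presence"),
              clustering_mix = chk(clustering_mix, "clustering_mix"),
              pair_mix = chk(pair_mix, "pair_mix"),
              p_lys_given_both = p_lys_given_both,
              alt_residues_with = chk(alt_residues_with,
                                      "alt_residues_with"),
              residue_mix_without = chk(residue_mix_without,
                                        "residue_mix_without"),
              p_abl = p_abl, mutation_distance = mutation_distance,
              n_decoys = as.integer(n_decoys),
              decoy_length = as.integer(decoy_length))
  if (cfg$n_genomes < 1L) stop("n_genomes must be >= 1")
  cfg
}

# per-genome RNG stream derived from (seed, genome index); stays < 2^31
.genomeSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 69621) %%
               2147483629)
}

# exact-composition class assignment: item i receives the class c whose
# running deficit p_c * i - assigned_c is largest (multi-class Bresenham).
# Deterministic, interleaves classes evenly, and realizes each proportion
# to within one item -- the emulated survey is a fixed cohort, not an iid
# draw, so planted compositions are exact rather than multinomial.
.quotaAssign <- function(n, probs) {
  if (n == 0L) return(character(0))
  cls <- names(probs)
  got <- setNames(numeric(length(probs)), cls)
  out <- character(n)
  for (i in seq_len(n)) {
    deficit <- probs * i - got
    pick <- cls[which.max(deficit)]
    got[pick] <- got[pick] + 1
    out[i] <- pick
  }
  out
}

.mutateFromReference <- function(family, d) {
  ref <- as.character(referenceFamilies()[[family]])[[1L]]
  .aaDecode(.evolveStates(.aaEncode(ref)[[1L]], d))
}

.makeEfp <- function(residue, d) {
  ref <- as.character(referenceFamilies()$efp)[[1L]]
  s <- .aaDecode(.evolveStates(.aaEncode(ref)[[1L]], d))
  substr(s, 30L, 38L) <- substr(ref, 30L, 38L)  # keep the anchor context
  substr(s, 34L, 34L) <- residue
  s
}

# one genome: returns list(genome = Genome, truth = one-row data.frame);
# the planted composition (presence class, arrangement, pair, anchor
# residues, abl carriage) arrives precomputed in 'plant'
.simulateOneGenome <- function(genome_id, cfg, plant) {
  pres <- plant$pres
  has_yjeA <- pres %in% c("both", "onlyA")
  has_yjeK <- pres %in% c("both", "onlyB")
  has_abl <- plant$has_abl
  d <- cfg$mutation_distance
  category <- plant$category; pair <- plant$pair
  efp_residues <- plant$efp_residues

  # planted gene blocks; each block is a data.frame(family, protein, strand,
  # tight) where tight marks operon-style intergenic gaps
  mk <- function(family, protein, strand = sample(c("+", "-"), 1L),
                 tight = FALSE)
    data.frame(family = family, protein = protein, strand = strand,
               tight = tight, stringsAsFactors = FALSE)
  blocks <- list()
  efp_gene <- function(res, tight = FALSE, strand = sample(c("+", "-"), 1L))
    mk("efp", .makeEfp(res, d), strand, tight)
  if (pres == "both") {
    members <- list(efp = efp_gene(efp_residues[1L], tight = TRUE),
                    yjeA = mk("yjeA", .mutateFromReference("yjeA", d),
                              tight = TRUE),
                    yjeK = mk("yjeK", .mutateFromReference("yjeK", d),
                              tight = TRUE))
    if (category == "operon") {
      op <- do.call(rbind, members)
      op$strand <- sample(c("+", "-"), 1L)
      blocks <- list(op)
    } else if (category == "pairwise") {
      fs <- strsplit(pair, "_", fixed = TRUE)[[1L]]
      third <- setdiff(names(members), fs)
      pb <- do.call(rbind, members[fs])
      pb$tight <- FALSE
      n_between <- sample(0:2, 1L)
      pb <- rbind(pb[1L, ], if (n_between > 0)
        do.call(rbind, replicate(n_between, .decoyGene(cfg, mk),
                                 simplify = FALSE)), pb[2L, ])
      tb <- members[[third]]
      tb$tight <- FALSE
      blocks <- list(pb, tb)
    } else {
      blocks <- lapply(members, function(b) { b$tight <- FALSE; b })
    }
    if (length(efp_residues) > 1L)
      blocks <- c(blocks, list(efp_gene(efp_residues[2L])))
  } else {
    category <- "incomplete"
    blocks <- list(efp_gene(efp_residues[1L]))
    if (has_yjeA)
      blocks <- c(blocks, list(mk("yjeA",
                                  .mutateFromReference("yjeA", d))))
    if (has_yjeK)
      blocks <- c(blocks, list(mk("yjeK",
                                  .mutateFromReference("yjeK", d))))
  }
  if (has_abl) {
    ab <- rbind(mk("ablA", .mutateFromReference("ablA", d), tight = TRUE),
                mk("ablB", .mutateFromReference("ablB", d), tight = TRUE))
    ab$strand <- sample(c("+", "-"), 1L)
    blocks <- c(blocks, list(ab))
  }

  # decoy padding: at least 6 decoys between blocks so planted blocks can
  # never cluster with each other under the default max_intervening of 5
  n_blocks <- length(blocks)
  pad_min <- 6L
  n_decoys <- sample(cfg$n_decoys[1L]:cfg$n_decoys[2L], 1L)
  needed <- pad_min * max(0L, n_blocks - 1L)
  if (n_decoys < needed) n_decoys <- needed
  extra <- n_decoys - needed
  pads <- rep(0L, n_blocks + 1L)
  if (extra > 0L) {
    add <- table(factor(sample.int(n_blocks + 1L, extra, replace = TRUE),
                        levels = seq_len(n_blocks + 1L)))
    pads <- pads + as.integer(add)
  }
  if (n_blocks > 1L) pads[2:n_blocks] <- pads[2:n_blocks] + pad_min

  decoy_block <- function(n) if (n > 0L)
    do.call(rbind, replicate(n, .decoyGene(cfg, mk), simplify = FALSE))
  parts <- list(decoy_block(pads[1L]))
  for (b in seq_len(n_blocks))
    parts <- c(parts, list(blocks[[b]], decoy_block(pads[b + 1L])))
  tab <- do.call(rbind, Filter(Negate(is.null), parts))

  # coordinates: tight gaps 20-80 bp (operon-compatible), loose 200-1500 bp
  n <- nrow(tab)
  lens <- nchar(tab$protein) * 3L
  gaps <- ifelse(tab$tight & c(tab$tight[-1L], FALSE),
                 sample(20:80, n, replace = TRUE),
                 sample(200:1500, n, replace = TRUE))
  starts <- integer(n); ends <- integer(n)
  at <- sample(500:1500, 1L)
  for (i in seq_len(n)) {
    starts[i] <- at; ends[i] <- at + lens[i] - 1L
    at <- ends[i] + 1L + gaps[i]
  }
  ids <- sprintf("%s_g%03d", genome_id, seq_len(n))
  rep_id <- paste0(genome_id, "_chr")
  gr <- GRanges(rep_id, IRanges(starts, ends), tab$strand, gene_id = ids)
  sl <- ends[n] + sample(500:5000, 1L)
  seqinfo(gr) <- Seqinfo(rep_id, seqlengths = sl, isCircular = FALSE)
  genome <- Genome(genome_id, gr, setNames(tab$protein, ids))
  truth <- data.frame(
    genome_id = genome_id, presence_class = pres,
    category = if (pres == "both") c(operon = "three_gene_operon",
                                     pairwise = "pairwise_cluster",
                                     none = "no_cluster")[category]
               else "incomplete",
    pair = pair, has_efp = TRUE, has_yjeA = has_yjeA, has_yjeK = has_yjeK,
    has_ablA = has_abl, has_ablB = has_abl,
    efp_residues = paste(efp_residues, collapse = ","),
    n_genes = n, stringsAsFactors = FALSE)
  attr(truth, "gene_families") <- setNames(tab$family, ids)
  list(genome = genome, truth = truth)
}

.decoyGene <- function(cfg, mk) {
  len <- sample(cfg$decoy_length[1L]:cfg$decoy_length[2L], 1L)
  mk("decoy", .randProtein(len))
}

#' Simulate annotated genomes with known ground truth
#'
#' Generates genomes containing decoy genes plus planted
#' efp/yjeA/yjeK/ablA/ablB members (derived from
#' \code{\link{referenceFamilies}} by a JTT substitution process), with
#' arrangements planted in the configured proportions and the anchored
#' EF-P residue planted per stratum. One RNG stream is derived per genome
#' from \code{(seed, genome index)}, so any subset regenerates
#' identically.
#'
#' @param config See \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @param outdir Optional directory; when given, each genome is written as
#'   \code{<genome_id>.gff3} + \code{<genome_id>.faa} and the truth table
#'   as \code{truth.tsv}.
#' @return A list: \code{genomes} (list of \code{\linkS4class{Genome}}),
#'   \code{truth} (data.frame, one row per genome, with per-gene planted
#'   families in attribute \code{gene_families}), and \code{outdir}.
#' @export
simulateGenomes <- function(config = simulationConfig(), seed = 1L,
                            outdir = NULL) {
  n <- config$n_genomes
  ids <- sprintf("SG%04d", seq_len(n))
  # exact cohort composition (see .quotaAssign): presence classes, abl
  # carriage, arrangements among with-both genomes, pairwise pair choice,
  # paralog carriage and anchor residues all realize their configured
  # proportions to within one genome
  pres <- .quotaAssign(n, config$presence_mix)
  has_abl <- .quotaAssign(n, c(abl = config$p_abl,
                               no = 1 - config$p_abl)) == "abl"
  category <- rep(NA_character_, n)
  pair <- rep(NA_character_, n)
  efp_res <- vector("list", n)
  bi <- which(pres == "both")
  category[bi] <- .quotaAssign(length(bi), config$clustering_mix)
  pw <- bi[category[bi] == "pairwise"]
  pair[pw] <- .quotaAssign(length(pw), config$pair_mix)
  lys <- .quotaAssign(length(bi),
                      c(single = config$p_lys_given_both,
                        paralog = 1 - config$p_lys_given_both))
  par_i <- bi[lys == "paralog"]
  alt <- .quotaAssign(length(par_i), config$alt_residues_with)
  efp_res[bi] <- list("K")
  efp_res[par_i] <- lapply(alt, function(a) c("K", a))
  wo <- which(pres != "both")
  efp_res[wo] <- as.list(.quotaAssign(length(wo),
                                      config$residue_mix_without))
  sims <- lapply(seq_along(ids), function(i)
    .withSeed(.genomeSeed(seed, i),
              .simulateOneGenome(ids[i], config,
                plant = list(pres = pres[i], category = category[i],
                             pair = pair[i],
                             efp_residues = efp_res[[i]],
                             has_abl = has_abl[i]))))
  genomes <- lapply(sims, `[[`, "genome")
  names(genomes) <- ids
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  fams <- do.call(c, lapply(sims, function(s)
    attr(s$truth, "gene_families")))
  attr(truth, "gene_families") <- fams
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (g in genomes)
      writeGenome(g, file.path(outdir, paste0(genomeId(g), ".gff3")),
                  file.path(outdir, paste0(genomeId(g), ".faa")))
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genomes = genomes, truth = truth, outdir = outdir)
}

#' Evolve a protein alignment along a tree under the JTT model
#'
#' The root sequence is drawn from the JTT stationary frequencies and each
#' site evolves independently along every branch using
#' \code{\link{jttTransition}}.
#'
#' @param tree A \code{phylo} with branch lengths in substitutions/site.
#' @param region_length Number of columns to simulate (> 0).
#' @param seed Integer seed.
#' @return An \code{AAStringSet} of ungapped rows named by tip label, with
#'   attribute \code{truth}: a data.frame giving each tip's side of the
#'   root split (\code{clade} 1 or 2).
#' @export
evolveAlignment <- function(tree, region_length, seed = 1L) {
  region_length <- as.integer(region_length)
  if (is.na(region_length) || region_length < 1L)
    stop("region_length must be a positive integer")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  .withSeed(seed, {
    states <- vector("list", ntip + tree$Nnode)
    states[[root]] <- sample.int(20L, region_length, replace = TRUE,
                                 prob = unname(.JTT_FREQ))
    # preorder: parents before children
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    for (k in seq_len(nrow(ord))) {
      par <- ord[k, 1L]; child <- ord[k, 2L]
      t_k <- tree$edge.length[which(tree$edge[, 1L] == par &
                                      tree$edge[, 2L] == child)][1L]
      states[[child]] <- if (t_k == 0) states[[par]] else
        .evolveStates(states[[par]], t_k)
    }
    rows <- vapply(seq_len(ntip), function(i) .aaDecode(states[[i]]), "")
    aln <- AAStringSet(setNames(rows, tree$tip.label))
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    clade <- rep(NA_integer_, ntip)
    for (ci in seq_along(kids))
      clade[.tipsUnder(tree, kids[ci])] <- ci
    attr(aln, "truth") <- data.frame(taxon = tree$tip.label, clade = clade,
                                     stringsAsFactors = FALSE)
    aln
  })
}

# tip indices under a node (the node itself if a tip)
.tipsUnder <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Balanced two-clade tree with a deep split
#'
#' Convenience topology for subfamily-split experiments: two balanced
#' clades of \code{n_per_clade} tips each, tip and internal branches of
#' length \code{intra}, joined by a deep internal edge of length
#' \code{deep}.
#'
#' @param n_per_clade Tips per clade (>= 2).
#' @param intra Within-clade branch length (substitutions/site).
#' @param deep Length of the edge separating the clades.
#' @param labels Optional length-2 character vector of tip-label prefixes
#'   (default \code{c("lam", "yjek")}).
#' @return A \code{phylo} tree.
#' @export
twoCladeTree <- function(n_per_clade = 12L, intra = 0.15, deep = 1.0,
                         labels = c("lam", "yjek")) {
  balanced <- function(tips, bl) {
    if (length(tips) == 1L) return(sprintf("%s:%g", tips, bl))
    half <- ceiling(length(tips) / 2)
    sprintf("(%s,%s):%g", balanced(tips[seq_len(half)], bl),
            balanced(tips[-seq_len(half)], bl), bl)
  }
  t1 <- balanced(sprintf("%s%02d", labels[1L], seq_len(n_per_clade)), intra)
  t2 <- balanced(sprintf("%s%02d", labels[2L], seq_len(n_per_clade)), intra)
  txt <- sprintf("(%s:%g,%s:%g);",
                 sub(":[0-9.eE+-]+$", "", t1), deep / 2,
                 sub(":[0-9.eE+-]+$", "", t2), deep / 2)
  ape::read.tree(text = txt)
}
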