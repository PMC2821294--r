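# Synthetic genome generator and JTT alignment evolution

test_that("simulation probabilities are validated", {
  expect_error(simulationConfig(p_both = 0.5, p_onlyA = 0.6,
                                p_onlyB = 0.2, p_neither = 0.2),
               "inconsistent probabilities")
  expect_error(simulationConfig(clustering_mix = c(operon = 0.5,
                                                   pairwise = 0.2,
                                                   none = 0.1)),
               "inconsistent probabilities")
  expect_error(simulationConfig(n_genomes = 0), "n_genomes")
})

test_that("emitted files re-parse without warnings and match the truth table", {
  cfg <- simulationConfig(n_genomes = 6)
  td <- withr::local_tempdir()
  sim <- simulateGenomes(cfg, seed = 51, outdir = td)
  expect_true(file.exists(file.path(td, "truth.tsv")))
  for (id in sim$truth$genome_id) {
    expect_no_warning(
      g <- parseGenome(file.path(td, paste0(id, ".gff3")),
                       file.path(td, paste0(id, ".faa")),
                       genome_id = id))
    expect_equal(nGenes(g),
                 sim$truth$n_genes[sim$truth$genome_id == id])
  }
  # construction audit: planted family genes carry the planted sequences
  fams <- attr(sim$truth, "gene_families")
  for (g in sim$genomes) {
    ids <- S4Vectors::mcols(genes(g))$gene_id
    expect_true(all(ids %in% names(fams)))
    planted <- fams[ids]
    tr_row <- sim$truth[sim$truth$genome_id == genomeId(g), ]
    expect_equal(sum(planted == "efp") > 0, tr_row$has_efp)
    expect_equal(sum(planted == "yjeA") > 0, tr_row$has_yjeA)
    expect_equal(sum(planted == "yjeK") > 0, tr_row$has_yjeK)
    # planted EF-P copies carry the planted anchor residues at the motif
    efp_seqs <- as.character(proteins(g))[ids[planted == "efp"]]
    expect_setequal(substr(efp_seqs, 34, 34),
                    strsplit(tr_row$efp_residues, ",")[[1]])
  }
})

test_that("the closed loop recovers a pure operon plant exactly", {
  cfg <- simulationConfig(n_genomes = 8, p_both = 1, p_onlyA = 0,
                          p_onlyB = 0, p_neither = 0,
                          clustering_mix = c(operon = 1, pairwise = 0,
                                             none = 0),
                          p_lys_given_both = 1, p_abl = 0)
  sim <- simulateGenomes(cfg, seed = 52)
  for (g in sim$genomes) {
    a <- assignFamilies(g, referenceFamilies())
    cl <- classifyClustering(g, a)
    expect_equal(cl$category, "three_gene_operon")
  }
})

test_that("same seed gives byte-identical outputs; streams are per-genome", {
  cfg <- simulationConfig(n_genomes = 4)
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  s1 <- simulateGenomes(cfg, seed = 53, outdir = t1)
  s2 <- simulateGenomes(cfg, seed = 53, outdir = t2)
  for (f in list.files(t1)) {
    l1 <- readLines(file.path(t1, f), warn = FALSE)
    l2 <- readLines(file.path(t2, f), warn = FALSE)
    if (f == "truth.tsv" || grepl("faa$", f)) {
      expect_identical(l1, l2)
    } else {
      expect_identical(grep("^##date", l1, value = TRUE, invert = TRUE),
                       grep("^##date", l2, value = TRUE, invert = TRUE))
    }
  }
  # changing the seed redraws layout and sequences but never the planted
  # cohort composition (exact quota assignment)
  s3 <- simulateGenomes(cfg, seed = 99)
  expect_identical(s3$truth$presence_class, s1$truth$presence_class)
  expect_identical(s3$truth$category, s1$truth$category)
  expect_identical(s3$truth$efp_residues, s1$truth$efp_residues)
  expect_false(identical(as.character(proteins(s3$genomes[[1]])),
                         as.character(proteins(s1$genomes[[1]]))))
})

test_that("planted compositions are exact at survey scale", {
  cfg <- simulationConfig(n_genomes = 725)
  pres <- EFPcontext:::.quotaAssign(725, cfg$presence_mix)
  expect_equal(sum(pres == "both"), 200L)
  expect_equal(sum(pres == "onlyA"), 2L)
  cats <- EFPcontext:::.quotaAssign(200, cfg$clustering_mix)
  expect_equal(as.vector(table(cats)[c("operon", "pairwise", "none")]),
               c(62L, 120L, 18L))
  # quota realizes any proportion vector to within one item
  set.seed(77)
  for (r in 1:10) {
    p <- runif(4); p <- p / sum(p); names(p) <- letters[1:4]
    n <- sample(10:300, 1)
    got <- table(factor(EFPcontext:::.quotaAssign(n, p),
                        levels = names(p)))
    expect_true(all(abs(got - n * p) <= 1))
  }
})

test_that("evolveAlignment honors branch lengths and the stationary limit", {
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln0 <- evolveAlignment(tr0, 50, seed = 54)
  expect_length(unique(as.character(aln0)), 1L)  # zero branches: all equal
  expect_error(evolveAlignment(tr0, 0, seed = 1), "positive")
  # deep split: inter-clade distances exceed intra-clade distances
  tr <- twoCladeTree(4, 0.1, 1.5)
  aln <- evolveAlignment(tr, 300, seed = 55)
  D <- jttDistanceMatrix(aln)
  intra <- c(D[1:4, 1:4][upper.tri(D[1:4, 1:4])],
             D[5:8, 5:8][upper.tri(D[5:8, 5:8])])
  expect_gt(min(D[1:4, 5:8]), max(intra))
  # the truth attribute marks the two sides of the root split
  truth <- attr(aln, "truth")
  expect_equal(sort(unique(truth$clade)), c(1L, 2L))
  expect_length(unique(truth$clade[startsWith(truth$taxon, "lam")]), 1L)
})

test_that("long branches drive pairwise identity to the stationary expectation", {
  tr <- ape::read.tree(text = "(a:5,b:5);")
  ids <- vapply(1:40, function(r) {
    aln <- evolveAlignment(tr, 500, seed = 5600 + r)
    ra <- strsplit(as.character(aln)[["a"]], "")[[1]]
    rb <- strsplit(as.character(aln)[["b"]], "")[[1]]
    mean(ra == rb)
  }, 1)
  # exact expectation at total separation t = 10, itself within 0.004 of
  # the infinite-time limit sum(pi^2) ~ 0.058
  exp_id <- sum(jttFrequencies() * diag(jttTransition(10)))
  expect_equal(mean(ids), exp_id, tolerance = 0.02)
  expect_equal(exp_id, sum(jttFrequencies()^2), tolerance = 0.07)
})
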