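# Smith-Waterman alignment and family assignment

S62 <- EFPcontext:::.substitutionMatrix("BLOSUM62")

test_that("identity alignment scores the diagonal sum", {
  r <- smithWaterman("PGKG", "PGKG")
  expect_equal(alignmentScore(r), 24)   # P=7, G=6, K=5, G=6
  expect_equal(alignmentIdentity(r), 1)
  expect_equal(queryCoverage(r), 1)
  # property: self-score equals sum of diagonal entries for random seqs
  set.seed(5)
  for (i in 1:20) {
    s <- randomProtein(sample(5:40, 1))
    res <- strsplit(s, "")[[1]]
    expect_equal(alignmentScore(smithWaterman(s, s)),
                 sum(diag(S62)[match(res, rownames(S62))]))
  }
})

test_that("score is symmetric and floors at 0", {
  set.seed(6)
  for (i in 1:25) {
    a <- randomProtein(sample(4:30, 1))
    b <- randomProtein(sample(4:30, 1))
    expect_equal(alignmentScore(smithWaterman(a, b)),
                 alignmentScore(smithWaterman(b, a)))
  }
  # C vs G scores -3 under BLOSUM62: no positive pair, empty alignment
  r <- smithWaterman("CCCC", "GGGG")
  expect_equal(alignmentScore(r), 0)
  expect_equal(r@alignedPairs, 0L)
  expect_equal(queryCoverage(r), 0)
})

test_that("DP equals the exhaustive matching-enumeration oracle", {
  set.seed(7)
  alpha <- c("A", "C", "D", "W")   # reduced alphabet, varied scores
  for (i in 1:60) {
    a <- randomProtein(sample(2:8, 1), alpha)
    b <- randomProtein(sample(2:8, 1), alpha)
    expect_equal(alignmentScore(smithWaterman(a, b)),
                 bruteForceLocalScore(a, b, S62),
                 info = paste(a, b))
  }
})

test_that("scores match an independent reference aligner", {
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(8)
  for (i in 1:50) {
    a <- randomProtein(sample(10:60, 1))
    b <- randomProtein(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    expect_equal(alignmentScore(smithWaterman(a, b)),
                 max(0, Biostrings::score(ref)))
  }
})

test_that("unknown matrix and empty input are configuration errors", {
  expect_error(smithWaterman("MK", "MK", matrix = "NOSUCH"), "unknown")
  expect_error(smithWaterman("", "MK"), "non-empty")
  # X scores 0 against everything
  expect_equal(alignmentScore(smithWaterman("XXXX", "XXXX")), 0)
})

test_that("assignFamilies recovers planted families and rejects decoys", {
  sim <- simulateGenomes(simulationConfig(n_genomes = 4), seed = 31)
  truth_fams <- attr(sim$truth, "gene_families")
  for (g in sim$genomes) {
    a <- assignFamilies(g, referenceFamilies())
    planted <- truth_fams[a$gene_id]
    called <- a$family
    # decoys must all be 'none'; planted members must be recovered, except
    # that yjeK/ablA may swap before context disambiguation
    expect_true(all(called[planted == "decoy"] == "none"))
    lam <- planted %in% c("yjeK", "ablA")
    expect_equal(called[!lam & planted != "decoy"],
                 unname(planted[!lam & planted != "decoy"]))
    expect_true(all(called[lam] %in% c("yjeK", "ablA")))
  }
})

test_that("a gene identical to a reference gets identity 1; below-threshold genes get none", {
  refs <- referenceFamilies()
  yk <- as.character(refs$yjeK)[[1]]
  g <- toyGenome(c(100, 5000), proteins = c(yk, randomProtein(250)))
  a <- assignFamilies(g, refs)
  expect_equal(a$family[1], "yjeK")
  expect_equal(a$identity[1], 1)
  expect_equal(a$family[2], "none")
})

test_that("equal-score ties break to the alphabetically first family, flagged", {
  seq <- "MKVILAGHEWQRNDPSTYFC"
  refs <- list(zeta = c(z1 = seq), alpha = c(a1 = seq))
  g <- toyGenome(100, proteins = seq)
  a <- assignFamilies(g, refs, t_id = 0.3, t_cov = 0.7)
  expect_equal(a$family[1], "alpha")
  expect_match(a$flags[1], "family-tie")
  expect_error(assignFamilies(g, list()), "configuration")
  expect_error(assignFamilies(g, list(efp = character(0))), "configuration")
})

test_that("genomic context disambiguates the LAM superfamily pool", {
  a <- S4Vectors::DataFrame(
    genome_id = "G", gene_id = c("g1", "g2", "g3", "g4"),
    family = c("ablA", "yjeK", "ablA", "yjeK"),
    reference_id = NA_character_, score = 0, identity = 0, coverage = 0,
    flags = "")
  ctx <- list(g1 = c("efp"), g2 = c("ablB", "decoyfam"),
              g3 = character(0), g4 = c("efp", "ablB"))
  d <- disambiguateYjekLam(a, ctx)
  expect_equal(d$family, c("yjeK", "ablA", "ablA", "yjeK"))
  expect_match(d$flags[3], "context-unresolved")
  expect_match(d$flags[4], "conflicting-context")
  expect_equal(d$flags[1:2], c("", ""))
})
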