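# Physical clustering, operon calling, arrangement classification

test_that("areClustered follows the intervening-gene rule and is symmetric", {
  g <- toyGenome(seq(100, by = 2000, length.out = 10))
  ids <- S4Vectors::mcols(genes(g))$gene_id
  cfg <- neighborhoodConfig()
  expect_true(areClustered(ids[1], ids[2], g, cfg))    # 0 intervening
  expect_true(areClustered(ids[1], ids[7], g, cfg))    # 5 intervening
  expect_false(areClustered(ids[1], ids[8], g, cfg))   # 6 intervening
  # symmetry over random pairs
  set.seed(9)
  for (i in 1:10) {
    p <- sample(ids, 2)
    expect_equal(areClustered(p[1], p[2], g, cfg),
                 areClustered(p[2], p[1], g, cfg))
  }
  expect_error(areClustered("nope", ids[1], g, cfg), "not in genome")
})

test_that("different replicons never cluster; circular replicons wrap", {
  gr <- GenomicRanges::GRanges(rep(c("c1", "c2"), each = 2),
    IRanges::IRanges(c(100, 600, 100, 600), width = 300), "+",
    gene_id = c("a1", "a2", "b1", "b2"))
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(c("c1", "c2"),
    seqlengths = c(2000L, 2000L), isCircular = c(FALSE, FALSE))
  g2 <- Genome("two", gr, setNames(replicate(4, randomProtein(80)),
                                   c("a1", "a2", "b1", "b2")))
  expect_false(areClustered("a1", "b1", g2))
  # ten genes on a circle: first and last are adjacent across the origin
  gc <- toyGenome(seq(100, by = 2000, length.out = 10), circular = TRUE)
  ids <- S4Vectors::mcols(genes(gc))$gene_id
  expect_true(areClustered(ids[1], ids[10], gc))
  gl <- toyGenome(seq(100, by = 2000, length.out = 10), circular = FALSE)
  expect_false(areClustered(ids[1], ids[10], gl))
})

test_that("isOperon needs one strand, consecutiveness and small gaps", {
  # genes of width 300; starts chosen for gaps of 20 and 40 bp
  g <- toyGenome(c(100, 420, 760, 5000, 11000),
                 strands = c("+", "+", "+", "+", "-"))
  ids <- S4Vectors::mcols(genes(g))$gene_id
  expect_true(isOperon(ids[1:3], g))
  expect_false(isOperon(ids[3:4], g))          # 3,941 bp gap
  expect_false(isOperon(ids[4:5], g))          # opposite strands
  expect_false(isOperon(ids[c(1, 3)], g))      # not consecutive
  expect_error(isOperon(ids[1], g), "at least 2")
  # operon implies pairwise clustering for every member pair
  for (p in combn(3, 2, simplify = FALSE))
    expect_true(areClustered(ids[p[1]], ids[p[2]], g))
})

test_that("classifyClustering reproduces the arrangement taxonomy", {
  mkg <- function(starts, strands, fams) {
    g <- toyGenome(starts, strands = strands)
    list(g = g, a = stubAssignments(g, fams))
  }
  # efp-yjeK adjacent, yjeA 8 genes away -> pairwise efp_yjeK
  x <- mkg(seq(100, by = 2000, length.out = 10), rep("+", 10),
           c("efp", "yjeK", rep("decoy", 7), "yjeA"))
  cl <- classifyClustering(x$g, x$a)
  expect_equal(cl$category, "pairwise_cluster")
  expect_equal(cl$pair, "efp_yjeK")
  # three consecutive same-strand small-gap genes -> operon
  y <- mkg(c(100, 420, 760, 9000, 20000), rep("+", 5),
           c("efp", "yjeA", "yjeK", "decoy", "decoy"))
  expect_equal(classifyClustering(y$g, y$a)$category, "three_gene_operon")
  # all three spread far apart -> no_cluster
  z <- mkg(seq(100, by = 2000, length.out = 20), rep("+", 20),
           c("efp", rep("decoy", 8), "yjeA", rep("decoy", 8), "yjeK",
             "decoy"))
  expect_equal(classifyClustering(z$g, z$a)$category, "no_cluster")
  # missing family -> incomplete
  w <- mkg(c(100, 5000), c("+", "+"), c("efp", "yjeA"))
  expect_equal(classifyClustering(w$g, w$a)$category, "incomplete")
})

test_that("classification is invariant to assignment row order and paralogs use the best combination", {
  g <- toyGenome(seq(100, by = 2000, length.out = 12), rep("+", 12))
  fams <- c("efp", rep("decoy", 7), "yjeA", "yjeK", "decoy", "efp")
  a <- stubAssignments(g, fams)
  cl1 <- classifyClustering(g, a)
  set.seed(10)
  cl2 <- classifyClustering(g, a[sample(nrow(a)), ])
  expect_equal(cl1$category, cl2$category)
  expect_equal(cl1$pair, cl2$pair)
  # the second efp copy (position 12) clusters with yjeA/yjeK even though
  # the first (position 1) does not
  expect_equal(cl1$category, "pairwise_cluster")
})

test_that("neighborhoodContext windows truncate on linear replicons", {
  g <- toyGenome(seq(100, by = 2000, length.out = 8))
  ids <- S4Vectors::mcols(genes(g))$gene_id
  fams <- c("efp", "decoy", "ablA", rep("decoy", 4), "ablB")
  a <- stubAssignments(g, fams)
  ctx3 <- neighborhoodContext(ids[3], g, a)
  expect_setequal(ctx3, c("efp", "ablB"))       # both within 5 genes
  ctx1 <- neighborhoodContext(ids[1], g, a)     # truncated left edge
  expect_setequal(ctx1, "ablA")
  cfg2 <- neighborhoodConfig(context_window = 2)
  expect_setequal(neighborhoodContext(ids[3], g, a, cfg2), "efp")
  # isolated gene: empty context
  gi <- toyGenome(c(100, 30000))
  ai <- stubAssignments(gi, c("yjeK", "decoy"))
  expect_length(neighborhoodContext("g01", gi, ai), 0)
})

test_that("neighborhood parameters must be non-negative", {
  expect_error(neighborhoodConfig(max_intervening = -1), "non-negative")
})
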