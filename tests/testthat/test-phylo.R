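# JTT transition model, ML distances, NJ, bootstrap, subfamily splitting

test_that("jttTransition is a proper reversible transition matrix", {
  expect_equal(jttTransition(0), diag(20), ignore_attr = TRUE)
  for (t in c(1e-4, 0.1, 0.5, 2)) {
    P <- jttTransition(t)
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    # detailed balance with the stationary frequencies
    pi <- jttFrequencies()
    expect_lt(max(abs(pi * P - t(pi * P))), 1e-12)
  }
  # ergodic limit: every row approaches the stationary vector
  P50 <- jttTransition(50)
  expect_lt(max(abs(sweep(P50, 2, jttFrequencies()))), 1e-6)
  expect_error(jttTransition(-0.1), "non-negative")
})

test_that("jttTransition satisfies Chapman-Kolmogorov", {
  for (st in list(c(0.1, 0.2), c(0.05, 0.6), c(1, 1.5))) {
    lhs <- jttTransition(st[1]) %*% jttTransition(st[2])
    expect_lt(max(abs(lhs - jttTransition(sum(st)))), 1e-8)
  }
})

test_that("embedded JTT constants agree with an independent copy", {
  skip_if_not_installed("phangorn")
  ref <- phangorn:::.JTT
  S <- EFPcontext:::.jttExchangeMatrix()
  expect_equal(unname(S[lower.tri(S)]), ref$Q, ignore_attr = TRUE)
  expect_equal(unname(jttFrequencies()), unname(ref$bf), tolerance = 1e-12)
})

test_that("jttDistance: identical sequences, symmetry, saturation flag", {
  set.seed(13)
  s <- randomProtein(80)
  expect_lte(jttDistance(s, s), 1e-6)
  a <- randomProtein(60); b <- randomProtein(60)
  expect_equal(as.numeric(jttDistance(a, b)),
               as.numeric(jttDistance(b, a)))
  # unrelated random sequences at short length can saturate; force it
  d <- jttDistance(strrep("A", 40), strrep("W", 40))
  expect_true(attr(d, "saturated"))
  expect_error(jttDistance("A-", "-A"), "shared")
  expect_error(jttDistance("AA", "AAA"), "equal length")
})

test_that("jttDistance equals a dense grid search over the same likelihood", {
  set.seed(14)
  tr <- twoCladeTree(3, 0.2, 0.8)
  aln <- evolveAlignment(tr, 150, seed = 15)
  rows <- as.character(aln)
  pairs <- combn(length(rows), 2)
  for (k in sample(ncol(pairs), 8)) {
    a <- rows[pairs[1, k]]; b <- rows[pairs[2, k]]
    d <- as.numeric(jttDistance(a, b))
    g <- gridSearchJttDistance(a, b)
    expect_lt(abs(d - g), 2e-4)
  }
})

test_that("jttDistance recovers the generating distance (parameter recovery)", {
  # sequences simulated at a known distance; estimate within 3 SE over reps
  true_t <- 0.4
  tr <- ape::read.tree(text = sprintf("(a:%g,b:0);", true_t))
  set.seed(16)
  ests <- vapply(1:12, function(r) {
    aln <- evolveAlignment(tr, 400, seed = 1600 + r)
    as.numeric(jttDistance(as.character(aln)[["a"]],
                           as.character(aln)[["b"]]))
  }, 1)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_t), 3 * se + 0.02)
})

test_that("njTree solves the 3-taxon closed form and additive 4-taxon case", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- njTree(D3)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # ((A:1,B:1):1,(C:1,D:1):1): AB=2, CD=2, all cross = 4
  D4 <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D4) <- 0; D4["A", "B"] <- D4["B", "A"] <- 2
  D4["C", "D"] <- D4["D", "C"] <- 2
  tr4 <- njTree(D4)
  expect_equal(patristicDistances(tr4)[rownames(D4), colnames(D4)], D4)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dbad <- D3; Dbad[1, 2] <- 3
  expect_error(njTree(Dbad), "symmetric")
})

test_that("njTree reproduces random additive matrices exactly", {
  set.seed(17)
  for (r in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    out <- njTree(D)
    expect_lt(max(abs(patristicDistances(out)[rownames(D), colnames(D)] -
                        D)), 1e-9)
    # and the recovered topology matches the generating one
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(out)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrapTrees is reproducible and degenerate alignments collapse", {
  tr <- twoCladeTree(4, 0.2, 0.8)
  aln <- evolveAlignment(tr, 60, seed = 18)
  b1 <- bootstrapTrees(aln, n_reps = 5, seed = 42)
  b2 <- bootstrapTrees(aln, n_reps = 5, seed = 42)
  expect_equal(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  b3 <- bootstrapTrees(aln, n_reps = 5, seed = 43)
  expect_false(identical(lapply(b1, ape::write.tree),
                         lapply(b3, ape::write.tree)))
  expect_length(bootstrapTrees(aln, n_reps = 1, seed = 1), 1)
  # single repeated column pattern: every replicate tree is identical
  one <- Biostrings::AAStringSet(setNames(
    strrep(c("A", "A", "C", "C"), 30), paste0("t", 1:4)))
  reps <- bootstrapTrees(one, n_reps = 6, seed = 7)
  expect_length(unique(vapply(reps, ape::write.tree, "")), 1L)
  expect_error(bootstrapTrees(aln, n_reps = 0, seed = 1), ">= 1")
})

test_that("consensusSupport counts bipartitions out of n_reps", {
  tr <- twoCladeTree(4, 0.2, 0.8)
  aln <- evolveAlignment(tr, 200, seed = 19)
  main <- njTree(jttDistanceMatrix(aln))
  reps <- bootstrapTrees(aln, n_reps = 20, seed = 20)
  st <- consensusSupport(main, reps, majority = TRUE)
  expect_true(all(st$node.label <= 20L))
  expect_true(all(st$node.label >= 0L))
  # replicates identical to the main tree: every support = n_reps
  st2 <- consensusSupport(main, rep(list(main), 10))
  expect_true(all(st2$node.label == 10L))
  expect_s3_class(attr(st, "consensus"), "phylo")
  bad <- main; bad$tip.label[1] <- "zzz"
  expect_error(consensusSupport(main, list(bad)), "taxon sets")
})

test_that("a bipartition present in half the replicates gets half support", {
  # two fixed topologies over 5 taxa differing in one internal edge
  tA <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  tB <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,e:1);")
  st <- consensusSupport(tA, c(rep(list(tA), 5), rep(list(tB), 5)))
  labs <- st$node.label
  expect_true(any(labs == 5L))   # the ab|cde and cd|abe edges
  expect_equal(labs[1], 10L)     # root bipartition trivially everywhere
})

test_that("splitSubfamilies separates context-consistent clades", {
  tr <- twoCladeTree(4, 0.2, 1.0)
  aln <- evolveAlignment(tr, 300, seed = 21)
  main <- njTree(jttDistanceMatrix(aln))
  reps <- bootstrapTrees(aln, n_reps = 50, seed = 22)
  main <- consensusSupport(main, reps)
  taxa <- main$tip.label
  ctx <- setNames(lapply(taxa, function(t)
    if (startsWith(t, "lam")) "ablB" else "efp"), taxa)
  sp <- splitSubfamilies(main, ctx)
  expect_equal(nrow(sp$clades), 2L)
  expect_setequal(sp$clades$context, c("efp", "ablB"))
  expect_equal(sort(sp$clades$n), c(4L, 4L))
  expect_true(all(sp$taxa$status == "labeled"))
  # empty contexts ride along with their clade
  ctx2 <- ctx; ctx2[["lam01"]] <- character(0)
  sp2 <- splitSubfamilies(main, ctx2)
  expect_equal(sp2$taxa$status[sp2$taxa$taxon == "lam01"], "imputed")
  expect_equal(sp2$taxa$clade[sp2$taxa$taxon == "lam01"],
               sp2$taxa$clade[sp2$taxa$taxon == "lam02"])
  # all contexts empty: single unassigned partition
  ctx3 <- setNames(rep(list(character(0)), length(taxa)), taxa)
  sp3 <- splitSubfamilies(main, ctx3)
  expect_equal(nrow(sp3$clades), 0L)
  expect_true(all(sp3$taxa$status == "unassigned"))
  expect_error(splitSubfamilies(main, ctx[-1]), "every taxon")
})

test_that("a mislabeled taxon is reported as conflict, clade otherwise intact", {
  # exhaustive planted-label check on small trees
  set.seed(23)
  for (r in 1:6) {
    tr <- twoCladeTree(3, 0.3, 1.2, labels = c("x", "y"))
    aln <- evolveAlignment(tr, 400, seed = 230 + r)
    main <- njTree(jttDistanceMatrix(aln))
    taxa <- main$tip.label
    ctx <- setNames(lapply(taxa, function(t)
      if (startsWith(t, "x")) "ablB" else "efp"), taxa)
    flip <- sample(taxa, 1)
    ctx[[flip]] <- if (identical(ctx[[flip]], "ablB")) "efp" else "ablB"
    sp <- splitSubfamilies(main, ctx)
    # the flipped taxon is reported as a placement conflict; the opposite
    # clade stays intact with all three members, and the flipped taxon's
    # home clade keeps its two consistent members
    fl_row <- sp$taxa[sp$taxa$taxon == flip, ]
    expect_equal(fl_row$status, "conflict")
    expect_true(is.na(fl_row$clade))
    # the opposite clade is intact (all 3 members); the home clade keeps
    # only consistent members (2 when the flip is the lone tip, 1 when it
    # sits inside the nested pair) and never contains the flip
    intact <- sp$clades$clade[sp$clades$n == 3L]
    expect_length(intact, 1L)
    expect_true(all(startsWith(
      sp$taxa$taxon[!is.na(sp$taxa$clade) & sp$taxa$clade == intact],
      setdiff(c("x", "y"), substr(flip, 1, 1)))))
    home <- sp$clades[sp$clades$clade != intact, ]
    expect_equal(home$context,
                 if (startsWith(flip, "x")) "ablB" else "efp")
    expect_true(home$n %in% 1:2)
  }
})
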