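# Distance phylogenetics for the LAM/YjeK subfamily question: JTT
# maximum-likelihood pairwise distances, neighbor-joining, column bootstrap,
# bipartition supports as counts, and the clade-vs-genomic-context split.

#' Read and validate an aligned protein FASTA
#'
#' @param x Path to an aligned multi-FASTA, or an \code{AAStringSet} /
#'   named character vector of equal-length gapped rows.
#' @param region Optional length-2 integer vector \code{c(start, end)}
#'   selecting a column slice (e.g. a conserved active-site region chosen
#'   upstream); applied before any analysis.
#' @return An \code{AAStringSet} of equal-width rows with unique names.
#' @export
proteinAlignment <- function(x, region = NULL) {
  aln <- if (is.character(x) && length(x) == 1L && file.exists(x))
    readAAStringSet(x) else AAStringSet(x)
  if (length(aln) == 0L) stop("empty alignment")
  if (length(unique(width(aln))) != 1L)
    stop("alignment rows must all have equal length")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment rows must carry unique taxon names")
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1L] < 1L ||
        region[2L] > width(aln)[1L] || region[1L] > region[2L])
      stop("invalid region slice")
    aln <- subseq(aln, region[1L], region[2L])
  }
  if (width(aln)[1L] == 0L) stop("alignment of width 0")
  aln
}

# taxa x columns integer matrix (1..20; 0 = gap/X/other)
.alignmentMatrix <- function(aln) {
  enc <- .aaEncode(as.character(aln))
  m <- do.call(rbind, enc)
  rownames(m) <- names(aln)
  m
}

#' JTT maximum-likelihood distance between two aligned sequences
#'
#' Finds the branch length t maximizing the likelihood
#' \code{prod(pi[a] * P_t(a, b))} over pairwise-complete columns (pairwise
#' deletion: columns gapped in either row are excluded for that pair), by
#' bounded one-dimensional search on \code{[lower, upper]}.
#'
#' @param a,b Gapped protein sequences of equal length.
#' @param lower,upper Search bounds in substitutions/site (defaults 1e-6
#'   and 10).
#' @param tol Convergence tolerance (default 1e-6).
#' @return Distance estimate in substitutions per site, with attribute
#'   \code{saturated = TRUE} when the optimum sits at the upper bound.
#' @export
jttDistance <- function(a, b, lower = 1e-6, upper = 10, tol = 1e-6) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  D <- .jttDistmat(rbind2taxa = .alignmentMatrix(
    AAStringSet(c(s1 = a, s2 = b))), lower = lower, upper = upper,
    tol = tol)
  d <- D[1L, 2L]
  attr(d, "saturated") <- d >= upper - tol
  d
}

.jttDistmat <- function(rbind2taxa, lower = 1e-6, upper = 10, tol = 1e-6) {
  eg <- .efp_cache$jtt_eigen
  jtt_ml_distmat_cpp(rbind2taxa, eg$V, eg$Vinv, eg$lambda,
                     unname(eg$pi), lower, upper, tol)
}

#' All pairwise JTT distances of an alignment
#'
#' @param aln An alignment accepted by \code{\link{proteinAlignment}}.
#' @inheritParams jttDistance
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
jttDistanceMatrix <- function(aln, lower = 1e-6, upper = 10, tol = 1e-6) {
  aln <- proteinAlignment(aln)
  m <- .alignmentMatrix(aln)
  D <- .jttDistmat(m, lower = lower, upper = upper, tol = tol)
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion (via
#' \code{ape::nj}); negative branch-length estimates are clamped to zero
#' and the originals recorded in the \code{clamped} attribute. On an
#' additive matrix the tree reproduces every input distance exactly.
#'
#' @param D Symmetric distance matrix (>= 3 taxa, zero diagonal) with
#'   taxon dimnames, or a \code{dist}.
#' @return An \code{ape} \code{phylo} tree (unrooted for > 3 taxa).
#' @export
njTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("'D' must be square")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    attr(tr, "clamped") <- data.frame(edge = which(neg),
                                      original = tr$edge.length[neg])
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Column-bootstrap replicate trees
#'
#' Resamples alignment columns with replacement to the original width,
#' recomputes the JTT distance matrix and the NJ tree for each replicate.
#' Fully reproducible given \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param aln An alignment accepted by \code{\link{proteinAlignment}}.
#' @param n_reps Number of replicates (>= 1; the classical choice is 1000).
#' @param seed Integer seed.
#' @inheritParams jttDistance
#' @return List of \code{phylo} trees of length \code{n_reps}.
#' @export
bootstrapTrees <- function(aln, n_reps = 1000L, seed = 1L, lower = 1e-6,
                           upper = 10, tol = 1e-6) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  aln <- proteinAlignment(aln)
  m <- .alignmentMatrix(aln)
  if (ncol(m) == 0L) stop("alignment of width 0")
  .withSeed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      D <- .jttDistmat(m[, idx, drop = FALSE], lower = lower,
                       upper = upper, tol = tol)
      dimnames(D) <- list(rownames(m), rownames(m))
      njTree(D)
    })
  })
}

#' Annotate a tree with bootstrap bipartition supports
#'
#' Each internal edge of the main tree is labelled with the number of
#' replicate trees containing the same bipartition (counts out of
#' \code{length(reps)}, the style in which distance-phylogenetics supports
#' are traditionally reported).
#'
#' @param main A \code{phylo} tree.
#' @param reps List of replicate \code{phylo} trees over the same taxa.
#' @param majority Also compute the extended majority-rule consensus
#'   topology of the replicates (default \code{FALSE}).
#' @return \code{main} with integer \code{node.label} supports (the root
#'   label is the replicate count); if \code{majority}, the consensus tree
#'   is attached as attribute \code{consensus}.
#' @export
consensusSupport <- function(main, reps, majority = FALSE) {
  taxa <- main$tip.label
  same <- vapply(reps, function(tr) setequal(tr$tip.label, taxa), logical(1))
  if (!all(same)) stop("taxon sets of main tree and replicates differ")
  cnt <- ape::prop.clades(main, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  cnt[1L] <- length(reps)   # root bipartition is trivially present
  main$node.label <- as.integer(cnt)
  if (majority)
    attr(main, "consensus") <- ape::consensus(reps, p = 0.5)
  main
}

#' Split a tree into context-consistent subfamily clades
#'
#' Partitions the taxa at the tree's primary structural split (the longest
#' internal edge, i.e. the deep split between subfamilies) and, within each
#' side, takes the largest clade whose members' non-empty genomic-context
#' labels all agree -- e.g. an all-\code{efp} clade (YjeK subfamily) versus
#' an all-\code{ablB} clade (canonical LAM). Taxa with empty context are
#' carried by the clade that contains them (\code{imputed}); labeled taxa
#' whose context disagrees with their side's clade are reported as
#' placement conflicts and left unassigned.
#'
#' @param tree A \code{phylo} tree with branch lengths, optionally with
#'   support \code{node.label}s from \code{\link{consensusSupport}}.
#' @param context_labels Named list: taxon -> character vector of family
#'   labels from its genomic neighborhood (possibly empty).
#' @return A list with \code{clades} (data.frame: \code{clade},
#'   \code{context}, \code{n}, \code{support} -- the bipartition support of
#'   the clade's subtending edge, \code{NA} when no supports are present)
#'   and \code{taxa} (data.frame: \code{taxon}, \code{clade} (\code{NA} if
#'   unassigned), \code{context}, \code{status} among \code{labeled},
#'   \code{imputed}, \code{conflict}, \code{unassigned}).
#' @export
splitSubfamilies <- function(tree, context_labels) {
  taxa <- tree$tip.label
  if (!all(taxa %in% names(context_labels)))
    stop("every taxon needs a (possibly empty) context label set")
  ctx <- vapply(taxa, function(t) {
    v <- unique(context_labels[[t]])
    if (length(v) == 0L) "" else paste(sort(v), collapse = "+")
  }, "")
  ntip <- length(taxa)
  empty <- list(
    clades = data.frame(clade = integer(0), context = character(0),
                        n = integer(0), support = numeric(0)),
    taxa = data.frame(taxon = taxa, clade = NA_integer_, context = ctx,
                      status = "unassigned", row.names = NULL,
                      stringsAsFactors = FALSE))
  if (!any(nzchar(ctx))) return(empty)

  # tips under each internal node, node supports, candidate sides
  parts <- ape::prop.part(tree)
  node_of_part <- ntip + seq_along(parts)
  supports <- tree$node.label
  supp_of_node <- function(v) {
    k <- v - ntip
    if (!is.null(supports) && k >= 1L && k <= length(supports))
      suppressWarnings(as.numeric(supports[k])) else NA_real_
  }
  sides <- list()
  for (k in seq_along(parts)) {
    s <- supp_of_node(node_of_part[k])
    sides[[length(sides) + 1L]] <- list(tips = parts[[k]], support = s)
    sides[[length(sides) + 1L]] <- list(tips = setdiff(seq_len(ntip),
                                                       parts[[k]]),
                                        support = s)
  }
  for (i in seq_len(ntip))   # single tips as degenerate sides
    sides[[length(sides) + 1L]] <- list(tips = i, support = NA_real_)

  # primary structural split: the longest internal edge (ties: first);
  # falls back to the first internal edge when lengths are absent
  int_edges <- which(tree$edge[, 2L] > ntip)
  if (length(int_edges) == 0L) {
    s1 <- 1L
    side1 <- 1L
  } else {
    e <- if (!is.null(tree$edge.length))
      int_edges[which.max(tree$edge.length[int_edges])] else int_edges[1L]
    v <- tree$edge[e, 2L]
    side1 <- parts[[v - ntip]]
  }
  side2 <- setdiff(seq_len(ntip), side1)

  uniformContext <- function(tips) {
    lab <- unique(ctx[tips])
    lab <- lab[nzchar(lab)]
    if (length(lab) == 1L) lab else NA_character_
  }
  # within one side of the primary split, the subfamily clade is the
  # largest sub-side uniform for the side's dominant (majority) context;
  # remaining labeled taxa are placement conflicts
  bestClade <- function(side) {
    labs <- ctx[side]
    labs <- labs[nzchar(labs)]
    if (length(labs) == 0L) return(NULL)
    dom <- names(sort(table(labs), decreasing = TRUE))[1L]
    cand <- Filter(function(cl)
      all(cl$tips %in% side) &&
        identical(uniformContext(cl$tips), dom), sides)
    if (length(cand) == 0L) return(NULL)
    cand[[which.max(vapply(cand, function(cl) length(cl$tips), 1L))]]
  }
  chosen <- Filter(Negate(is.null), list(bestClade(side1),
                                         bestClade(side2)))
  if (length(chosen) == 0L) return(empty)
  clade_df <- do.call(rbind, lapply(seq_along(chosen), function(i) {
    cl <- chosen[[i]]
    data.frame(clade = i, context = uniformContext(cl$tips),
               n = length(cl$tips), support = cl$support,
               stringsAsFactors = FALSE)
  }))
  taxon_clade <- rep(NA_integer_, ntip)
  for (i in seq_along(chosen)) taxon_clade[chosen[[i]]$tips] <- i
  status <- ifelse(!is.na(taxon_clade),
                   ifelse(nzchar(ctx), "labeled", "imputed"),
                   ifelse(nzchar(ctx), "conflict", "unassigned"))
  list(clades = clade_df,
       taxa = data.frame(taxon = taxa, clade = taxon_clade, context = ctx,
                         status = status, row.names = NULL,
                         stringsAsFactors = FALSE))
}

#' Patristic (path-length) distances of a tree
#'
#' @param tree A \code{phylo} with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
patristicDistances <- function(tree) ape::cophenetic.phylo(tree)

# evaluate an expression with a temporary RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
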