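# Family assignment by local alignment against per-family reference
# sequences. Stands in for database annotation: each gene gets the family of
# its best-scoring reference that passes identity and coverage thresholds.

# substitution matrix by name, with X (and any extra letters) scoring 0
# against everything, cached per name
.substitutionMatrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.efp_cache[[key]])) return(.efp_cache[[key]])
  ok <- tryCatch({
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
  }, warning = function(w) NULL, error = function(e) NULL)
  if (is.null(ok)) stop("unknown substitution matrix '", name, "'")
  aa <- aminoAcids()
  m <- ok[aa, aa]
  .efp_cache[[key]] <- m
  m
}

#' @title Local alignment result
#' @description Score and summary statistics of a Smith-Waterman local
#' alignment under affine gap penalties (a gap of length L costs
#' \code{gap_open + gap_extend * L}).
#' @slot score Optimal local alignment score (>= 0).
#' @slot identity Fraction of identical residues over aligned (non-gap)
#'   columns, in [0, 1].
#' @slot queryCoverage Fraction of the query spanned by the alignment.
#' @slot alignedPairs Number of aligned residue-residue columns.
#' @aliases AlignmentResult-class
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  slots = c(score = "numeric", identity = "numeric",
            queryCoverage = "numeric", alignedPairs = "integer"))

setValidity("AlignmentResult", function(object) {
  if (object@score < 0) return("local alignment score must be >= 0")
  if (object@identity < 0 || object@identity > 1)
    return("identity must lie in [0, 1]")
  if (object@queryCoverage < 0 || object@queryCoverage > 1)
    return("queryCoverage must lie in [0, 1]")
  TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: score %.1f, identity %.3f, coverage %.3f (%d columns)\n",
    object@score, object@identity, object@queryCoverage,
    object@alignedPairs))
})

#' @describeIn smithWaterman Accessor for the alignment score.
#' @param x An \code{AlignmentResult}.
#' @export
alignmentScore <- function(x) x@score

#' @describeIn smithWaterman Accessor for the identity fraction.
#' @export
alignmentIdentity <- function(x) x@identity

#' @describeIn smithWaterman Accessor for the query coverage fraction.
#' @export
queryCoverage <- function(x) x@queryCoverage

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine gap penalties. Identity is computed
#' over aligned (non-gap) columns and query coverage as the fraction of the
#' first sequence spanned by the alignment. Residues outside the 20-letter
#' alphabet (including X) score 0 against everything.
#'
#' @param a,b Protein sequences (single strings); \code{a} is the query.
#' @param matrix Substitution matrix name (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Affine gap penalties (default 11 and 1); a gap
#'   of length L costs \code{gap_open + gap_extend * L}.
#' @return An \code{\linkS4class{AlignmentResult}}.
#' @export
#' @examples
#' alignmentScore(smithWaterman("PGKG", "PGKG"))  # 24 under BLOSUM62
smithWaterman <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  S <- .substitutionMatrix(matrix)
  enc <- .aaEncode(c(a, b))
  st <- sw_stats_cpp(enc[[1]], enc[[2]], S, gap_open, gap_extend)
  qspan <- if (st$score > 0) st$query_end - st$query_start + 1L else 0L
  new("AlignmentResult", score = st$score,
      identity = if (st$aligned_pairs > 0) st$matches / st$aligned_pairs else 0,
      queryCoverage = qspan / nchar(a),
      alignedPairs = as.integer(st$aligned_pairs))
}

# score-only fast path on pre-encoded integer sequences
.swScoreEncoded <- function(ea, eb, S, gap_open, gap_extend) {
  sw_score_cpp(ea, eb, S, gap_open, gap_extend)
}

#' Assign genes to the tracked gene families
#'
#' Aligns every protein of a genome against per-family reference sequences
#' and assigns each gene the family of its best-scoring reference passing
#' the identity and coverage thresholds (the coverage threshold is what
#' separates the truncated yjeA/yjeK families from their full-length
#' relatives). Ties on score across families are broken by ascending family
#' name and flagged. Paralogous copies are assessed independently.
#'
#' @param genome A \code{\linkS4class{Genome}}.
#' @param references Named list (family -> \code{AAStringSet} or character
#'   vector of reference proteins); see \code{\link{referenceFamilies}}.
#' @param t_id Minimum identity over aligned columns (default 0.30).
#' @param t_cov Minimum query coverage (default 0.70).
#' @param matrix,gap_open,gap_extend Alignment parameters as in
#'   \code{\link{smithWaterman}}.
#' @return A \code{DataFrame} with one row per gene: \code{genome_id},
#'   \code{gene_id}, \code{family} (\code{"none"} if no reference passes),
#'   \code{reference_id}, \code{score}, \code{identity}, \code{coverage},
#'   \code{flags}.
#' @export
assignFamilies <- function(genome, references, t_id = 0.30, t_cov = 0.70,
                           matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (!is.list(references) || length(references) == 0L ||
      is.null(names(references)) || any(!nzchar(names(references))))
    stop("configuration error: 'references' must be a non-empty named list")
  if (any(vapply(references, length, 1L) == 0L))
    stop("configuration error: empty reference set for family '",
         names(references)[vapply(references, length, 1L) == 0L][1L], "'")
  S <- .substitutionMatrix(matrix)
  ref_tab <- do.call(rbind, lapply(names(references), function(fam) {
    seqs <- as.character(references[[fam]])
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0(fam, "_ref", seq_along(seqs))
    data.frame(family = fam, reference_id = ids, seq = unname(seqs),
               stringsAsFactors = FALSE)
  }))
  ref_enc <- .aaEncode(ref_tab$seq)
  prot <- as.character(proteins(genome))
  qenc <- .aaEncode(prot)
  n <- length(prot)
  fam <- character(n); refid <- character(n); sc <- numeric(n)
  idn <- numeric(n); cov <- numeric(n); flags <- character(n)
  for (i in seq_len(n)) {
    scores <- vapply(ref_enc, .swScoreEncoded, numeric(1), ea = qenc[[i]],
                     S = S, gap_open = gap_open, gap_extend = gap_extend)
    ord <- order(-scores, ref_tab$family)
    best <- NULL; best_k <- NA_integer_; tie <- FALSE
    for (k in ord) {
      if (!is.null(best) && scores[k] < best$score) break
      st <- sw_stats_cpp(qenc[[i]], ref_enc[[k]], S, gap_open, gap_extend)
      qspan <- if (st$score > 0) st$query_end - st$query_start + 1L else 0L
      id_k <- if (st$aligned_pairs > 0) st$matches / st$aligned_pairs else 0
      cov_k <- qspan / length(qenc[[i]])
      if (id_k >= t_id && cov_k >= t_cov) {
        if (is.null(best)) {
          best <- list(score = st$score, identity = id_k, coverage = cov_k)
          best_k <- k
        } else if (st$score == best$score &&
                   ref_tab$family[k] != ref_tab$family[best_k]) {
          tie <- TRUE   # equal-score pass in a second family; keep the
        }               # alphabetically first (already ordered), flag it
      }
    }
    if (is.null(best)) {
      fam[i] <- "none"; refid[i] <- NA_character_
      sc[i] <- max(scores); idn[i] <- 0; cov[i] <- 0; flags[i] <- ""
    } else {
      fam[i] <- ref_tab$family[best_k]; refid[i] <- ref_tab$reference_id[best_k]
      sc[i] <- best$score; idn[i] <- best$identity; cov[i] <- best$coverage
      flags[i] <- if (tie) "family-tie" else ""
    }
  }
  DataFrame(genome_id = genomeId(genome), gene_id = names(prot),
            family = fam, reference_id = refid, score = sc, identity = idn,
            coverage = cov, flags = flags)
}

#' Disambiguate YjeK from canonical LAM by genomic context
#'
#' Genes of the lysine 2,3-aminomutase superfamily are relabelled by the
#' company they keep: a gene whose neighborhood contains \code{efp} is the
#' EF-P-associated subfamily (\code{yjeK}); one whose neighborhood contains
#' \code{ablB} (beta-lysine acetyltransferase, lysine catabolism) is
#' canonical LAM (\code{ablA}). Genes with neither context keep their
#' sequence-based label and are flagged \code{context-unresolved}; a context
#' containing both markers leaves the label unchanged with flag
#' \code{conflicting-context}.
#'
#' @param assignments \code{DataFrame} from \code{\link{assignFamilies}}.
#' @param contexts Named list: \code{gene_id} -> character vector of family
#'   labels found within the context window (see
#'   \code{\link{neighborhoodContext}}).
#' @return The assignments with updated \code{family} and \code{flags}.
#' @export
disambiguateYjekLam <- function(assignments, contexts) {
  pool <- assignments$family %in% c("yjeK", "ablA")
  for (i in which(pool)) {
    ctx <- contexts[[assignments$gene_id[i]]]
    has_efp <- "efp" %in% ctx
    has_ablB <- "ablB" %in% ctx
    add_flag <- function(f) {
      old <- assignments$flags[i]
      paste0(old, if (nzchar(old)) ";", f)
    }
    if (has_efp && has_ablB) {
      assignments$flags[i] <- add_flag("conflicting-context")
    } else if (has_efp) {
      assignments$family[i] <- "yjeK"
    } else if (has_ablB) {
      assignments$family[i] <- "ablA"
    } else {
      assignments$flags[i] <- add_flag("context-unresolved")
    }
  }
  assignments
}

#' Write family assignments as TSV
#'
#' @param assignments \code{DataFrame} from \code{\link{assignFamilies}} (or
#'   several row-bound together).
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAssignments <- function(assignments, path) {
  write.table(as.data.frame(assignments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
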