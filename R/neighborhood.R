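# Physical clustering of efp/yjeA/yjeK (and ablA/ablB): clustering is
# measured in intervening genes, operons additionally require co-orientation
# and short intergenic gaps.

#' Neighborhood analysis parameters
#'
#' @param max_intervening Maximum number of genes allowed between two
#'   clustered members (default 5). The underlying database criterion of the
#'   original neighborhood browsing is unstated, so the value is explicit
#'   and echoed in all outputs.
#' @param operon_max_gap Maximum intergenic gap in bp between consecutive
#'   same-strand operon members (default 100).
#' @param context_window Number of genes on each side considered when
#'   collecting neighborhood family labels (default 5).
#' @return A named list of validated parameters.
#' @export
neighborhoodConfig <- function(max_intervening = 5L, operon_max_gap = 100L,
                               context_window = 5L) {
  p <- list(max_intervening = as.integer(max_intervening),
            operon_max_gap = as.integer(operon_max_gap),
            context_window = as.integer(context_window))
  if (any(vapply(p, function(x) is.na(x) || x < 0L, logical(1))))
    stop("all neighborhood parameters must be non-negative integers")
  p
}

# ordinal positions + replicon bookkeeping for one genome
.genomeIndex <- function(genome) {
  g <- genes(genome)
  rep_id <- as.character(seqnames(g))
  ids <- mcols(g)$gene_id
  si <- seqinfo(g)
  circ <- isCircular(si)
  list(ids = ids, rep_id = rep_id,
       pos = ave(start(g), rep_id, FUN = rank),
       n_rep = table(rep_id),
       circular = setNames(!is.na(circ) & circ, seqlevels(si)))
}

.interveningCount <- function(pi, pj, n, circular) {
  direct <- abs(pi - pj) - 1L
  if (circular) min(direct, n - abs(pi - pj) - 1L) else direct
}

#' Are two genes physically clustered?
#'
#' TRUE iff both genes lie on the same replicon with at most
#' \code{max_intervening} genes between them (wrapping across the origin on
#' circular replicons). Symmetric in its gene arguments.
#'
#' @param gene_a,gene_b Gene ids present in \code{genome}.
#' @param genome A \code{\linkS4class{Genome}}.
#' @param config See \code{\link{neighborhoodConfig}}.
#' @return Logical scalar.
#' @export
areClustered <- function(gene_a, gene_b, genome,
                         config = neighborhoodConfig()) {
  ix <- .genomeIndex(genome)
  i <- match(gene_a, ix$ids); j <- match(gene_b, ix$ids)
  if (is.na(i) || is.na(j)) stop("gene not in genome")
  if (ix$rep_id[i] != ix$rep_id[j]) return(FALSE)
  n <- as.integer(ix$n_rep[ix$rep_id[i]])
  .interveningCount(ix$pos[i], ix$pos[j], n, ix$circular[ix$rep_id[i]]) <=
    config$max_intervening
}

#' Are genes organized as an operon?
#'
#' TRUE iff all genes lie on one replicon and strand, are consecutive in
#' gene order (no intervening genes) and every intergenic gap is at most
#' \code{operon_max_gap} bp. Deliberately simple: no transcription-unit
#' model.
#'
#' @param gene_ids Two or more gene ids.
#' @inheritParams areClustered
#' @return Logical scalar.
#' @export
isOperon <- function(gene_ids, genome, config = neighborhoodConfig()) {
  if (length(gene_ids) < 2L) stop("an operon needs at least 2 genes")
  g <- genes(genome)
  ids <- mcols(g)$gene_id
  i <- match(gene_ids, ids)
  if (anyNA(i)) stop("gene not in genome")
  if (length(unique(as.character(seqnames(g)[i]))) != 1L) return(FALSE)
  if (length(unique(as.character(strand(g)[i]))) != 1L) return(FALSE)
  ix <- .genomeIndex(genome)
  pos <- sort(ix$pos[i])
  if (!all(diff(pos) == 1L)) return(FALSE)   # consecutive, no wrap
  ord <- i[order(ix$pos[i])]
  gaps <- start(g)[ord[-1L]] - end(g)[ord[-length(ord)]] - 1L
  all(gaps <= config$operon_max_gap)
}

#' Classify the efp/yjeA/yjeK arrangement of one genome
#'
#' Categories, in precedence order (mutually exclusive): a genome lacking
#' any of the three families is \code{incomplete}; \code{three_gene_operon}
#' if some (efp, yjeA, yjeK) copy triple passes \code{\link{isOperon}};
#' \code{pairwise_cluster} (with the best clustered family pair) if any two
#' of the families are clustered; otherwise \code{no_cluster}. With
#' paralogs, a genome is scored on its best-clustering combination of
#' copies. Genomes where more than one distinct family pair clusters are
#' flagged \code{multi-pair}.
#'
#' @param genome A \code{\linkS4class{Genome}}.
#' @param assignments \code{DataFrame} from \code{\link{assignFamilies}}.
#' @inheritParams areClustered
#' @return One-row \code{data.frame}: \code{genome_id}, \code{category},
#'   \code{pair} (\code{NA} unless pairwise), \code{supporting_genes},
#'   \code{flags}, and the parameters used.
#' @export
classifyClustering <- function(genome, assignments,
                               config = neighborhoodConfig()) {
  fams <- c("efp", "yjeA", "yjeK")
  copies <- lapply(fams, function(f)
    assignments$gene_id[assignments$family == f])
  names(copies) <- fams
  row <- function(category, pair = NA_character_, support = "",
                  flags = "") {
    data.frame(genome_id = genomeId(genome), category = category,
               pair = pair, supporting_genes = support, flags = flags,
               max_intervening = config$max_intervening,
               operon_max_gap = config$operon_max_gap,
               stringsAsFactors = FALSE)
  }
  if (any(lengths(copies) == 0L)) return(row("incomplete"))
  # operon: any combination of one copy per family
  for (e in copies$efp) for (a in copies$yjeA) for (k in copies$yjeK) {
    if (isOperon(c(e, a, k), genome, config))
      return(row("three_gene_operon",
                 support = paste(c(e, a, k), collapse = ",")))
  }
  # pairwise: best pair = fewest intervening genes, ties broken by pair
  # name order (efp_yjeA, efp_yjeK, yjeA_yjeK) then gene position
  ix <- .genomeIndex(genome)
  pair_names <- c(efp_yjeA = "efp.yjeA", efp_yjeK = "efp.yjeK",
                  yjeA_yjeK = "yjeA.yjeK")
  hits <- list()
  for (pn in names(pair_names)) {
    fs <- strsplit(pair_names[[pn]], ".", fixed = TRUE)[[1L]]
    for (x in sort(copies[[fs[1L]]])) for (y in sort(copies[[fs[2L]]])) {
      if (areClustered(x, y, genome, config)) {
        i <- match(x, ix$ids); j <- match(y, ix$ids)
        n <- as.integer(ix$n_rep[ix$rep_id[i]])
        hits[[length(hits) + 1L]] <- list(pair = pn, genes = c(x, y),
          d = .interveningCount(ix$pos[i], ix$pos[j], n,
                                ix$circular[ix$rep_id[i]]))
      }
    }
  }
  if (length(hits) > 0L) {
    pairs_seen <- unique(vapply(hits, `[[`, "", "pair"))
    best <- hits[[which.min(vapply(hits, `[[`, 1, "d"))]]
    return(row("pairwise_cluster", pair = best$pair,
               support = paste(best$genes, collapse = ","),
               flags = if (length(pairs_seen) > 1L) "multi-pair" else ""))
  }
  row("no_cluster")
}

#' Family labels in a gene's neighborhood
#'
#' Collects the (non-\code{none}) family labels of genes within
#' \code{context_window} genes on each side on the same replicon, wrapping
#' on circular replicons and truncating at the ends of linear ones.
#'
#' @param gene_id A gene id in \code{genome}.
#' @inheritParams classifyClustering
#' @return Character vector of family labels (possibly empty), excluding
#'   the focal gene itself.
#' @export
neighborhoodContext <- function(gene_id, genome, assignments,
                                config = neighborhoodConfig()) {
  ix <- .genomeIndex(genome)
  i <- match(gene_id, ix$ids)
  if (is.na(i)) stop("gene not in genome")
  rep_i <- ix$rep_id[i]
  on_rep <- which(ix$rep_id == rep_i)
  n <- length(on_rep)
  pos <- ix$pos[i]
  offs <- setdiff(seq(pos - config$context_window,
                      pos + config$context_window), pos)
  if (ix$circular[rep_i]) {
    sel <- unique(((offs - 1L) %% n) + 1L)
    sel <- setdiff(sel, pos)
  } else {
    sel <- offs[offs >= 1L & offs <= n]
  }
  nb_ids <- ix$ids[on_rep][match(sel, ix$pos[on_rep])]
  labs <- assignments$family[match(nb_ids, assignments$gene_id)]
  labs <- labs[!is.na(labs) & labs != "none"]
  unique(labs)
}

# contexts for every gene in the LAM superfamily pool (used by the
# disambiguation step); returns list gene_id -> label vector
.lamContexts <- function(genome, assignments, config = neighborhoodConfig()) {
  pool <- assignments$gene_id[assignments$family %in% c("yjeK", "ablA")]
  setNames(lapply(pool, neighborhoodContext, genome = genome,
                  assignments = assignments, config = config), pool)
}
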