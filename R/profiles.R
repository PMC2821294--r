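# Phyletic presence/absence profiles and the co-occurrence / clustering
# summary statistics. Presence is genome-level: any copy counts.

#' @title Phyletic presence/absence profile
#' @description Genomes x families logical matrix recording which gene
#' families are present (at least one copy) in each genome.
#' @slot presence Logical matrix, rownames = genome ids, colnames = family
#'   labels.
#' @aliases PhyleticProfile-class
#' @exportClass PhyleticProfile
setClass("PhyleticProfile", slots = c(presence = "matrix"))

setValidity("PhyleticProfile", function(object) {
  m <- object@presence
  if (!is.logical(m)) return("presence matrix must be logical")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("presence matrix needs genome rownames and family colnames")
  if (anyDuplicated(rownames(m))) return("duplicate genome_id")
  if (anyDuplicated(colnames(m))) return("duplicate family label")
  TRUE
})

setMethod("show", "PhyleticProfile", function(object) {
  m <- object@presence
  cat("PhyleticProfile:", nrow(m), "genomes x", ncol(m), "families\n")
  cat("  families:", paste(colnames(m), collapse = ", "), "\n")
})

#' @describeIn buildProfile Genome ids of a profile.
#' @export
profileGenomes <- function(x) rownames(x@presence)

#' @describeIn buildProfile Family labels of a profile.
#' @export
profileFamilies <- function(x) colnames(x@presence)

#' @describeIn buildProfile The logical presence matrix.
#' @export
presenceMatrix <- function(x) x@presence

#' Build a phyletic profile from family assignments
#'
#' @param assignments Either a single table with \code{genome_id} and
#'   \code{family} columns covering all genomes (e.g. row-bound outputs of
#'   \code{\link{assignFamilies}}), or a named list of per-genome assignment
#'   tables (names = genome ids; duplicate names are an error).
#' @param families Family labels to profile (default the five tracked
#'   families). \code{"none"} never counts as presence.
#' @param x A \code{PhyleticProfile} (accessors).
#' @return A \code{\linkS4class{PhyleticProfile}}.
#' @export
buildProfile <- function(assignments,
                         families = c("efp", "yjeA", "yjeK", "ablA",
                                      "ablB")) {
  if (is.list(assignments) && !is.data.frame(assignments) &&
      !is(assignments, "DataFrame")) {
    if (length(assignments) == 0L) stop("empty dataset")
    ids <- names(assignments)
    if (is.null(ids) || anyDuplicated(ids)) stop("duplicate genome_id")
    tab <- do.call(rbind, lapply(seq_along(assignments), function(i)
      data.frame(genome_id = ids[i],
                 family = as.character(assignments[[i]]$family),
                 stringsAsFactors = FALSE)))
  } else {
    tab <- data.frame(genome_id = as.character(assignments$genome_id),
                      family = as.character(assignments$family),
                      stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty dataset")
  gids <- unique(tab$genome_id)
  m <- matrix(FALSE, length(gids), length(families),
              dimnames = list(gids, families))
  hit <- tab$family %in% families
  m[cbind(tab$genome_id[hit], tab$family[hit])] <- TRUE
  new("PhyleticProfile", presence = m)
}

#' Co-occurrence summary of two families
#'
#' Counts genomes by joint presence/absence of two families. The convention
#' \code{cooccurrence(p, A, B)} equals \code{cooccurrence(p, B, A)} with the
#' only-A / only-B counts swapped.
#'
#' @param profile A \code{\linkS4class{PhyleticProfile}}.
#' @param fam_a,fam_b Family labels present in the profile.
#' @return One-row \code{data.frame}: \code{n_total}, \code{n_both},
#'   \code{n_onlyA}, \code{n_onlyB}, \code{n_neither}, \code{fraction_both}
#'   (unrounded; round only when reporting).
#' @export
cooccurrence <- function(profile, fam_a, fam_b) {
  m <- presenceMatrix(profile)
  if (!fam_a %in% colnames(m)) stop("unknown family '", fam_a, "'")
  if (!fam_b %in% colnames(m)) stop("unknown family '", fam_b, "'")
  a <- m[, fam_a]; b <- m[, fam_b]
  out <- data.frame(n_total = nrow(m), n_both = sum(a & b),
                    n_onlyA = sum(a & !b), n_onlyB = sum(!a & b),
                    n_neither = sum(!a & !b))
  out$fraction_both <- out$n_both / out$n_total
  out
}

#' Clustering-category breakdown over a genome set
#'
#' Percentages of the three mutually exclusive arrangement categories over a
#' restricted genome set (typically the genomes possessing both yjeA and
#' yjeK). Genomes classified \code{incomplete} cannot occur in a correctly
#' restricted set and are dropped with a warning.
#'
#' @param classes \code{data.frame} of rows from
#'   \code{\link{classifyClustering}} (one per genome).
#' @param restrict_to Character vector of genome ids to restrict to; by
#'   default all classified genomes.
#' @return Named numeric vector of percentages
#'   (\code{three_gene_operon}, \code{pairwise_cluster}, \code{no_cluster})
#'   summing to 100, with attribute \code{n} = number of genomes tallied.
#' @export
clusteringBreakdown <- function(classes,
                                restrict_to = classes$genome_id) {
  keep <- classes$genome_id %in% restrict_to
  sub <- classes[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty restricted set")
  if (any(sub$category == "incomplete")) {
    warning("dropping ", sum(sub$category == "incomplete"),
            " 'incomplete' genome(s) from the breakdown")
    sub <- sub[sub$category != "incomplete", , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty restricted set")
  }
  cats <- c("three_gene_operon", "pairwise_cluster", "no_cluster")
  n <- nrow(sub)
  pct <- 100 * vapply(cats, function(ct) sum(sub$category == ct), 1) / n
  attr(pct, "n") <- n
  pct
}

#' Read a per-genome family/clustering table
#'
#' Reads a TSV in the dialect of a distribution-and-clustering supplement:
#' one row per genome, one column per family holding an accession (or
#' blank/\code{NA} when absent), plus an optional clustering-category
#' column. The column mapping is configurable because supplement layouts
#' vary.
#'
#' @param path TSV path.
#' @param genome_col Name of the genome-id column (default
#'   \code{"genome_id"}).
#' @param family_cols Named character vector mapping family label ->
#'   column name (default the five tracked families mapped to identically
#'   named columns).
#' @param clustering_col Optional name of a clustering-category column with
#'   values among \code{three_gene_operon}, \code{pairwise_cluster},
#'   \code{no_cluster}, \code{incomplete} (default \code{"clustering"};
#'   skipped if absent).
#' @return A list with \code{profile}
#'   (\code{\linkS4class{PhyleticProfile}}) and \code{classes} (data.frame
#'   as from \code{\link{classifyClustering}}, or \code{NULL}).
#' @export
readFamilyTable <- function(path, genome_col = "genome_id",
                            family_cols = setNames(
                              c("efp", "yjeA", "yjeK", "ablA", "ablB"),
                              c("efp", "yjeA", "yjeK", "ablA", "ablB")),
                            clustering_col = "clustering") {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!genome_col %in% names(tab))
    stop("column '", genome_col, "' not found in '", path, "'")
  fams <- names(family_cols)
  miss <- !family_cols %in% names(tab)
  if (any(miss))
    stop("family column(s) not found: ",
         paste(family_cols[miss], collapse = ", "))
  gids <- as.character(tab[[genome_col]])
  if (anyDuplicated(gids)) stop("duplicate genome_id")
  m <- vapply(family_cols, function(cn) {
    v <- tab[[cn]]
    !(is.na(v) | !nzchar(trimws(as.character(v))))
  }, logical(nrow(tab)))
  m <- matrix(m, nrow = nrow(tab), dimnames = list(gids, fams))
  classes <- NULL
  if (!is.null(clustering_col) && clustering_col %in% names(tab)) {
    classes <- data.frame(genome_id = gids,
                          category = as.character(tab[[clustering_col]]),
                          stringsAsFactors = FALSE)
  }
  list(profile = new("PhyleticProfile", presence = m), classes = classes)
}
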