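#' @title Annotated genome container
#'
#' @description An S4 container for one annotated genome: ordered, stranded
#' protein-coding gene features on one or more replicons (a \code{GRanges}
#' with 1-based inclusive coordinates, GFF3 convention) together with the
#' encoded protein sequences (an \code{AAStringSet} named by gene id).
#' Replicon lengths and circularity live in the \code{Seqinfo} of the gene
#' ranges; a circular replicon treats its last and first genes as adjacent
#' for neighborhood analysis.
#'
#' @slot genomeId Single genome identifier.
#' @slot taxonLabel Organism label (free text).
#' @slot genes \code{GRanges} of CDS features, sorted by replicon then start,
#'   with a \code{gene_id} metadata column.
#' @slot proteins \code{AAStringSet} of protein sequences, names matching
#'   \code{gene_id}.
#'
#' @aliases Genome-class
#' @exportClass Genome
setClass("Genome",
  slots = c(genomeId = "character", taxonLabel = "character",
            genes = "GRanges", proteins = "AAStringSet"))

.AA_ALPHABET_RE <- "^[ARNDCQEGHILKMFPSTWYVX]+$"

setValidity("Genome", function(object) {
  msgs <- character(0)
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msgs <- c(msgs, "'genomeId' must be a single non-empty string")
  g <- object@genes
  ids <- mcols(g)$gene_id
  if (is.null(ids))
    return("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicate gene_id in genome")
  if (length(g) == 0L)
    msgs <- c(msgs, "genome has no genes")
  if (any(start(g) < 1L))
    msgs <- c(msgs, "gene start coordinates must be >= 1")
  sl <- seqlengths(seqinfo(g))
  if (any(!is.na(sl))) {
    lim <- sl[as.character(seqnames(g))]
    if (any(!is.na(lim) & end(g) > lim))
      msgs <- c(msgs, "gene end exceeds replicon length")
  }
  if (any(!as.character(strand(g)) %in% c("+", "-")))
    msgs <- c(msgs, "gene strand must be '+' or '-'")
  # sorted by replicon then start
  o <- order(as.integer(seqnames(g)), start(g))
  if (!identical(o, seq_along(g)))
    msgs <- c(msgs, "genes must be sorted by replicon then start")
  p <- object@proteins
  if (!setequal(names(p), ids) || length(p) != length(g))
    msgs <- c(msgs, "protein names must match gene_id one-to-one")
  if (length(p) && any(width(p) == 0L))
    msgs <- c(msgs, "empty protein sequence")
  if (length(p) && !all(grepl(.AA_ALPHABET_RE, as.character(p))))
    msgs <- c(msgs, "protein sequences restricted to the 20 residues plus X")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Genome object
#'
#' @param genome_id Genome identifier.
#' @param genes \code{GRanges} of CDS features with a \code{gene_id}
#'   metadata column; sorted internally.
#' @param proteins \code{AAStringSet} (or named character vector) of protein
#'   sequences, names matching \code{gene_id}.
#' @param taxon_label Organism label; defaults to \code{genome_id}.
#' @param circular Optional named logical vector flagging circular replicons.
#' @return A validated \code{\linkS4class{Genome}}.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(100, 399), "+",
#'                              gene_id = "g1")
#' Genome("G1", gr, c(g1 = "MKVLPGKG"))
Genome <- function(genome_id, genes, proteins, taxon_label = genome_id,
                   circular = NULL) {
  if (is.character(proteins)) proteins <- AAStringSet(proteins)
  o <- order(as.integer(seqnames(genes)), start(genes))
  genes <- genes[o]
  ids <- mcols(genes)$gene_id
  proteins <- proteins[match(ids, names(proteins))]
  if (!is.null(circular)) {
    ic <- isCircular(seqinfo(genes))
    ic[names(circular)] <- circular
    isCircular(seqinfo(genes)) <- ic
  }
  new("Genome", genomeId = as.character(genome_id),
      taxonLabel = as.character(taxon_label), genes = genes,
      proteins = proteins)
}

#' @describeIn Genome Genome identifier.
#' @param x,object A \code{Genome}.
#' @export
genomeId <- function(x) x@genomeId

#' @describeIn Genome Organism label.
#' @export
taxonLabel <- function(x) x@taxonLabel

#' @describeIn Genome The gene \code{GRanges} (sorted, with \code{gene_id}).
#' @export
genes <- function(x) x@genes

#' @describeIn Genome The protein \code{AAStringSet}, named by gene id.
#' @export
proteins <- function(x) x@proteins

#' @describeIn Genome Number of genes.
#' @export
nGenes <- function(x) length(x@genes)

setMethod("show", "Genome", function(object) {
  cat("Genome '", object@genomeId, "' (", object@taxonLabel, ")\n", sep = "")
  cat("  ", length(object@genes), " protein-coding genes on ",
      length(seqlevels(object@genes)), " replicon(s)\n", sep = "")
})

# quick structural sanity check of a GFF3 file: every non-directive,
# non-comment line must have 9 tab-separated fields
.checkGff3Lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GFF3 line ", bad, " in '", path,
         "': expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
  }
  # replicon lengths from ##sequence-region directives (rtracklayer's
  # importer does not surface them)
  reg <- lines[startsWith(lines, "##sequence-region")]
  sl <- NULL
  if (length(reg)) {
    parts <- strsplit(trimws(reg), "\\s+")
    ok <- lengths(parts) >= 4L
    sl <- setNames(vapply(parts[ok], function(p) as.integer(p[4L]), 1L),
                   vapply(parts[ok], `[[`, "", 2L))
  }
  invisible(list(n_features = sum(body), seqlengths = sl))
}

#' Parse an annotated genome from GFF3 + protein FASTA
#'
#' Reads CDS features (falling back to \code{gene} features when no CDS rows
#' are present) from a GFF3 file and attaches protein sequences from a FASTA
#' file whose record ids match the feature \code{ID} attributes. Features
#' without a matching protein are dropped with a warning; if the unmatched
#' fraction exceeds \code{max_unmatched} the dataset is rejected.
#'
#' @param gff3_path Path to a GFF3 annotation file.
#' @param fasta_path Path to the matching protein multi-FASTA.
#' @param genome_id Genome identifier; defaults to the GFF3 file stem.
#' @param taxon_label Organism label; defaults to \code{genome_id}.
#' @param circular Optional named logical vector of circular replicons.
#' @param max_unmatched Maximum tolerated fraction of features without a
#'   protein record (default 0.2) before a dataset error is raised.
#' @return A \code{\linkS4class{Genome}}.
#' @export
parseGenome <- function(gff3_path, fasta_path,
                        genome_id = sub("\\.[^.]*$", "", basename(gff3_path)),
                        taxon_label = genome_id, circular = NULL,
                        max_unmatched = 0.2) {
  hdr <- .checkGff3Lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr) == 0L) stop("no features in '", gff3_path, "'")
  keep <- mcols(gr)$type %in% "CDS"
  if (!any(keep)) keep <- mcols(gr)$type %in% "gene"
  if (!any(keep)) stop("no CDS or gene features in '", gff3_path, "'")
  gr <- gr[keep]
  ids <- as.character(mcols(gr)$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 features without an ID attribute in '", gff3_path, "'")
  aa <- readAAStringSet(fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  miss <- !(ids %in% names(aa))
  if (mean(miss) > max_unmatched)
    stop("dataset error: ", sum(miss), "/", length(ids),
         " GFF3 features lack a FASTA protein record (> ",
         max_unmatched * 100, "% mismatch)")
  if (any(miss)) {
    warning("dropping ", sum(miss),
            " feature(s) without a protein sequence in '", gff3_path, "'")
    gr <- gr[!miss]
    ids <- ids[!miss]
  }
  out <- granges(gr)
  mcols(out)$gene_id <- ids
  if (!is.null(hdr$seqlengths)) {
    sl <- seqlengths(seqinfo(out))
    known <- intersect(names(hdr$seqlengths), names(sl))
    sl[known] <- hdr$seqlengths[known]
    seqlengths(out) <- sl
  }
  Genome(genome_id, out, aa[ids], taxon_label, circular = circular)
}

#' Write a Genome back to GFF3 + protein FASTA
#'
#' Inverse of \code{\link{parseGenome}}: emits one CDS feature per gene and
#' the protein multi-FASTA. Re-parsing the emitted pair reproduces the gene
#' coordinates, strands, ids and sequences.
#'
#' @param genome A \code{\linkS4class{Genome}}.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
writeGenome <- function(genome, gff3_path, fasta_path) {
  g <- genes(genome)
  mcols(g)$type <- "CDS"
  mcols(g)$ID <- mcols(g)$gene_id
  mcols(g)$source <- "EFPcontext"
  mcols(g)$phase <- 0L
  rtracklayer::export(g, gff3_path, format = "gff3")
  sl <- seqlengths(seqinfo(g))
  # add the sequence-region directives rtracklayer omits, and drop its
  # ##date stamp so equal inputs give byte-identical files
  lines <- readLines(gff3_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "##date")]
  if (any(!is.na(sl))) {
    reg <- sprintf("##sequence-region %s 1 %d", names(sl)[!is.na(sl)],
                   sl[!is.na(sl)])
    at <- max(grep("^##", lines), 1L)
    lines <- append(lines, reg, after = at)
  }
  writeLines(lines, gff3_path)
  writeXStringSet(proteins(genome), fasta_path)
  invisible(c(gff3 = gff3_path, fasta = fasta_path))
}

#' Ordinal gene positions within each replicon
#'
#' @param genome A \code{\linkS4class{Genome}}.
#' @return A \code{data.frame} with columns \code{gene_id},
#'   \code{replicon_id} and \code{ordinal} (0-based position in start order
#'   within the replicon; a bijection onto 0..n-1 per replicon).
#' @export
geneOrderIndex <- function(genome) {
  g <- genes(genome)
  ids <- mcols(g)$gene_id
  if (anyDuplicated(ids)) stop("duplicate gene_id in genome")
  rep_id <- as.character(seqnames(g))
  ord <- unlist(lapply(split(seq_along(g), rep_id),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  idx <- unlist(split(seq_along(g), rep_id), use.names = FALSE)
  out <- data.frame(gene_id = ids[idx], replicon_id = rep_id[idx],
                    ordinal = ord, stringsAsFactors = FALSE)
  out[order(match(out$gene_id, ids)), , drop = FALSE]
}

#' Per-replicon gene count summary
#'
#' @param genome A \code{\linkS4class{Genome}}.
#' @return \code{data.frame} with \code{genome_id}, \code{replicon} and
#'   \code{n_genes}, suitable for a TSV summary.
#' @export
genomeSummary <- function(genome) {
  tab <- table(as.character(seqnames(genes(genome))))
  data.frame(genome_id = genomeId(genome), replicon = names(tab),
             n_genes = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}
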