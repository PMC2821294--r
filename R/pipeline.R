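# End-to-end orchestration: family assignment, clustering classification,
# phyletic profile + co-occurrence, clustering breakdown restricted to
# with-both genomes, stratified residue distributions and logo tables, and
# (when an alignment is supplied) the NJ tree with supports plus the
# context-based subfamily split. Every stage writes a TSV so stages are
# independently checkable, and the machine-readable summary mirrors the
# headline statistics.

.writeTsv <- function(x, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  write.table(as.data.frame(x), file.path(outdir, name), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the comparative-genomics pipeline
#'
#' @param genomes A list of \code{\linkS4class{Genome}} objects, or a
#'   directory containing \code{<genome_id>.gff3} + \code{<genome_id>.faa}
#'   pairs (as emitted by \code{\link{simulateGenomes}}).
#' @param references Named list of per-family reference sequences (default
#'   \code{\link{referenceFamilies}}); an empty or unnamed list is
#'   rejected before any compute.
#' @param neighborhood See \code{\link{neighborhoodConfig}}.
#' @param anchor See \code{\link{anchorConfig}}.
#' @param alignment Optional aligned protein FASTA (path or
#'   \code{AAStringSet}) for the subfamily tree stage.
#' @param tree_contexts Optional named list taxon -> context labels for
#'   \code{\link{splitSubfamilies}}; required when \code{alignment} is
#'   given.
#' @param n_reps Bootstrap replicates for the tree stage (default 1000).
#' @param seed Integer seed (bootstrap resampling).
#' @param outdir Optional output directory for the TSV/newick bundle.
#' @param t_id,t_cov Assignment thresholds, see
#'   \code{\link{assignFamilies}}.
#' @return A summary list with components \code{assignments},
#'   \code{classes}, \code{profile}, \code{cooccurrence},
#'   \code{breakdown}, \code{residues_with}, \code{residues_without},
#'   \code{logo_with}, \code{logo_without}, \code{tree},
#'   \code{subfamilies}, and \code{parameters}.
#' @export
runPipeline <- function(genomes, references = referenceFamilies(),
                        neighborhood = neighborhoodConfig(),
                        anchor = anchorConfig(), alignment = NULL,
                        tree_contexts = NULL, n_reps = 1000L, seed = 1L,
                        outdir = NULL, t_id = 0.30, t_cov = 0.70) {
  if (!is.list(references) || length(references) == 0L ||
      is.null(names(references)))
    stop("stage 'configuration': missing or unnamed family references")
  if (!is.null(alignment) && is.null(tree_contexts))
    stop("stage 'configuration': 'alignment' requires 'tree_contexts'")
  if (is.character(genomes) && length(genomes) == 1L) {
    if (!dir.exists(genomes))
      stop("stage 'input': genome directory '", genomes, "' does not exist")
    gffs <- sort(list.files(genomes, pattern = "\\.gff3$",
                            full.names = TRUE))
    if (length(gffs) == 0L)
      stop("stage 'input': no .gff3 files in '", genomes, "'")
    genomes <- lapply(gffs, function(gf)
      parseGenome(gf, sub("\\.gff3$", ".faa", gf)))
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  per_genome <- stage("assign", lapply(genomes, function(g) {
    a <- assignFamilies(g, references, t_id = t_id, t_cov = t_cov)
    a <- disambiguateYjekLam(a, .lamContexts(g, a, neighborhood))
    a
  }))
  assignments <- do.call(rbind, per_genome)
  .writeTsv(assignments, outdir, "assignments.tsv")

  classes <- stage("neighborhood", do.call(rbind,
    lapply(seq_along(genomes), function(i)
      classifyClustering(genomes[[i]], per_genome[[i]], neighborhood))))
  .writeTsv(classes, outdir, "clusters.tsv")

  profile <- stage("profile", buildProfile(assignments))
  co <- stage("profile", cooccurrence(profile, "yjeA", "yjeK"))
  .writeTsv(cbind(genome_id = profileGenomes(profile),
                  as.data.frame(presenceMatrix(profile))),
            outdir, "profile.tsv")
  .writeTsv(co, outdir, "cooccurrence.tsv")

  m <- presenceMatrix(profile)
  with_both <- rownames(m)[m[, "yjeA"] & m[, "yjeK"]]
  breakdown <- stage("breakdown",
    if (length(with_both)) clusteringBreakdown(classes, with_both) else
      NULL)
  if (!is.null(breakdown))
    .writeTsv(data.frame(category = names(breakdown),
                         percent = as.numeric(breakdown),
                         n = attr(breakdown, "n")),
              outdir, "breakdown.tsv")

  # EF-P sequences stratified by yjeA/yjeK presence of their genome
  efp_tab <- as.data.frame(assignments[assignments$family == "efp",
                                       c("genome_id", "gene_id")])
  prot_of <- function(rows) {
    unlist(lapply(seq_len(nrow(rows)), function(k) {
      g <- genomes[[match(rows$genome_id[k],
                          vapply(genomes, genomeId, ""))]]
      as.character(proteins(g)[rows$gene_id[k]])
    }))
  }
  strat <- stage("conservation", {
    win <- efp_tab$genome_id %in% with_both
    list(with_seqs = prot_of(efp_tab[win, , drop = FALSE]),
         without_seqs = prot_of(efp_tab[!win, , drop = FALSE]))
  })
  res_stats <- stage("conservation", lapply(strat, function(ss) {
    if (length(ss) == 0L) return(NULL)
    rd <- residueDistribution(ss, anchor)
    win <- anchorWindows(ss, anchor)
    list(residues = rd, logo = if (length(win)) logoHeights(win) else NULL)
  }))
  rw <- res_stats$with_seqs; rwo <- res_stats$without_seqs
  res_df <- function(x) if (is.null(x)) NULL else
    data.frame(residue = names(x$residues$percent),
               percent = as.numeric(x$residues$percent),
               n_anchored = x$residues$n_anchored,
               n_excluded = x$residues$n_excluded)
  .writeTsv(res_df(rw), outdir, "residues_with_yjeAK.tsv")
  .writeTsv(res_df(rwo), outdir, "residues_without_yjeAK.tsv")
  if (!is.null(rw) && !is.null(rw$logo))
    .writeTsv(rw$logo, outdir, "logo_with_yjeAK.tsv")
  if (!is.null(rwo) && !is.null(rwo$logo))
    .writeTsv(rwo$logo, outdir, "logo_without_yjeAK.tsv")

  tree <- NULL; subfam <- NULL
  if (!is.null(alignment)) {
    tree <- stage("tree", {
      aln <- proteinAlignment(alignment)
      D <- jttDistanceMatrix(aln)
      main <- njTree(D)
      reps <- bootstrapTrees(aln, n_reps = n_reps, seed = seed)
      consensusSupport(main, reps)
    })
    subfam <- stage("tree", splitSubfamilies(tree, tree_contexts))
    if (!is.null(outdir)) {
      ape::write.tree(tree, file.path(outdir, "tree.nwk"))
      .writeTsv(subfam$taxa, outdir, "subfamilies.tsv")
    }
  }

  summary <- list(assignments = assignments, classes = classes,
                  profile = profile, cooccurrence = co,
                  breakdown = breakdown,
                  residues_with = if (!is.null(rw)) rw$residues,
                  residues_without = if (!is.null(rwo)) rwo$residues,
                  logo_with = if (!is.null(rw)) rw$logo,
                  logo_without = if (!is.null(rwo)) rwo$logo,
                  tree = tree, subfamilies = subfam,
                  parameters = list(neighborhood = neighborhood,
                                    anchor = anchor, t_id = t_id,
                                    t_cov = t_cov, n_reps = n_reps,
                                    seed = seed,
                                    n_genomes = length(genomes)))
  if (!is.null(outdir))
    writeLines(reportSummary(summary), file.path(outdir, "report.txt"))
  summary
}

#' Human-readable pipeline report
#'
#' Formats the pipeline summary as text; every number carries its
#' denominator and the parameters that produced it. Empty strata are
#' reported as \code{n=0}, never omitted.
#'
#' @param summary The list returned by \code{\link{runPipeline}}.
#' @return Character vector of report lines.
#' @export
reportSummary <- function(summary) {
  p <- summary$parameters
  co <- summary$cooccurrence
  lines <- c(
    "EF-P modification-gene context report",
    sprintf("parameters: max_intervening=%d operon_max_gap=%d bp, motif=%s, identity>=%.2f coverage>=%.2f, n_reps=%d, seed=%d",
            p$neighborhood$max_intervening, p$neighborhood$operon_max_gap,
            p$anchor$motif, p$t_id, p$t_cov, p$n_reps, p$seed),
    sprintf("genomes analyzed: %d", p$n_genomes),
    sprintf("yjeA+yjeK co-occurrence: %d/%d genomes (%.1f%%); yjeA only %d, yjeK only %d, neither %d",
            co$n_both, co$n_total, 100 * co$fraction_both, co$n_onlyA,
            co$n_onlyB, co$n_neither))
  b <- summary$breakdown
  lines <- c(lines, if (is.null(b))
    "clustering breakdown: n=0 (no genome has both yjeA and yjeK)"
    else sprintf(
      "clustering among with-both genomes (n=%d): operon %.1f%%, pairwise %.1f%%, none %.1f%%",
      attr(b, "n"), b[["three_gene_operon"]], b[["pairwise_cluster"]],
      b[["no_cluster"]]))
  fmt_res <- function(r, label) {
    if (is.null(r)) return(sprintf("%s: n=0", label))
    pc <- sort(r$percent, decreasing = TRUE)
    sprintf("%s (n=%d anchored, %d excluded): %s", label, r$n_anchored,
            r$n_excluded,
            paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "))
  }
  lines <- c(lines,
             fmt_res(summary$residues_with,
                     "anchored residue, genomes with yjeA+yjeK"),
             fmt_res(summary$residues_without,
                     "anchored residue, genomes without yjeA+yjeK"))
  if (!is.null(summary$subfamilies) &&
      nrow(summary$subfamilies$clades) > 0) {
    cl <- summary$subfamilies$clades
    lines <- c(lines, sprintf(
      "subfamily clades: %s",
      paste(sprintf("clade %d (%s context, n=%d, support %s/%d)",
                    cl$clade, cl$context, cl$n,
                    ifelse(is.na(cl$support), "NA",
                           format(cl$support)), p$n_reps),
            collapse = "; ")))
  }
  lines
}
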