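# Motif-anchored positional conservation. The conserved "PGKG" context of
# EF-P Lys34 is used as an anchoring landmark instead of a full multiple
# alignment: the motif itself defines the focal position, and a degenerate
# fallback (focal position free, flanks scored by the substitution matrix)
# picks up sequences where the lysine has been replaced.

#' Anchoring parameters for positional conservation
#'
#' @param motif Amino-acid anchoring motif (default \code{"PGKG"}).
#' @param anchor_offset 1-based index of the focal residue within the motif
#'   (default 3, the K of PGKG, homologous to E. coli EF-P Lys34).
#' @param window Odd number of alignment columns centered on the focal
#'   residue for logo statistics (default 9).
#' @param floor Minimum summed substitution score of the non-focal motif
#'   positions for a degenerate match (default 12 under BLOSUM62, i.e. the
#'   three flanking residues at near-identity).
#' @param matrix Substitution matrix used for degenerate matching.
#' @return Named list of validated parameters.
#' @export
anchorConfig <- function(motif = "PGKG", anchor_offset = 3L, window = 9L,
                         floor = 12, matrix = "BLOSUM62") {
  motif <- toupper(motif)
  if (!grepl(.AA_ALPHABET_RE, motif)) stop("invalid motif")
  anchor_offset <- as.integer(anchor_offset)
  if (anchor_offset < 1L || anchor_offset > nchar(motif))
    stop("anchor_offset must lie within the motif")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd")
  list(motif = motif, anchor_offset = anchor_offset, window = window,
       floor = floor, matrix = matrix)
}

#' Locate the focal (Lys34-homologous) residue of a protein
#'
#' Exact occurrences of the motif are preferred (leftmost wins). When the
#' exact motif is absent, every window of motif length is scored with the
#' focal position left free and the remaining positions scored by the
#' substitution matrix against the motif; the leftmost best-scoring window
#' at or above \code{floor} anchors the sequence. Returns \code{NA} when no
#' window qualifies (the sequence is excluded from statistics).
#'
#' @param seq A protein sequence (single string).
#' @param config See \code{\link{anchorConfig}}.
#' @return 1-based index of the focal residue, or \code{NA_integer_}.
#' @export
#' @examples
#' p <- paste0(strrep("A", 31), "PGKG")   # K lands at position 34
#' anchorPosition(p)
anchorPosition <- function(seq, config = anchorConfig()) {
  seq <- toupper(seq)
  L <- nchar(config$motif)
  if (nchar(seq) < L) return(NA_integer_)
  hit <- regexpr(config$motif, seq, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit) + config$anchor_offset - 1L)
  S <- .substitutionMatrix(config$matrix)
  mot <- strsplit(config$motif, "")[[1L]]
  res <- strsplit(seq, "")[[1L]]
  flank <- setdiff(seq_len(L), config$anchor_offset)
  nwin <- nchar(seq) - L + 1L
  sc <- vapply(seq_len(nwin), function(p) {
    w <- res[p + flank - 1L]
    ok <- w %in% rownames(S) & mot[flank] %in% rownames(S)
    sum(S[cbind(mot[flank][ok], w[ok])])
  }, numeric(1))
  best <- max(sc)
  if (best < config$floor) return(NA_integer_)
  which.max(sc) + config$anchor_offset - 1L   # leftmost best window
}

#' Residue distribution at the anchored position
#'
#' Anchors every sequence with \code{\link{anchorPosition}} and tabulates
#' the focal residue. In \code{per_sequence} mode every anchored protein
#' contributes one observation (paralogs count separately); in
#' \code{per_genome} mode each genome contributes one observation, which is
#' the reference residue (default \code{"K"}) if any of its copies carries
#' it, else the residue of its first anchored copy.
#'
#' @param seqs Character vector (or \code{AAStringSet}) of protein
#'   sequences.
#' @param config See \code{\link{anchorConfig}}.
#' @param mode \code{"per_sequence"} (default) or \code{"per_genome"}.
#' @param genome_ids Required for \code{per_genome} mode: genome of each
#'   sequence.
#' @param reference_residue Residue whose any-copy presence defines a
#'   genome in \code{per_genome} mode (default \code{"K"}).
#' @return A list: \code{percent} (named percentages over anchored
#'   observations, summing to 100), \code{n_anchored}, \code{n_excluded}.
#' @export
residueDistribution <- function(seqs, config = anchorConfig(),
                                mode = c("per_sequence", "per_genome"),
                                genome_ids = NULL,
                                reference_residue = "K") {
  mode <- match.arg(mode)
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("no sequences")
  pos <- vapply(seqs, anchorPosition, integer(1), config = config,
                USE.NAMES = FALSE)
  anchored <- !is.na(pos)
  if (!any(anchored)) stop("no sequence could be anchored")
  res <- substr(seqs[anchored], pos[anchored], pos[anchored])
  if (mode == "per_genome") {
    if (is.null(genome_ids) || length(genome_ids) != length(seqs))
      stop("per_genome mode needs one genome_id per sequence")
    gsplit <- split(res, genome_ids[anchored])
    res <- vapply(gsplit, function(r)
      if (reference_residue %in% r) reference_residue else r[[1L]], "")
  }
  tab <- table(res)
  list(percent = setNames(100 * as.numeric(tab) / sum(tab), names(tab)),
       n_anchored = sum(anchored), n_excluded = sum(!anchored))
}

#' Extract anchored alignment windows
#'
#' Returns the \code{window}-column slice centered on the anchored focal
#' residue of each sequence; sequences that cannot be anchored or whose
#' window would run past either end are excluded.
#'
#' @inheritParams residueDistribution
#' @return Character vector of equal-length windows (possibly empty), with
#'   attribute \code{n_excluded}.
#' @export
anchorWindows <- function(seqs, config = anchorConfig()) {
  seqs <- as.character(seqs)
  half <- (config$window - 1L) %/% 2L
  pos <- vapply(seqs, anchorPosition, integer(1), config = config,
                USE.NAMES = FALSE)
  ok <- !is.na(pos) & pos - half >= 1L & pos + half <= nchar(seqs)
  out <- substr(seqs[ok], pos[ok] - half, pos[ok] + half)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Sequence-logo information content per column
#'
#' Per-column residue frequencies and information content in bits, as
#' rendered by standard logo tools: R = log2(20) - (H + e_n) with Shannon
#' entropy H and the small-sample correction e_n = 19 / (2 ln(2) n);
#' negative values are clamped to 0. Gaps and non-standard residues are
#' excluded from a column's count n.
#'
#' @param windows Character vector of equal-length aligned sequence
#'   windows (e.g. from \code{\link{anchorWindows}}).
#' @return A \code{data.frame} with one row per (column, residue) pair:
#'   \code{column}, \code{residue}, \code{frequency}, \code{n},
#'   \code{bits} (the column's information content, repeated across its
#'   residues).
#' @export
#' @examples
#' logoHeights(rep("K", 200))  # single pure column: 4.2534 bits
logoHeights <- function(windows) {
  windows <- as.character(windows)
  if (length(windows) == 0L) stop("no sequences (n = 0)")
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("all windows must have equal length")
  aa <- aminoAcids()
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  out <- lapply(seq_len(w), function(j) {
    col <- mat[, j]
    col <- col[col %in% aa]
    n <- length(col)
    if (n == 0L) stop("no standard residues in column ", j)
    f <- as.numeric(table(factor(col, levels = aa)))
    names(f) <- aa
    f <- f[f > 0] / n
    H <- -sum(f * log2(f))
    en <- 19 / (2 * log(2) * n)
    bits <- max(0, log2(20) - H - en)
    data.frame(column = j, residue = names(f), frequency = as.numeric(f),
               n = n, bits = bits, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
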