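# Jones-Taylor-Thornton (1992) empirical amino-acid replacement model, in the
# parameterisation used by distance programs: symmetric exchangeabilities S
# and stationary frequencies pi, with the rate matrix Q = S %*% diag(pi)
# rescaled to one expected substitution per site per unit branch length.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues in the historical substitution-matrix order
#' (ARNDCQEGHILKMFPSTWYV).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# lower triangle (column-major) of the JTT exchangeability counts
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQ <- c(
  A = 0.0767479232520768, R = 0.0516909483090517, N = 0.0426449573550427,
  D = 0.0515439484560515, C = 0.0198029801970198, Q = 0.0407519592480408,
  E = 0.0618299381700618, G = 0.0731519268480732, H = 0.0229439770560229,
  I = 0.0537609462390538, L = 0.0919039080960919, K = 0.0586759413240587,
  M = 0.0238259761740238, F = 0.0401259598740401, P = 0.0509009490990509,
  S = 0.0687649312350688, T = 0.0585649414350586, W = 0.0142609857390143,
  Y = 0.0321019678980321, V = 0.0660049339950660)

#' JTT stationary amino-acid frequencies
#'
#' @return Named numeric vector of length 20 summing to 1, in
#'   \code{\link{aminoAcids}} order.
#' @export
jttFrequencies <- function() .JTT_FREQ

# symmetric 20x20 exchangeability matrix
.jttExchangeMatrix <- function() {
  aa <- aminoAcids()
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- .JTT_EXCH
  S + t(S)
}

# normalized rate matrix Q (rows sum to 0, -sum(pi * diag(Q)) == 1)
.jttRateMatrix <- function() {
  pi <- .JTT_FREQ
  Q <- .jttExchangeMatrix() * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

# eigendecomposition of Q via the symmetrized form
# B = D^{1/2} Q D^{-1/2}; P(t) = V exp(L t) Vinv with V = D^{-1/2} U.
.jttEigen <- function() {
  pi <- .JTT_FREQ
  Q <- .jttRateMatrix()
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(V = e$vectors / sq, Vinv = t(e$vectors) * rep(sq, each = 20),
       lambda = e$values, pi = pi)
}

#' JTT transition-probability matrix
#'
#' Probability of replacing one amino acid by another along a branch of
#' length \code{t} expected substitutions per site under the
#' Jones-Taylor-Thornton model.
#'
#' @param t Branch length in expected substitutions per site (scalar >= 0).
#' @return A 20x20 row-stochastic matrix in \code{\link{aminoAcids}} order;
#'   the identity matrix at \code{t = 0}, and every row approaches the
#'   stationary frequency vector as \code{t} grows large.
#' @export
#' @examples
#' P <- jttTransition(0.3)
#' stopifnot(all(abs(rowSums(P) - 1) < 1e-10))
jttTransition <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length 't' must be a single non-negative number")
  aa <- aminoAcids()
  if (t == 0)
    return(matrix(diag(20), 20, 20, dimnames = list(aa, aa)))
  eg <- .efp_cache$jtt_eigen
  P <- eg$V %*% (exp(eg$lambda * t) * eg$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(aa, aa)
  P
}

# encode protein strings as integer vectors (1..20; 0 for gap/X/other)
.aaEncode <- function(x) {
  codes <- setNames(seq_len(20L), aminoAcids())
  lapply(strsplit(toupper(x), ""), function(ch) {
    v <- codes[ch]
    v[is.na(v)] <- 0L
    as.integer(v)
  })
}

.aaDecode <- function(idx) paste(aminoAcids()[idx], collapse = "")

# sample a residue evolved from each residue of 'states' over distance t
.evolveStates <- function(states, t, P = NULL) {
  if (is.null(P)) P <- jttTransition(t)
  vapply(states, function(s) sample.int(20L, 1L, prob = P[s, ]), integer(1))
}
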