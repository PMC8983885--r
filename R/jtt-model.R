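# JTT amino-acid substitution model (Jones, Taylor & Thornton 1992).
#
# The exchangeability matrix is the published integer lower triangle and the
# equilibrium frequencies are the published values, both in the conventional
# ARNDCQEGHILKMFPSTWYV residue order. The instantaneous rate matrix is
# normalized to one expected substitution per site at equilibrium.

#' Standard amino-acid alphabet used by the JTT model
#'
#' The 20 standard residues in the conventional ARNDCQEGHILKMFPSTWYV order.
#' @export
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# Published JTT exchangeabilities, lower triangle by rows (R,A), (N,A), (N,R), ...
.jtt_exch <- c(
   58,  54,  81,  56,  57, 105, 179,  27,  36,  30,  35,  54,  15, 194, 378,
  475,   9,  11, 298,  45,  16, 113, 310,  29, 137, 328,  22,  38, 646,  44,
    5,  74, 101,  64, 126,  20,  17, 528,  34,  86,  58,  81, 391,  47,  12,
  263,  30,  10,  15, 503, 232,   8,  70,  16,  10,  49, 767, 130, 112,  11,
    7,  26,  15,   4,  15,  59,  38,   4,  46,  31,   9,   5,  59,  69,  17,
   23,   7,  31,  78,  14, 223,  42, 115, 209,  62, 323,  26, 597,   9,  72,
  292,  43,   4, 164,  53,  51,  18,  24,  20, 119,  26,  12,   9, 181,  18,
    5,  18,  30,  32,  10,   7,  45,  23,   6,   6,  27,  14,   5,  24, 201,
   33,  55,   8,  47,  16,  56,  45,  33,  40, 115,  73,  46,   8, 573,  11,
  229,  21, 479,  89,  10,  40, 245,   9,  32, 961,  14, 388, 248, 102,  59,
   25,  52,  24, 180,  65,   4,  21,  47, 103,  10,   8,  14,  43,  16,  29,
  226,  24,  18, 323,  17,  92,  12,  53, 536,  62, 285, 118,   6,  10,  23,
  477,  35,  63,  38,  12,  21, 112,  71,  25,  16)

# Published JTT equilibrium frequencies (same residue order).
.jtt_freq <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' JTT equilibrium amino-acid frequencies
#'
#' @return Named numeric vector of length 20 (sums to 1), in
#'   [AA_ALPHABET] order.
#' @export
jtt_frequencies <- function() {
  f <- .jtt_freq / sum(.jtt_freq)
  names(f) <- AA_ALPHABET
  f
}

#' JTT instantaneous rate matrix
#'
#' Builds the reversible rate matrix Q from the published exchangeabilities
#' and equilibrium frequencies, scaled so that the expected substitution rate
#' at equilibrium is 1 (branch lengths are then substitutions per site).
#'
#' @return A 20 x 20 numeric matrix with rows summing to zero.
#' @export
jtt_rate_matrix <- function() {
  s <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  s[lower.tri(s)] <- .jtt_exch
  s <- s + t(s)
  pi <- jtt_frequencies()
  q <- s * rep(pi, each = 20L)
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))
  q / mu
}

# Cached symmetric eigendecomposition of Q: with D = diag(pi),
# B = D^{1/2} Q D^{-1/2} is symmetric, and
# P(t) = D^{-1/2} V exp(L t) V' D^{1/2}.
.jtt_cache <- new.env(parent = emptyenv())

jtt_eigen <- function() {
  if (is.null(.jtt_cache$eig)) {
    q <- jtt_rate_matrix()
    pi <- jtt_frequencies()
    sp <- sqrt(pi)
    b <- (sp %o% (1 / sp)) * q
    b <- (b + t(b)) / 2          # symmetrize away rounding noise
    e <- eigen(b, symmetric = TRUE)
    .jtt_cache$eig <- list(values = e$values, vectors = e$vectors,
                           sqrtpi = sp, pi = pi)
  }
  .jtt_cache$eig
}

#' JTT transition probability matrix
#'
#' P(t) = exp(Q r t) for elapsed time `t` (substitutions/site at rate 1) and
#' relative site rate `rate`.
#'
#' @param t Non-negative branch length in expected substitutions per site.
#' @param rate Relative rate multiplier (e.g. a discrete-Gamma category mean).
#' @return A 20 x 20 row-stochastic matrix.
#' @export
jtt_prob_matrix <- function(t, rate = 1) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0, rate >= 0)
  e <- jtt_eigen()
  w <- exp(e$values * t * rate)
  p <- (e$vectors %*% (w * t(e$vectors)))
  p <- p * ((1 / e$sqrtpi) %o% e$sqrtpi)
  p[p < 0] <- 0                  # clip eigen-roundoff
  p <- p / rowSums(p)
  dimnames(p) <- list(AA_ALPHABET, AA_ALPHABET)
  p
}

#' Discrete-Gamma rate category means
#'
#' Equal-probability discretization of the Gamma(shape, rate = shape)
#' distribution (mean 1): category k's rate is the conditional mean of the
#' distribution between the (k-1)/K and k/K quantiles (Yang's 1994
#' convention).
#'
#' @param shape Positive Gamma shape parameter (smaller = more rate
#'   heterogeneity among sites).
#' @param k Number of categories (default 5).
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 5L) {
  stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0,
            k >= 1L, k == as.integer(k))
  k <- as.integer(k)
  if (k == 1L) return(1)
  bounds <- qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  # E[X | a < X <= b] * P(a < X <= b) = pgamma(b, shape+1) - pgamma(a, shape+1)
  cum <- pgamma(bounds, shape = shape + 1, rate = shape)
  rates <- k * diff(cum)
  rates / mean(rates)
}

# Encode a protein string as 1-based indices into AA_ALPHABET; errors on any
# residue outside the 20 standard ones.
aa_index <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("non-standard residue '", chars[bad], "' at position ", bad)
  }
  idx
}
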