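# HKY85 substitution model: transition probabilities, discrete-gamma rates,
# and two-sequence maximum-likelihood distances.

DNA_STATES <- c("A", "C", "G", "T")

#' Substitution model parameters (HKY85 + discrete gamma)
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Equilibrium base frequencies in A, C, G, T order; must
#'   be nonnegative and sum to 1.
#' @param gamma_shape Shape of the gamma distribution of among-site rate
#'   variation (alpha > 0).
#' @param n_categories Number of equal-probability discrete categories
#'   (default 5).
#' @return Object of class `substitution_params`.
#' @export
substitution_params <- function(kappa = 4, base_freqs = rep(0.25, 4),
                                gamma_shape = 0.5, n_categories = 5L) {
  stopifnot(kappa > 0, gamma_shape > 0, n_categories >= 1)
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be 4 nonnegative values summing to 1")
  structure(list(kappa = kappa, base_freqs = as.numeric(base_freqs),
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "substitution_params")
}

#' Discrete-gamma category rates
#'
#' Mean rates of `ncat` equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretization for among-site rate
#' heterogeneity.
#'
#' @param alpha Gamma shape.
#' @param ncat Number of categories.
#' @return Numeric vector of length `ncat` with mean exactly 1.
#' @export
gamma_category_rates <- function(alpha, ncat) {
  if (ncat == 1) return(1)
  q <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  ncat * diff(p)
}

#' HKY85 transition probability matrix
#'
#' @param b Branch length in expected substitutions per site.
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Base frequencies (A, C, G, T).
#' @return 4x4 matrix `P[i, j] = P(j at end | i at start)`.
#' @export
hky_pmat <- function(b, kappa, base_freqs) {
  P <- hky_pmat_cpp(b, kappa, base_freqs)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

# Encode nucleotide characters as 0:3 (A,C,G,T); anything else (gap, N,
# ambiguity codes) becomes 4 = missing.
encode_dna <- function(x) {
  codes <- match(toupper(x), DNA_STATES) - 1L
  codes[is.na(codes)] <- 4L
  codes
}

two_seq_loglik <- function(counts, d, kappa, freqs) {
  # counts: 4x4 table of (state in A, state in B) over shared ungapped sites
  if (d < 0) return(-Inf)
  P <- hky_pmat_cpp(d, kappa, freqs)
  ll <- sum(counts * log(pmax(freqs * P, 1e-300)))
  ll
}

#' Pairwise maximum-likelihood distance under HKY85
#'
#' Estimates the expected number of substitutions per site between two
#' aligned sequences, maximizing the two-sequence likelihood jointly over
#' the distance and (unless fixed) the transition/transversion ratio kappa.
#' Frequencies are empirical, pooled over both sequences, unless supplied.
#'
#' Distances that run into the saturation cap (10 substitutions/site) are
#' returned as the cap value with attribute `saturated = TRUE`.
#'
#' @param seq_a,seq_b Character vectors (aligned, equal length).
#' @param freqs Optional base frequencies; default empirical.
#' @param fix_kappa Optional fixed kappa (numeric); default `NULL` estimates
#'   kappa jointly.
#' @param cap Saturation cap on the distance (substitutions/site).
#' @return Numeric distance with attributes `kappa`, `saturated`, and
#'   `n_sites` (shared ungapped sites used).
#' @export
hky_distance <- function(seq_a, seq_b, freqs = NULL, fix_kappa = NULL,
                         cap = 10) {
  if (length(seq_a) != length(seq_b)) stop("sequences must be aligned (equal length)")
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  ok <- a < 4L & b < 4L
  n <- sum(ok)
  if (n < 1) stop("no shared ungapped sites")
  counts <- matrix(0, 4, 4)
  tab <- table(factor(a[ok], levels = 0:3), factor(b[ok], levels = 0:3))
  counts[] <- as.numeric(tab)
  if (is.null(freqs)) {
    cnt <- tabulate(c(a[ok], b[ok]) + 1L, nbins = 4)
    freqs <- (cnt + 0.5) / sum(cnt + 0.5)  # light smoothing avoids zeros
  }
  p_diff <- 1 - sum(diag(counts)) / n
  if (p_diff == 0) {
    return(structure(0, kappa = if (is.null(fix_kappa)) NA_real_ else fix_kappa,
                     saturated = FALSE, n_sites = n))
  }
  d0 <- max(min(-0.75 * log(max(1 - 4 * p_diff / 3, 1e-6)), cap / 2), 1e-4)
  if (is.null(fix_kappa)) {
    fit <- stats::optim(
      c(log(d0), log(2)),
      function(par) -two_seq_loglik(counts, exp(par[1]), exp(par[2]), freqs),
      method = "L-BFGS-B",
      lower = c(log(1e-8), log(0.02)), upper = c(log(cap), log(500)))
    d <- exp(fit$par[1]); kap <- exp(fit$par[2])
  } else {
    fit <- stats::optimize(
      function(ld) -two_seq_loglik(counts, exp(ld), fix_kappa, freqs),
      lower = log(1e-8), upper = log(cap))
    d <- exp(fit$minimum); kap <- fix_kappa
  }
  saturated <- d > 0.999 * cap
  if (saturated) d <- cap
  structure(d, kappa = kap, saturated = saturated, n_sites = n)
}
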