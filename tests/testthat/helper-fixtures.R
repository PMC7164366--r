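# Shared fixture builders; everything is generated in code, deterministically.

fix_sub <- function() {
  substitution_params(kappa = 4, base_freqs = c(0.27, 0.23, 0.26, 0.24),
                      gamma_shape = 0.5, n_categories = 5)
}

# small dated tree + alignment in one call
fix_dataset <- function(n_tips = 8, root_age = 0.4, model = "STR",
                        mu = 0.1, sigma2 = 0, n_codons = 200, seed = 1,
                        cp = c(1, 1, 1)) {
  tt <- simulate_timetree(n_tips, root_age, seed = seed)
  spec <- clock_model_spec(model, mu, sigma2)
  r <- simulate_branch_rates(tt, spec, seed = seed + 1)
  aln <- simulate_alignment(tt, r, fix_sub(), n_codons, cp_multipliers = cp,
                            seed = seed + 2)
  list(tt = tt, rates = r, aln = aln)
}

# timetree rescaled to Ma for calibration construction
tt_in_ma <- function(tt) {
  tt$ages <- tt$ages * 100
  tt$root_age <- tt$root_age * 100
  tt$phy$edge.length <- tt$phy$edge.length * 100
  tt
}

# tiny hand-built coding alignment
aln_from_strings <- function(seqs, gene_id = "g1", frame_offset = 0) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  gene_alignment(gene_id, m, frame_offset)
}

# matrix exponential via eigendecomposition (independent of the package's
# closed-form transition probabilities)
expm_eigen <- function(Q, t) {
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

hky_Q <- function(kappa, pi) {
  R <- c(TRUE, FALSE, TRUE, FALSE)  # purines A, G
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- ifelse(R[i] == R[j], kappa, 1) * pi[j]
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))  # mean rate 1
}
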