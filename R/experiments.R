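# Replicated synthetic experiments: clock-model recovery, dating coverage,
# and the complete-vs-reduced (clocklike-subset) comparison. These drive
# the package's validation studies at desk scale.

#' Clock-model recovery experiment
#'
#' Simulates datasets under a known clock model (strict, or independent
#' lognormal rates with a stated sigma2), runs exact-likelihood
#' stepping-stone model selection among STR/IR/AR, and reports the winning
#' model per replicate. Recovery means: STR data select STR; IR data select
#' a relaxed clock (IR or AR) over STR.
#'
#' @param n_replicates Replicates per generating model.
#' @param n_taxa,n_codons Data size per replicate (default 20 taxa, 334
#'   codons = 1 kb).
#' @param sigma2_ir Log-rate variance of the IR generating model.
#' @param root_age Tree root age in 100-Myr units.
#' @param K,a Stepping-stone schedule.
#' @param n_iter,sample_every Power-posterior chain length per stone.
#' @param seed Master seed.
#' @return Data frame: `generating`, `replicate`, `winner`, `recovered`,
#'   and the three log marginal likelihoods.
#' @export
experiment_clock_recovery <- function(n_replicates = 10, n_taxa = 20,
                                      n_codons = 334, sigma2_ir = 0.5,
                                      root_age = 0.364, K = 8, a = 0.3,
                                      n_iter = 250, sample_every = 2,
                                      seed = 1) {
  sub <- substitution_params(kappa = 4,
                             base_freqs = c(0.27, 0.23, 0.26, 0.24),
                             gamma_shape = 0.5)
  rows <- list()
  for (gen in c("STR", "IR")) {
    for (rep in seq_len(n_replicates)) {
      s <- derive_seed(seed, paste0("recov.", gen, ".", rep))
      tt <- simulate_timetree(n_taxa, root_age, seed = s)
      spec <- clock_model_spec(gen, 0.1, if (gen == "STR") 0 else sigma2_ir)
      r <- simulate_branch_rates(tt, spec, seed = s + 1)
      aln <- simulate_alignment(tt, r, sub, n_codons, seed = s + 2)
      st <- mcmc_settings(n_iter = n_iter, sample_every = sample_every,
                          n_chains = 1, seed = s + 3)
      sel <- select_clock_model(list(partitions = list(aln), sub = sub),
                                tt$phy, settings = st, K = K, a = a)
      winner <- sel$table$model[1]
      rows[[length(rows) + 1L]] <- data.frame(
        generating = gen, replicate = rep, winner = winner,
        recovered = if (gen == "STR") winner == "STR"
        else winner %in% c("IR", "AR"),
        logml_STR = sel$estimates[["STR"]]$log_ml,
        logml_IR = sel$estimates[["IR"]]$log_ml,
        logml_AR = sel$estimates[["AR"]]$log_ml,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Dating coverage experiment under the autocorrelated clock
#'
#' Simulates fossil-calibrated datasets under the AR clock, dates them with
#' the approximate-likelihood MCMC, and reports how often true node ages
#' fall inside the 95% credibility intervals (pooled over datasets), plus a
#' prior-only check that the sampled root-calibration quantiles match the
#' analytic values.
#'
#' @param n_datasets Number of synthetic datasets.
#' @param n_taxa Tips per tree.
#' @param n_partitions Partitions (independent gene alignments).
#' @param n_codons Codons per partition (default 667 = 2 kb).
#' @param sigma2 AR diffusion parameter.
#' @param root_age Root age (100-Myr units).
#' @param n_anchors Calibrated non-root nodes per dataset.
#' @param n_iter,sample_every Dating chain length.
#' @param seed Master seed.
#' @return List: `per_node` (data frame of truth vs CI), `coverage`,
#'   `n_nodes`, `prior_q` (sampled and analytic root quantiles of the
#'   fossil root calibration), `prior_q_err` (max relative error).
#' @export
experiment_coverage <- function(n_datasets = 20, n_taxa = 16,
                                n_partitions = 3, n_codons = 667,
                                sigma2 = 0.5, root_age = 0.364,
                                n_anchors = 3, n_iter = 20000,
                                sample_every = 10, seed = 1) {
  sub <- substitution_params(kappa = 4,
                             base_freqs = c(0.27, 0.23, 0.26, 0.24),
                             gamma_shape = 0.5)
  spec <- clock_model_spec("AR", 0.1, sigma2)
  per_node <- list()
  for (ds in seq_len(n_datasets)) {
    s <- derive_seed(seed, paste0("cover.", ds))
    tt <- simulate_timetree(n_taxa, root_age, seed = s)
    surfs <- lapply(seq_len(n_partitions), function(p) {
      r <- simulate_branch_rates(tt, spec, seed = s + 10 * p)
      aln <- simulate_alignment(tt, r, sub, n_codons, seed = s + 10 * p + 1)
      suppressWarnings(build_approx_surface(aln, tt$phy, sub))
    })
    ttma <- tt
    ttma$ages <- tt$ages * 100; ttma$root_age <- tt$root_age * 100
    ttma$phy$edge.length <- tt$phy$edge.length * 100
    anchors <- eligible_anchor_pairs(tt, n_anchors)
    cals <- make_calibrations(ttma, anchors, rel_offsets = c(0.1, 0.1),
                              tails = c(0, 0.025))
    st <- mcmc_settings(n_iter = n_iter, sample_every = sample_every,
                        n_chains = 1, seed = s + 5)
    tr <- run_mcmc("AR", surfs, tt$phy, cals, settings = st)
    sm <- summarize_posterior(tr)
    nodes <- sm[!is.na(sm$node), ]
    per_node[[ds]] <- data.frame(
      dataset = ds, node = nodes$node, truth = tt$ages[nodes$node] * 100,
      mean = nodes$mean, lo = nodes$q2.5, hi = nodes$q97.5)
  }
  pn <- do.call(rbind, per_node)
  inside <- pn$truth >= pn$lo & pn$truth <= pn$hi
  # prior-only quantile fidelity for the fossil root calibration
  fc <- fossil_calibration_table()[1, ]
  tt0 <- simulate_timetree(8, fc$t_min * 1.2 / 100, seed = derive_seed(seed, "prior"))
  rt <- root_anchor_tips(tt0$phy)
  cal0 <- calibration_set(data.frame(
    tip_a = rt[1], tip_b = rt[2], t_min = fc$t_min, min_type = fc$min_type,
    t_max = fc$t_max, max_type = fc$max_type, p_lower = fc$p_lower,
    p_upper = fc$p_upper))
  st0 <- mcmc_settings(n_iter = 40000, sample_every = 8, n_chains = 1,
                       seed = derive_seed(seed, "prior.chain"))
  tr0 <- run_mcmc("STR", NULL, tt0$phy, cal0, settings = st0)
  sampled <- quantile(post_burnin(tr0)[[paste0("t_", 9)]], c(0.025, 0.975),
                      names = FALSE)
  analytic <- c(fc$t_min + 0.025 * (fc$t_max - fc$t_min) / 0.975, fc$t_max)
  list(per_node = pn, coverage = mean(inside), n_nodes = nrow(pn),
       prior_q = data.frame(q = c(2.5, 97.5), sampled = sampled,
                            analytic = analytic),
       prior_q_err = max(abs(sampled - analytic) / analytic))
}

# anchor pairs for non-root internal clades with >= 2 tips
eligible_anchor_pairs <- function(tt, n_anchors) {
  phy <- tt$phy
  ntip <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)
  sizes <- lengths(pp)
  cand <- setdiff(order(-sizes), 1L)
  cand <- cand[sizes[cand] >= 2]
  lapply(utils::head(cand, n_anchors), function(i) {
    node <- ntip + i
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    below <- function(v) if (v <= ntip) phy$tip.label[v]
    else phy$tip.label[pp[[v - ntip]][1]]
    c(below(kids[1]), below(kids[2]))
  })
}

#' Complete-vs-reduced dataset comparison experiment
#'
#' For each replicate, simulates a full gene set with heterogeneous
#' clocklikeness (half the genes strict-clock, half with AR rate
#' variation), selects the most clocklike subset from the true gene trees,
#' dates both datasets with the same MCMC settings, and reports the mean
#' 95% CI-width ratio (reduced/full) plus the infinite-sites slopes of the
#' full data at 3, 6, and 10 partitions.
#'
#' @param n_replicates Replicates.
#' @param n_taxa,n_genes,n_codons Data size (default 12 taxa, 60 genes of
#'   100 codons).
#' @param n_reduced Size of the clocklike subset (default 10).
#' @param sigma2 AR diffusion for the non-clocklike half.
#' @param rate_range Range of per-gene rate multipliers (slow to fast
#'   genes; default spans a 25-fold spread, the order of magnitude seen
#'   across real protein-coding loci and the reason rate binning exists).
#' @param root_age Root age (100-Myr units).
#' @param n_iter,sample_every Dating chain length.
#' @param seed Master seed.
#' @return Data frame per replicate: `width_ratio`, `slope_3p`,
#'   `slope_6p`, `slope_10p`, `slope_reduced`.
#' @export
experiment_reduced_comparison <- function(n_replicates = 10, n_taxa = 10,
                                          n_genes = 60, n_codons = 100,
                                          n_reduced = 10, sigma2 = 0.5,
                                          rate_range = c(0.2, 5),
                                          root_age = 0.364, n_iter = 4000,
                                          sample_every = 2, seed = 1) {
  sub <- substitution_params(kappa = 4,
                             base_freqs = c(0.27, 0.23, 0.26, 0.24),
                             gamma_shape = 0.5)
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    s <- derive_seed(seed, paste0("reduced.", rep))
    tt <- simulate_timetree(n_taxa, root_age, seed = s)
    ids <- sprintf("g%03d", seq_len(n_genes))
    gmult <- exp(seq(log(rate_range[1]), log(rate_range[2]),
                     length.out = n_genes))
    alns <- list(); gtrees <- list()
    for (i in seq_len(n_genes)) {
      clockish <- i %% 2 == 0  # alternate so each rate bin holds both kinds
      spec <- clock_model_spec(if (clockish) "STR" else "AR", 0.1,
                               if (clockish) 0 else sigma2)
      r <- simulate_branch_rates(tt, spec, seed = s + 7 * i) * gmult[i]
      alns[[ids[i]]] <- simulate_alignment(tt, r, sub, n_codons,
                                           seed = s + 7 * i + 1,
                                           gene_id = ids[i])
      g <- tt$phy
      g$edge.length <- (tt$ages[g$edge[, 1]] - tt$ages[g$edge[, 2]]) * r
      gtrees[[ids[i]]] <- g
    }
    ttma <- tt
    ttma$ages <- tt$ages * 100; ttma$root_age <- tt$root_age * 100
    ttma$phy$edge.length <- tt$phy$edge.length * 100
    cals <- make_calibrations(ttma, eligible_anchor_pairs(tt, 2),
                              rel_offsets = c(0.1, 0.1),
                              tails = c(0, 0.025))
    tab <- gene_rate_table(alns, primary_pair = c("t1", "t2"),
                           fallback_taxa = paste0("t", 3:n_taxa))
    st <- mcmc_settings(n_iter = n_iter, sample_every = sample_every,
                        n_chains = 1, seed = s + 3)
    date_scheme <- function(scheme, genes) {
      blocks <- partition_alignments(scheme, genes)
      surfs <- lapply(blocks, function(b)
        suppressWarnings(build_approx_surface(b, tt$phy, sub)))
      tr <- run_mcmc("AR", surfs, tt$phy, cals, settings = st)
      summarize_posterior(tr)
    }
    s3 <- bin_genes(tab, 3)
    sm_full3 <- date_scheme(s3, alns)
    sm_full6 <- date_scheme(split_codon_positions(s3), alns)
    sm_full10 <- date_scheme(bin_genes(tab, 10), alns)
    top <- rank_clocklike(gtrees, tt$phy, n_reduced)$gene_id
    tab_red <- tab[tab$gene_id %in% top, , drop = FALSE]
    sm_red <- date_scheme(bin_genes(tab_red, 3), alns[top])
    cmp <- compare_datasets(sm_full3, sm_red)
    rows[[rep]] <- data.frame(
      replicate = rep, width_ratio = cmp$mean_width_ratio,
      slope_3p = infinite_sites_fit(sm_full3)$slope,
      slope_6p = infinite_sites_fit(sm_full6)$slope,
      slope_10p = infinite_sites_fit(sm_full10)$slope,
      slope_reduced = cmp$slope_reduced)
  }
  do.call(rbind, rows)
}
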