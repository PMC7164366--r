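# Metropolis-Hastings dating engine: R-facing setup around the compiled
# sampler, plus trace containers, ESS, and posterior summaries.
#
# Ages are supplied and reported in Ma; internally the sampler works in
# 100-Myr units, the scale on which the Gamma(2, 20) rate prior and the
# Gamma(2, 2) diffusion prior are expressed.

TIME_UNIT_MA <- 100

#' MCMC settings
#'
#' Desk-scale defaults (2e5 sweeps sampled every 20, two chains, 50%
#' burn-in); production-scale dating runs would use far longer chains with
#' the same machinery.
#'
#' @param n_iter Sweeps per chain (one sweep updates every parameter once).
#' @param sample_every Record every this many sweeps.
#' @param burnin_fraction Fraction of each chain discarded by summaries
#'   (step-size tuning also stops at this point).
#' @param n_chains Number of independent chains.
#' @param seed Master seed; chain c uses a seed derived from `(seed, c)`.
#' @param steps Initial proposal step sizes, named `age`, `root`, `rate`,
#'   `mu`, `sigma2`, `scale`.
#' @param beta Likelihood power (1 = posterior; in (0, 1] for power
#'   posteriors; 0 samples the prior while still recording the likelihood).
#' @param tune Auto-tune step sizes during burn-in toward 20-40%
#'   acceptance?
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 2e5, sample_every = 20,
                          burnin_fraction = 0.5, n_chains = 2, seed = 1L,
                          steps = c(age = 0.3, root = 0.3, rate = 0.5,
                                    mu = 0.5, sigma2 = 0.8, scale = 0.2),
                          beta = 1, tune = TRUE) {
  stopifnot(n_iter >= sample_every, burnin_fraction >= 0,
            burnin_fraction < 1, beta >= 0, beta <= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 sample_every = as.integer(sample_every),
                 burnin_fraction = burnin_fraction,
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 steps = steps, beta = beta, tune = tune),
            class = "mcmc_settings")
}

clock_code <- function(model) {
  switch(model, STR = 0L, IR = 1L, AR = 2L,
         stop("unknown clock model: ", model))
}

# Build the per-internal-node calibration matrix (internal units) and check
# that the root is calibrated.
calib_matrix <- function(cals, phy) {
  n <- ape::Ntip(phy)
  nint <- phy$Nnode
  cm <- matrix(0, nint, 5)
  nodes <- calibration_nodes(cals, phy)
  if (anyDuplicated(nodes)) stop("multiple calibrations anchor the same node")
  if (!((n + 1L) %in% nodes))
    stop("a root calibration is required for dating")
  for (i in seq_along(nodes)) {
    r <- nodes[i] - n
    cm[r, ] <- c(1, cals$t_min[i] / TIME_UNIT_MA, cals$t_max[i] / TIME_UNIT_MA,
                 cals$p_lower[i], cals$p_upper[i])
  }
  cm
}

# Calibration-consistent initial ages (internal units). Deterministic shape
# (clade-size depths) with random retries until the joint prior is finite.
init_ages <- function(phy, cm, bd, seed) {
  n <- ape::Ntip(phy)
  nnode <- n + phy$Nnode
  root <- n + 1L
  ndesc <- vapply(ape::prop.part(phy), length, integer(1))  # per internal node
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  set.seed(derive_seed(seed, "init"))
  for (attempt in 1:200) {
    ages <- numeric(nnode)
    rroot <- cm[1, ]
    span <- rroot[3] - rroot[2]
    ages[root] <- stats::runif(1, rroot[2] + 0.05 * span, rroot[3] - 0.05 * span)
    jit <- stats::runif(phy$Nnode, 0.75, 0.95)
    for (e in seq_len(nrow(pre))) {
      child <- pre[e, 2]
      if (child <= n) next
      par_age <- ages[pre[e, 1]]
      r <- child - n
      prop <- (ndesc[r] - 1) / max(ndesc[1] - 1, 1)
      a <- par_age * max(prop, 0.05) * jit[r]
      if (cm[r, 1] == 1) {  # aim inside the calibration window
        lo <- cm[r, 2]; hi <- min(cm[r, 3], par_age * 0.999)
        if (hi > lo) a <- lo + (hi - lo) * stats::runif(1, 0.25, 0.75)
      }
      ages[child] <- min(a, par_age * 0.999)
    }
    ok <- all(ages[pre[, 1]] > ages[pre[, 2]] | pre[, 2] <= n) &&
      all(ages[pre[, 2]] > 0 | pre[, 2] <= n)
    if (!ok) next
    lp <- ages_logprior(ages, phy, cm, bd)
    if (is.finite(lp)) return(ages)
  }
  stop("could not initialize node ages consistent with the calibrations")
}

# time prior in internal units, mirroring the sampler
ages_logprior <- function(ages, phy, cm, bd) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  if (any(ages[phy$edge[, 1]] <= ages[phy$edge[, 2]])) return(-Inf)
  lp <- 0
  for (v in (n + 1L):(n + phy$Nnode)) {
    r <- v - n
    lp <- lp + if (cm[r, 1] == 1) {
      calibration_logdensity(ages[v], data.frame(t_min = cm[r, 2],
                                                 t_max = cm[r, 3],
                                                 p_lower = cm[r, 4],
                                                 p_upper = cm[r, 5]))
    } else {
      bd_kernel_logdensity(ages[v], ages[root], bd)
    }
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

# Assemble the partition descriptors handed to the compiled sampler.
build_parts <- function(data, phy) {
  if (is.null(data)) return(list(list(mode = 0L)))
  if (inherits(data, "approx_surface")) data <- list(data)
  if (all(vapply(data, inherits, TRUE, "approx_surface"))) {
    # surfaces index rooted edges in phy's own edge order; the sampler walks
    # edges in postorder, so permute the map accordingly
    po <- postorder_edges(phy)
    perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                  paste(phy$edge[, 1], phy$edge[, 2]))
    return(lapply(data, function(s) {
      list(mode = 2L, emap = as.integer(s$emap[perm]), bhat = s$b_hat,
           g = s$g, H = s$H, logl_hat = s$logl_hat)
    }))
  }
  # exact: list(partitions = list of matrices, sub = substitution_params)
  stopifnot(is.list(data$partitions), inherits(data$sub, "substitution_params"))
  po <- postorder_edges(phy)
  lapply(data$partitions, function(m) {
    m <- aln_matrix(m)
    pat <- compress_patterns(m, phy)
    list(mode = 1L, tipstate = pat$tipstate, weights = pat$weights,
         kappa = data$sub$kappa, pi = data$sub$base_freqs,
         rates = gamma_category_rates(data$sub$gamma_shape,
                                      data$sub$n_categories))
  })
}

#' Run the dating MCMC
#'
#' Metropolis-Hastings over internal node ages, branch rates (IR/AR),
#' per-partition mean rates and diffusion parameters, with a whole-tree
#' age/rate rescaling mixing move. Node-age proposals slide within the
#' parent/child bracket; step sizes are tuned during burn-in to 20-40%
#' acceptance and frozen afterwards.
#'
#' @param model `"STR"`, `"IR"`, or `"AR"`.
#' @param data `NULL` for a prior-only run, a list of
#'   [build_approx_surface()] surfaces (approximate likelihood), or
#'   `list(partitions = <list of alignments>, sub = <substitution_params>)`
#'   for exact likelihood.
#' @param topology Fixed rooted binary species topology (`phylo`).
#' @param cals A [calibration_set()] including a root calibration (ages in
#'   Ma).
#' @param bd `bd_params` for the node-age prior.
#' @param settings An [mcmc_settings()].
#' @return Object of class `mcmc_trace`: `chains` (list of data frames:
#'   node ages in Ma as `t_<node>`, per-partition `mu`, `sigma2`,
#'   `meanrate` in substitutions/site/100 Myr, `logL`, `logPrior`,
#'   `logPost`), plus provenance (`settings`, `model`, `acceptance`,
#'   `node_ids`, `topology`).
#' @export
run_mcmc <- function(model, data, topology, cals, bd = bd_params(),
                     settings = mcmc_settings()) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (inherits(model, "clock_model_spec")) model <- model$model
  phy <- topology
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("topology must be rooted and binary")
  n <- ape::Ntip(phy)
  cm <- calib_matrix(cals, phy)
  bdp <- as_bd(bd)
  parts <- build_parts(data, phy)
  npart <- length(parts)
  po <- postorder_edges(phy)
  nedge <- nrow(po$edge)
  cl <- clock_code(model)

  chains <- vector("list", settings$n_chains)
  acc <- vector("list", settings$n_chains)
  steps_out <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    chseed <- derive_seed(settings$seed, paste0("chain", ch))
    ages0 <- init_ages(phy, cm, bdp, chseed)
    mu0 <- rep(0.1, npart)
    s20 <- rep(if (cl == 0L) 0 else 1, npart)
    rate0 <- matrix(0.1, nedge, npart)
    burnin_sweeps <- as.integer(settings$n_iter * settings$burnin_fraction)
    res <- run_mcmc_cpp(po$edge, n, ages0, cm,
                        c(bdp$lambda, bdp$mu_death, bdp$rho), cl, parts,
                        mu0, s20, rate0,
                        list(n_iter = settings$n_iter,
                             sample_every = settings$sample_every,
                             burnin_sweeps = burnin_sweeps,
                             beta = settings$beta, seed = chseed,
                             steps = as.numeric(settings$steps),
                             tune = settings$tune))
    sm <- res$samples
    node_ids <- (n + 1L):(n + phy$Nnode)
    cn <- c(paste0("t_", node_ids),
            unlist(lapply(seq_len(npart), function(p)
              paste0(c("mu", "sigma2", "meanrate"), p))),
            "logL", "logPrior", "logPost")
    colnames(sm) <- cn
    df <- as.data.frame(sm)
    df[paste0("t_", node_ids)] <- df[paste0("t_", node_ids)] * TIME_UNIT_MA
    df <- cbind(state = seq_len(nrow(df)) * settings$sample_every, df)
    chains[[ch]] <- df
    acc[[ch]] <- setNames(res$acceptance,
                          c("age", "root", "rate", "mu", "sigma2", "scale"))
    steps_out[[ch]] <- res$steps
  }
  structure(list(chains = chains, settings = settings, model = model,
                 acceptance = acc, steps = steps_out,
                 node_ids = (n + 1L):(n + phy$Nnode), topology = phy,
                 npart = npart, beta = settings$beta),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace: %d chain(s) x %d samples, model %s, beta %.3g\n",
              length(x$chains), nrow(x$chains[[1]]), x$model, x$beta))
  invisible(x)
}

post_burnin <- function(trace, burnin_fraction = NULL) {
  bf <- burnin_fraction %||% trace$settings$burnin_fraction
  do.call(rbind, lapply(trace$chains, function(df) {
    df[df$state > bf * max(df$state), , drop = FALSE]
  }))
}

#' Effective sample size of an MCMC series
#'
#' `n / (1 + 2 * sum of autocorrelations)`, with the sum truncated by the
#' initial-positive-sequence rule (consecutive lag-pair sums are added while
#' positive). A constant series is degenerate and reports ESS 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param series Numeric vector (length >= 10).
#' @return ESS (numeric), possibly with attribute `degenerate`.
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10) stop("series too short for an ESS estimate")
  if (stats::sd(series) == 0 || !is.finite(stats::sd(series)))
    return(structure(0, degenerate = TRUE))
  x <- series - mean(series)
  # autocovariance via FFT
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m
  rho <- ac / ac[1]
  tau <- 1
  k <- 1
  while (k + 1 < n) {
    gam <- rho[k + 1] + if (k + 2 <= n) rho[k + 2] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
    k <- k + 2
  }
  max(n / tau, 1e-12)
}

#' Posterior summaries of node ages and hyperparameters
#'
#' Equal-tail 95% credibility intervals (2.5% and 97.5% quantiles), CI
#' width, ESS, and a low-ESS flag (threshold 100, the conventional
#' convergence floor).
#'
#' @param trace An `mcmc_trace`.
#' @param burnin_fraction Override the burn-in fraction recorded in the
#'   settings.
#' @param min_samples Minimum post-burn-in sample count (error below).
#' @return Data frame: `parameter`, `node` (ape node id or `NA`), `mean`,
#'   `q2.5`, `q97.5`, `ci_width`, `ess`, `low_ess`.
#' @export
summarize_posterior <- function(trace, burnin_fraction = NULL,
                                min_samples = 100) {
  df <- post_burnin(trace, burnin_fraction)
  if (nrow(df) < min_samples)
    stop("insufficient post-burn-in samples (", nrow(df), " < ",
         min_samples, ")")
  pars <- setdiff(names(df), "state")
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- df[[p]]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    e <- ess(x)
    data.frame(parameter = p,
               node = if (grepl("^t_", p)) as.integer(sub("^t_", "", p))
               else NA_integer_,
               mean = mean(x), q2.5 = q[1], q97.5 = q[2],
               ci_width = q[2] - q[1], ess = as.numeric(e),
               low_ess = as.numeric(e) < 100, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a trace in Tracer-compatible TSV form
#'
#' @param trace An `mcmc_trace`.
#' @param file Output path (chain 1; other chains get `.chainN` suffixes).
#' @export
write_trace <- function(trace, file) {
  for (ch in seq_along(trace$chains)) {
    f <- if (ch == 1) file else paste0(file, ".chain", ch)
    df <- trace$chains[[ch]]
    con <- file(f, "w")
    writeLines(sprintf("# clockdate trace: model=%s beta=%g seed=%d chain=%d",
                       trace$model, trace$beta, trace$settings$seed, ch), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(file)
}

#' Dated tree with posterior mean ages and CI annotations
#'
#' @param trace An `mcmc_trace`.
#' @param ... Passed to [summarize_posterior()].
#' @return A `phylo` with branch lengths in Ma (posterior mean ages) and
#'   `node.label` strings `mean[lo,hi]`.
#' @export
dated_tree <- function(trace, ...) {
  sm <- summarize_posterior(trace, ...)
  sm <- sm[!is.na(sm$node), , drop = FALSE]
  phy <- trace$topology
  ages <- numeric(ape::Ntip(phy) + phy$Nnode)
  ages[sm$node] <- sm$mean
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  phy$node.label <- sprintf("%.2f[%.2f,%.2f]", sm$mean, sm$q2.5, sm$q97.5)
  phy
}
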