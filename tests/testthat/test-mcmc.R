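# The Metropolis-Hastings dating engine: determinism, prior sampling
# fidelity, ESS, posterior summaries, convergence across chains.

fix_cals <- function(tt, offsets = c(0.15, 0.2), tails = c(0, 0.025), ...) {
  make_calibrations(tt_in_ma(tt), rel_offsets = offsets, tails = tails, ...)
}

test_that("identical seeds give identical traces", {
  tt <- simulate_timetree(6, 0.4, seed = 71)
  cals <- fix_cals(tt)
  st <- mcmc_settings(n_iter = 1000, sample_every = 5, n_chains = 1,
                      seed = 7)
  t1 <- run_mcmc("IR", NULL, tt$phy, cals, settings = st)
  t2 <- run_mcmc("IR", NULL, tt$phy, cals, settings = st)
  expect_identical(t1$chains, t2$chains)
})

test_that("every sampled state respects ordering and hard bounds", {
  tt <- simulate_timetree(8, 0.4, seed = 72)
  cals <- fix_cals(tt, offsets = c(0.1, 0.15))
  st <- mcmc_settings(n_iter = 4000, sample_every = 4, n_chains = 1,
                      seed = 8)
  tr <- run_mcmc("AR", NULL, tt$phy, cals, settings = st)
  df <- tr$chains[[1]]
  phy <- tt$phy
  n <- ape::Ntip(phy)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    if (c > n)
      expect_true(all(df[[paste0("t_", p)]] > df[[paste0("t_", c)]]))
  }
  for (i in seq_len(nrow(cals))) {
    ages <- df[[paste0("t_", cals$node[i])]]
    expect_true(all(ages >= cals$t_min[i]))  # hard minimum
  }
})

test_that("prior-only sampling reproduces calibration quantiles", {
  tt <- simulate_timetree(6, 0.4, seed = 73)
  cals <- fix_cals(tt, offsets = c(0.2, 0.3))
  st <- mcmc_settings(n_iter = 30000, sample_every = 10, n_chains = 1,
                      seed = 9)
  tr <- run_mcmc("IR", NULL, tt$phy, cals, settings = st)
  s <- clockdate:::post_burnin(tr)
  root <- paste0("t_", 7)
  q <- quantile(s[[root]], c(0.025, 0.975), names = FALSE)
  tL <- cals$t_min[1]; tU <- cals$t_max[1]
  h <- 0.975 / (tU - tL)
  qa <- c(tL + 0.025 / 0.975 * (tU - tL) / (1 / 0.975),
          tU - log((1 - 0.975) / 0.025) * 0.025 / h)
  qa <- c(tL + (tU - tL) * 0.025 / 0.975, tU)  # 2.5% and 97.5% analytic
  expect_lt(abs(q[1] - qa[1]) / qa[1], 0.02)
  expect_lt(abs(q[2] - qa[2]) / qa[2], 0.02)
})

test_that("a 3-taxon prior-only marginal matches quadrature", {
  # root pinned by a narrow window; the single free age then follows the
  # BD kernel conditional on the root
  phy <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  cals <- calibration_set(data.frame(
    tip_a = "a", tip_b = "c", t_min = 0.999 * 100, min_type = "hard",
    t_max = 1.001 * 100, max_type = "hard"))
  st <- mcmc_settings(n_iter = 2e5, sample_every = 2, n_chains = 1,
                      seed = 10)
  tr <- run_mcmc("STR", NULL, phy, cals, settings = st)
  s <- clockdate:::post_burnin(tr)
  ages <- s[[paste0("t_", 5)]] / 100
  grid <- seq(0.01, 0.99, 0.01)
  emp <- stats::ecdf(ages)(grid)
  theo <- clockdate:::bd_kernel_cdf(grid, 1, 1, 1, 0.1)
  expect_lt(max(abs(emp - theo)), 0.03)
})

test_that("the whole-tree scaling leaves the likelihood term invariant", {
  d <- fix_dataset(n_tips = 8, n_codons = 100, seed = 74)
  surf <- suppressWarnings(build_approx_surface(d$aln, d$tt$phy, fix_sub()))
  rates <- rep(0.1, nrow(d$tt$phy$edge))
  l1 <- approx_loglik(surf, ages = d$tt$ages, rates = rates,
                      rooted_topology = d$tt$phy)
  c0 <- 1.37
  l2 <- approx_loglik(surf, ages = d$tt$ages * c0, rates = rates / c0,
                      rooted_topology = d$tt$phy)
  expect_lt(abs(l1 - l2), 1e-10)
})

test_that("ESS matches i.i.d. and AR(1) references and flags degeneracy", {
  set.seed(75)
  x <- rnorm(1e5)
  expect_lt(abs(ess(x) - 1e5) / 1e5, 0.10)
  phi <- 0.5
  y <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
  target <- 1e5 * (1 - phi) / (1 + phi)
  expect_lt(abs(ess(y) - target) / target, 0.15)
  z <- rep(36.4, 500)
  e <- ess(z)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "degenerate"))
  expect_error(ess(1:5), "too short")
})

fake_trace <- function(values, name = "t_9") {
  df <- data.frame(state = seq_along(values))
  df[[name]] <- values
  structure(list(chains = list(df),
                 settings = mcmc_settings(n_iter = length(values),
                                          sample_every = 1,
                                          burnin_fraction = 0,
                                          n_chains = 1),
                 model = "STR", npart = 1, beta = 1),
            class = "mcmc_trace")
}

test_that("posterior summaries report means, CI widths and ESS flags", {
  tr <- fake_trace(rep(36.4, 500))
  sm <- summarize_posterior(tr)
  expect_equal(sm$mean[1], 36.4)
  expect_equal(sm$ci_width[1], 0)
  set.seed(76)
  tr2 <- fake_trace(rnorm(1e5))
  sm2 <- summarize_posterior(tr2)
  expect_lt(abs(sm2$ci_width[1] - 3.92) / 3.92, 0.02)
  expect_false(sm2$low_ess[1])
  # strongly autocorrelated chain trips the ESS < 100 flag
  y <- as.numeric(stats::arima.sim(list(ar = 0.999), 2000))
  sm3 <- summarize_posterior(fake_trace(y))
  expect_true(sm3$low_ess[1])
  expect_error(summarize_posterior(fake_trace(rnorm(50))), "insufficient")
})

test_that("two chains agree on posterior means (approximate likelihood)", {
  d <- fix_dataset(n_tips = 8, n_codons = 400, seed = 77)
  surf <- suppressWarnings(build_approx_surface(d$aln, d$tt$phy, fix_sub()))
  cals <- fix_cals(d$tt, offsets = c(0.1, 0.1))
  st <- mcmc_settings(n_iter = 120000, sample_every = 10, n_chains = 2,
                      seed = 11)
  tr <- run_mcmc("STR", list(surf), d$tt$phy, cals, settings = st)
  root_age <- d$tt$root_age * 100
  agecols <- grep("^t_", names(tr$chains[[1]]), value = TRUE)
  for (cl in agecols) {
    m1 <- mean(clockdate:::post_burnin(
      structure(list(chains = tr$chains[1], settings = st),
                class = "mcmc_trace"))[[cl]])
    m2 <- mean(clockdate:::post_burnin(
      structure(list(chains = tr$chains[2], settings = st),
                class = "mcmc_trace"))[[cl]])
    expect_lt(abs(m1 - m2), 0.005 * root_age)
  }
})

test_that("a root calibration is mandatory and infeasible starts error", {
  tt <- simulate_timetree(8, 0.4, seed = 78)
  phy <- tt$phy
  # a tip pair whose MRCA is below the root
  pp <- ape::prop.part(phy)
  sub_clades <- which(lengths(pp) >= 2 & lengths(pp) < ape::Ntip(phy))
  tips <- phy$tip.label[pp[[sub_clades[1]]][1:2]]
  st <- mcmc_settings(n_iter = 100, sample_every = 10, n_chains = 1)
  noroot <- calibration_set(data.frame(
    tip_a = tips[1], tip_b = tips[2], t_min = 1, min_type = "hard",
    t_max = 2, max_type = "hard"))
  expect_error(run_mcmc("STR", NULL, phy, noroot, settings = st),
               "root calibration")
  # conflicting hard windows: a descendant forced to be older than the root
  both <- make_calibrations(tt_in_ma(tt), anchors = list(tips),
                            rel_offsets = c(0.1, 0.1), tails = c(0, 0))
  both$t_min[1] <- 1; both$t_max[1] <- 2        # root in [1, 2] Ma
  both$t_min[2] <- 30; both$t_max[2] <- 40      # child in [30, 40] Ma
  expect_error(run_mcmc("STR", NULL, phy, both, settings = st),
               "could not initialize")
})
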