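# Exact pruning likelihood, branch-length MLEs, finite-difference Hessian,
# quadratic approximate likelihood.

test_that("two-taxon single-site likelihood matches the matrix exponential", {
  pi <- c(0.27, 0.23, 0.26, 0.24)
  sub <- substitution_params(kappa = 3, base_freqs = pi, gamma_shape = 100,
                             n_categories = 1)
  phy <- ape::read.tree(text = "(a:0.1,b:0.15);")
  aln <- aln_from_strings(c(a = "A", b = "G"))
  ll <- prune_loglik(aln, phy, sub)
  Q <- hky_Q(3, pi)
  P <- expm_eigen(Q, 0.25)  # pulley principle: only the total path matters
  expect_equal(ll, log(pi[1] * P[1, 3]), tolerance = 1e-10)
})

test_that("zero-length trees give the stationary density per constant site", {
  pi <- c(0.4, 0.1, 0.1, 0.4)
  sub <- substitution_params(base_freqs = pi)
  phy <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- aln_from_strings(c(a = "ACG", b = "ACG", c = "ACG"))
  ll <- prune_loglik(aln, phy, sub)
  expect_equal(ll, log(pi[1]) + log(pi[2]) + log(pi[3]), tolerance = 1e-12)
})

test_that("the pruning likelihood matches an independent implementation", {
  d <- fix_dataset(n_tips = 6, model = "IR", sigma2 = 0.3, n_codons = 150,
                   seed = 50)
  phy <- d$tt$phy
  phy$edge.length <- (d$tt$ages[phy$edge[, 1]] -
                        d$tt$ages[phy$edge[, 2]]) * d$rates
  sub <- fix_sub()
  ll <- prune_loglik(d$aln, phy, sub)
  dat <- phangorn::phyDat(d$aln$matrix, type = "DNA")
  # HKY via GTR rates (AC, AG, AT, CG, CT, GT) with transitions = kappa
  fit <- phangorn::pml(phy, dat, bf = sub$base_freqs,
                       Q = c(1, sub$kappa, 1, 1, sub$kappa, 1),
                       k = sub$n_categories, shape = sub$gamma_shape)
  expect_equal(ll, fit$logLik, tolerance = 1e-8)
})

test_that("the likelihood is invariant to rerooting", {
  d <- fix_dataset(n_tips = 6, n_codons = 100, seed = 51)
  phy <- d$tt$phy
  phy$edge.length <- (d$tt$ages[phy$edge[, 1]] -
                        d$tt$ages[phy$edge[, 2]]) * d$rates
  ll0 <- prune_loglik(d$aln, phy, fix_sub())
  u <- ape::unroot(phy)
  expect_lt(abs(prune_loglik(d$aln, u, fix_sub()) - ll0), 1e-8)
  for (og in c("t2", "t4", "t5")) {
    re <- ape::root(u, outgroup = og, resolve.root = TRUE)
    expect_lt(abs(prune_loglik(d$aln, re, fix_sub()) - ll0), 1e-8)
  }
})

test_that("pattern compression reproduces the naive per-site product", {
  d <- fix_dataset(n_tips = 5, n_codons = 30, seed = 52)
  phy <- d$tt$phy
  phy$edge.length <- (d$tt$ages[phy$edge[, 1]] -
                        d$tt$ages[phy$edge[, 2]]) * d$rates
  ll <- prune_loglik(d$aln, phy, fix_sub())
  persite <- sum(vapply(seq_len(ncol(d$aln$matrix)), function(s) {
    m1 <- d$aln$matrix[, s, drop = FALSE]
    prune_loglik(m1, phy, fix_sub())
  }, 0))
  expect_equal(ll, persite, tolerance = 1e-9)
})

test_that("alignment taxa must be present in the tree", {
  d <- fix_dataset(n_tips = 4, n_codons = 5, seed = 53)
  m <- d$aln$matrix
  rownames(m)[1] <- "not_in_tree"
  expect_error(prune_loglik(m, d$tt$phy, fix_sub()), "absent from tree")
})

test_that("branch-length MLEs recover the generating lengths", {
  d <- fix_dataset(n_tips = 8, model = "IR", sigma2 = 0.2,
                   n_codons = 667, seed = 54)
  phy <- d$tt$phy
  phy$edge.length <- (d$tt$ages[phy$edge[, 1]] -
                        d$tt$ages[phy$edge[, 2]]) * d$rates
  fit <- mle_branch_lengths(d$aln, phy, fix_sub())
  gh <- hessian_at_mle(d$aln, phy, fix_sub(), fit$b_hat)
  se <- sqrt(pmax(diag(solve(-gh$H)), 0))
  true_u <- ape::unroot(phy)
  # map true branch lengths onto the fitted unrooted edge order via splits
  keys_fit <- clockdate:::edge_split_keys(fit$tree)
  keys_true <- clockdate:::edge_split_keys(true_u)
  b_true <- true_u$edge.length[match(keys_fit, keys_true)]
  expect_true(all(abs(fit$b_hat - b_true) < 3.5 * se + 1e-3))
})

test_that("identical sequences give zero-length connecting branches", {
  m <- rbind(a = strsplit(strrep("ACGTT", 30), "")[[1]],
             b = strsplit(strrep("ACGTT", 30), "")[[1]],
             c = strsplit(strrep("TTGCA", 30), "")[[1]])
  phy <- ape::read.tree(text = "((a,b),c);")
  fit <- suppressWarnings(mle_branch_lengths(m, phy, fix_sub()))
  ab_edges <- which(fit$tree$edge[, 2] %in% 1:2)
  expect_true(all(fit$b_hat[ab_edges] < 1e-6))
})

test_that("the MLE dominates random perturbations", {
  d <- fix_dataset(n_tips = 6, n_codons = 150, seed = 55)
  fit <- mle_branch_lengths(d$aln, d$tt$phy, fix_sub())
  lf <- clockdate:::make_loglik_fn(d$aln$matrix, fit$tree, fix_sub())
  set.seed(56)
  for (i in 1:100) {
    pert <- pmax(fit$b_hat * exp(rnorm(length(fit$b_hat), 0, 0.1)), 1e-8)
    expect_gte(fit$logl_hat, lf$fn(pert) - 1e-9)
  }
})

test_that("the 1-branch Hessian matches the analytic second derivative", {
  pi <- c(0.27, 0.23, 0.26, 0.24)
  sub <- substitution_params(kappa = 3, base_freqs = pi, gamma_shape = 100,
                             n_categories = 1)
  set.seed(57)
  d0 <- 0.15
  P <- hky_pmat(d0, 3, pi)
  states <- c("A", "C", "G", "T")
  a <- sample(states, 2000, TRUE, prob = pi)
  b <- vapply(a, function(x) sample(states, 1, prob = P[match(x, states), ]), "")
  phy <- ape::read.tree(text = "(a:0.1,b:0.1);")
  fit <- mle_branch_lengths(rbind(a = a, b = b), phy, sub)
  gh <- hessian_at_mle(rbind(a = a, b = b), phy, sub, fit$b_hat)
  # analytic oracle via eigen-decomposition derivatives of P(t)
  Q <- hky_Q(3, pi)
  e <- eigen(Q)
  V <- e$vectors; Vi <- solve(V)
  counts <- table(factor(a, levels = states), factor(b, levels = states))
  d2 <- function(t) {
    Pt <- Re(V %*% diag(exp(e$values * t)) %*% Vi)
    P1 <- Re(V %*% diag(e$values * exp(e$values * t)) %*% Vi)
    P2 <- Re(V %*% diag(e$values^2 * exp(e$values * t)) %*% Vi)
    sum(counts * (P2 / Pt - (P1 / Pt)^2))
  }
  expect_equal(gh$H[1, 1], d2(fit$b_hat[1]), tolerance = 1e-3)
})

test_that("finite differences recover a quadratic function exactly", {
  set.seed(58)
  n <- 5
  A <- crossprod(matrix(rnorm(n * n), n))
  g0 <- rnorm(n)
  fn <- function(b) -0.5 * sum(b * (A %*% b)) + sum(g0 * b)
  b0 <- runif(n, 0.5, 1)
  gh <- clockdate:::fd_gradient_hessian(fn, b0)
  expect_equal(gh$H, -A, tolerance = 1e-5)
  expect_equal(gh$g, g0 - as.numeric(A %*% b0), tolerance = 1e-5)
  expect_lt(max(abs(gh$H - t(gh$H))), 1e-8)
})

test_that("the quadratic surface is exact at its expansion point", {
  d <- fix_dataset(n_tips = 8, n_codons = 200, seed = 59)
  surf <- suppressWarnings(build_approx_surface(d$aln, d$tt$phy, fix_sub()))
  expect_identical(approx_loglik(surf, b = surf$b_hat), surf$logl_hat)
  expect_lt(max(abs(surf$H - t(surf$H))), 1e-8)
  expect_lt(max(abs(surf$g[surf$b_hat > 1e-8])) / surf$n_sites, 1e-3)
  expect_error(approx_loglik(surf, b = surf$b_hat[-1]), "dimension")
})

test_that("approximation error grows with the perturbation scale", {
  d <- fix_dataset(n_tips = 8, n_codons = 200, seed = 60)
  surf <- suppressWarnings(build_approx_surface(d$aln, d$tt$phy, fix_sub()))
  lf <- clockdate:::make_loglik_fn(d$aln$matrix, surf$utree, fix_sub())
  set.seed(61)
  dirn <- rnorm(length(surf$b_hat))
  dirn <- dirn / sqrt(sum(dirn^2))
  err <- vapply(c(0.01, 0.02, 0.04), function(eps) {
    b <- pmax(surf$b_hat * (1 + eps * dirn), 1e-8)
    abs(approx_loglik(surf, b = b) - lf$fn(b))
  }, 0)
  expect_true(all(diff(err) > -1e-10))
})

test_that("surfaces round-trip through the text bundle", {
  d <- fix_dataset(n_tips = 6, n_codons = 100, seed = 62)
  surf <- suppressWarnings(build_approx_surface(d$aln, d$tt$phy, fix_sub()))
  f <- tempfile(fileext = ".tsv")
  write_surface(surf, f)
  back <- read_surface(f, d$tt$phy)
  expect_equal(back$b_hat, surf$b_hat, tolerance = 1e-9)
  expect_equal(back$H, surf$H, tolerance = 1e-6)
  expect_equal(back$logl_hat, surf$logl_hat, tolerance = 1e-8)
  expect_equal(back$emap, surf$emap)
  # evaluation through the restored surface agrees
  b <- surf$b_hat * 1.02
  expect_equal(approx_loglik(back, b = b), approx_loglik(surf, b = b),
               tolerance = 1e-6)
})
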