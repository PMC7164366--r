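# Synthetic-data generator: timetrees, branch rates, alignments,
# calibrations, corruption.

test_that("two-tip trees place the single internal node exactly at the root age", {
  tt <- simulate_timetree(2, 36.4, seed = 1)
  expect_equal(tt$root_age, 36.4)
  expect_equal(sum(tt$ages > 0), 1)
})

test_that("simulation is deterministic and rejects invalid arguments", {
  a <- simulate_timetree(12, 1, seed = 42)
  b <- simulate_timetree(12, 1, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_timetree(1, 1), "at least 2")
  expect_error(simulate_timetree(5, -1), "positive")
  expect_error(simulate_timetree(5, 1, bd = c(-1, 1, 0.1)), "nonnegative")
  expect_error(simulate_timetree(5, 1, bd = c(1, 1, 0)), "rho")
})

test_that("every simulated tree satisfies parent age > child age", {
  for (seed in 1:10) {
    tt <- simulate_timetree(25, 2, seed = seed)
    expect_true(all(tt$ages[tt$phy$edge[, 1]] > tt$ages[tt$phy$edge[, 2]]))
    expect_silent(validate_timetree(tt))
  }
})

test_that("node-age ECDF matches the birth-death kernel CDF", {
  # 500 replicates of 200-tip trees under lambda = mu = 1, rho = 0.1
  ages <- unlist(lapply(1:500, function(s) {
    tt <- simulate_timetree(200, 1, bd = c(1, 1, 0.1), seed = s)
    a <- tt$ages[tt$ages > 0]
    a[a < 1]  # non-root internal ages
  }))
  grid <- seq(0.005, 0.995, by = 0.005)
  emp <- stats::ecdf(ages)(grid)
  theo <- clockdate:::bd_kernel_cdf(grid, 1, 1, 1, 0.1)
  expect_lt(max(abs(emp - theo)), 0.05)
})

test_that("strict-clock rates are exactly mu and degenerate AR collapses to mu", {
  tt <- simulate_timetree(10, 1, seed = 3)
  r <- simulate_branch_rates(tt, clock_model_spec("STR", 0.05), seed = 1)
  expect_true(all(r == 0.05))
  r0 <- simulate_branch_rates(tt, clock_model_spec("AR", 0.1, 0), seed = 1)
  expect_equal(unname(r0), rep(0.1, length(r0)), tolerance = 1e-12)
})

test_that("IR log rates have the mean-corrected lognormal location", {
  # many draws via a large tree: E[log r] = log(mu) - sigma2/2
  tt <- simulate_timetree(2000, 1, seed = 5)
  draws <- unlist(lapply(1:10, function(s)
    simulate_branch_rates(tt, clock_model_spec("IR", 0.1, 0.25), seed = s)))
  m <- mean(log(draws))
  se <- stats::sd(log(draws)) / sqrt(length(draws))
  expect_lt(abs(m - (log(0.1) - 0.125)), 3 * se)
})

test_that("AR child rates are a martingale given the parent rate", {
  # caterpillar tree; collect (parent branch, child branch) rate pairs
  txt <- "((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4);"
  tt <- timetree(ape::read.tree(text = txt))
  pairs <- do.call(rbind, lapply(1:3000, function(s) {
    r <- simulate_branch_rates(tt, clock_model_spec("AR", 0.1, 0.2), seed = s)
    pe <- match(tt$phy$edge[, 1], tt$phy$edge[, 2])
    cbind(parent = r[pe[!is.na(pe)]], child = r[!is.na(pe)])
  }))
  ratio <- pairs[, "child"] / pairs[, "parent"]
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("zero rates copy the root sequence to every tip", {
  tt <- simulate_timetree(6, 1, seed = 2)
  r <- setNames(rep(0, nrow(tt$phy$edge)), tt$phy$edge[, 2])
  aln <- simulate_alignment(tt, r, fix_sub(), 50, seed = 3)
  expect_true(all(apply(aln$matrix, 2, function(col) length(unique(col)) == 1)))
})

test_that("extreme kappa suppresses transversions", {
  tt <- simulate_timetree(2, 0.5, seed = 7)
  r <- setNames(rep(0.3, 2), tt$phy$edge[, 2])
  sub <- substitution_params(kappa = 1000, base_freqs = rep(0.25, 4),
                             gamma_shape = 100)
  aln <- simulate_alignment(tt, r, sub, 20000, cp_multipliers = c(1, 1, 1),
                            seed = 8)
  a <- aln$matrix[1, ]; b <- aln$matrix[2, ]
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  transversion <- purine(a) != purine(b)
  expect_lt(sum(diff & transversion) / sum(diff), 0.05)
})

test_that("root sequence composition follows the stationary frequencies", {
  tt <- simulate_timetree(2, 1, seed = 9)
  r <- setNames(rep(0, 2), tt$phy$edge[, 2])  # no change: tips = root
  pi <- c(0.4, 0.1, 0.1, 0.4)
  sub <- substitution_params(base_freqs = pi)
  aln <- simulate_alignment(tt, r, sub, 34000, seed = 10)
  emp <- tabulate(match(aln$matrix[1, ], c("A", "C", "G", "T")), 4) /
    ncol(aln$matrix)
  expect_true(all(abs(emp - pi) < 0.01))
})

test_that("alignment codon-position labels cycle with the frame offset", {
  m <- matrix("A", 2, 8, dimnames = list(c("a", "b"), NULL))
  aln <- gene_alignment("g", m, frame_offset = 2)
  expect_equal(aln$codon_pos[3:5], c(1L, 2L, 3L))
})

test_that("calibrations bracket true ages; degenerate widths are rejected", {
  tt <- tt_in_ma(simulate_timetree(10, 0.5, seed = 4))
  cals <- make_calibrations(tt, anchors = list(c("t1", "t2")),
                            rel_offsets = c(0.1, 0.2), tails = c(0, 0.025))
  expect_true(all(cals$t_min <= cals$true_age & cals$true_age <= cals$t_max))
  expect_error(make_calibrations(tt, rel_offsets = c(0, 0)), "rejected")
  # narrow root window in relative time: offsets 0.001 on age 1
  tt1 <- simulate_timetree(4, 1, seed = 5)
  c2 <- make_calibrations(tt1, rel_offsets = c(0.001, 0.001),
                          tails = c(0, 0))
  expect_equal(c2$t_min[1], 0.999)
  expect_equal(c2$t_max[1], 1.001)
})

test_that("corruption bookkeeping is exact and zero rules are the identity", {
  tt <- simulate_timetree(6, 0.4, seed = 6)
  gs <- simulate_gene_set(tt, 5, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 30, seed = 11)
  out0 <- corrupt_fixture(gs$alignments, list(), seed = 1)
  expect_identical(out0$alignments, gs$alignments)
  expect_equal(nrow(out0$log), 0)
  out <- corrupt_fixture(gs$alignments,
                         list(stop_genes = "g002", stops_per_gene = 1,
                              frameshift_genes = "g004"), seed = 2)
  expect_equal(out$log$gene_id, c("g002", "g004"))
  st <- out$log[out$log$type == "premature_stop", ]
  cols <- (st$codon - 1) * 3 + 1:3
  codon <- paste(out$alignments[["g002"]]$matrix[st$taxon, cols],
                 collapse = "")
  expect_true(codon %in% c("TAA", "TAG", "TGA"))
})

test_that("taxon dropout hits approximately the requested fraction of genes", {
  tt <- simulate_timetree(5, 0.3, seed = 8)
  gs <- simulate_gene_set(tt, 200, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 5, seed = 12)
  out <- corrupt_fixture(gs$alignments, list(dropout = c(t2 = 0.6)),
                         seed = 3)
  hits <- sum(out$log$type == "dropout")
  # binomial(200, 0.6): 3.5 sigma band
  expect_true(abs(hits - 120) < 3.5 * sqrt(200 * 0.6 * 0.4))
})

test_that("per-gene streams are reproducible under reordering", {
  tt <- simulate_timetree(5, 0.3, seed = 8)
  g1 <- simulate_gene_set(tt, 6, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 10, gene_rate_range = c(1, 1), seed = 13)
  g2 <- simulate_gene_set(tt, 3, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 10, gene_rate_range = c(1, 1), seed = 13)
  expect_identical(g1$alignments[["g002"]]$matrix,
                   g2$alignments[["g002"]]$matrix)
})
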