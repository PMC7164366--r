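# HKY distances, rate binning, codon-position splitting, clocklikeness
# ranking.

test_that("identical sequences have distance zero; JC closed form recovered", {
  s <- strsplit(strrep("ACGT", 75), "")[[1]]
  expect_equal(as.numeric(hky_distance(s, s)), 0)
  # kappa fixed to 1 with equal frequencies reduces HKY to JC69
  set.seed(31)
  n <- 3000
  a <- sample(c("A", "C", "G", "T"), n, TRUE)
  b <- a
  flip <- sample(n, n / 10)
  b[flip] <- vapply(a[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  d <- hky_distance(a, b, freqs = rep(0.25, 4), fix_kappa = 1)
  expect_equal(as.numeric(d), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-4)
})

test_that("the ML distance recovers the generating distance and kappa", {
  set.seed(32)
  n <- 1e5
  pi <- c(0.27, 0.23, 0.26, 0.24)
  P <- hky_pmat(0.2, 4, pi)
  a <- sample(c("A", "C", "G", "T"), n, TRUE, prob = pi)
  b <- vapply(a, function(x)
    sample(c("A", "C", "G", "T"), 1,
           prob = P[match(x, c("A", "C", "G", "T")), ]), "")
  d <- hky_distance(a, b)
  # Monte-Carlo scale: sd of the difference-proportion mapped through JC
  p <- mean(a != b)
  se <- sqrt(p * (1 - p) / n) / (1 - 4 * p / 3)
  expect_lt(abs(as.numeric(d) - 0.2), 3.5 * se)
  expect_gt(attr(d, "kappa"), 2.5)
  expect_lt(attr(d, "kappa"), 6)
})

test_that("no shared ungapped sites is a data error", {
  expect_error(hky_distance(c("A", "-"), c("-", "A")), "no shared")
})

test_that("gene rate tables use the primary pair with ordered fallbacks", {
  tt <- simulate_timetree(6, 0.4, seed = 33)
  gs <- simulate_gene_set(tt, 3, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 60, seed = 34)
  alns <- gs$alignments
  # knock t2 out of g002 entirely, and everything except t1 out of g003
  alns[["g002"]]$matrix["t2", ] <- "N"
  alns[["g003"]]$matrix[setdiff(rownames(alns[["g003"]]$matrix), "t1"), ] <- "N"
  tab <- gene_rate_table(alns, primary_pair = c("t1", "t2"),
                         fallback_taxa = c("t3", "t4"))
  expect_equal(tab$taxon_b[tab$gene_id == "g001"], "t2")
  expect_equal(tab$taxon_b[tab$gene_id == "g002"], "t3")
  expect_false("g003" %in% tab$gene_id)
  expect_equal(attr(tab, "unratable"), "g003")
})

test_that("bin sizes match the integer-division arithmetic", {
  tab <- structure(data.frame(gene_id = sprintf("g%04d", 1:3096),
                              distance = sort(runif(3096)),
                              taxon_a = "x", taxon_b = "y",
                              saturated = FALSE),
                   class = c("gene_rate_table", "data.frame"))
  s3 <- bin_genes(tab, 3)
  expect_equal(lengths(lapply(s3$partitions, `[[`, "genes")),
               rep(1032L, 3))
  s10 <- bin_genes(tab, 10)
  sizes <- lengths(lapply(s10$partitions, `[[`, "genes"))
  expect_equal(sizes, c(rep(310L, 6), rep(309L, 4)))
  expect_equal(sum(sizes), 3096L)
  s1 <- bin_genes(tab, 1)
  expect_setequal(s1$partitions[[1]]$genes, tab$gene_id)
  expect_error(bin_genes(tab, 4000), "between 1 and")
})

test_that("binning is permutation-invariant and rate-ordered", {
  set.seed(35)
  tab <- structure(data.frame(gene_id = sprintf("g%03d", 1:50),
                              distance = runif(50), taxon_a = "x",
                              taxon_b = "y", saturated = FALSE),
                   class = c("gene_rate_table", "data.frame"))
  perm <- tab[sample(50), ]
  s1 <- bin_genes(tab, 7)
  s2 <- bin_genes(perm, 7)
  expect_identical(lapply(s1$partitions, `[[`, "genes"),
                   lapply(s2$partitions, `[[`, "genes"))
  expect_silent(validate_partition_scheme(s1))
  d <- setNames(tab$distance, tab$gene_id)
  means <- vapply(s1$partitions, function(p) mean(d[p$genes]), 0)
  expect_true(all(diff(means) >= 0))
})

test_that("codon-position splitting doubles partitions and halves by class", {
  tt <- simulate_timetree(5, 0.3, seed = 36)
  gs <- simulate_gene_set(tt, 6, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 40, seed = 37)
  tab <- gene_rate_table(gs$alignments, c("t1", "t2"))
  s3 <- bin_genes(tab, 3)
  s6 <- split_codon_positions(s3)
  expect_equal(length(s6$partitions), 6)
  expect_equal(s6$label, "6p")
  s10 <- bin_genes(tab, 5)
  expect_equal(length(split_codon_positions(s10)$partitions), 10)
  expect_error(split_codon_positions(s6), "already split")
  # site counts: the 1st+2nd class has twice the sites of the 3rd class
  blocks <- partition_alignments(s6, gs$alignments)
  cls <- vapply(s6$partitions, `[[`, "", "cp_class")
  n12 <- vapply(blocks[cls == "12"], ncol, 0)
  n3 <- vapply(blocks[cls == "3"], ncol, 0)
  expect_equal(n12, 2 * n3)
  # gene membership unchanged
  expect_identical(lapply(s6$partitions[c(1, 3, 5)], `[[`, "genes"),
                   lapply(s3$partitions, `[[`, "genes"))
})

test_that("clocklike ranking prefers ultrametric trees and exact agreement", {
  sp <- simulate_timetree(8, 0.4, seed = 38)$phy
  clock <- sp
  clock$edge.length <- sp$edge.length * 0.1  # ultrametric gene tree
  wonky <- sp
  set.seed(39)
  wonky$edge.length <- sp$edge.length * 0.1 * exp(rnorm(nrow(sp$edge), 0, 1))
  ranked <- rank_clocklike(list(gA = clock, gB = wonky), sp, 2)
  expect_equal(ranked$gene_id[1], "gA")
  expect_equal(ranked$rtt_variance[1], 0)
  expect_equal(ranked$agreement, c(1, 1))
  tiny <- ape::rtree(3)
  r2 <- rank_clocklike(list(gA = clock, tiny = tiny), sp, 2)
  expect_true("tiny" %in% attr(r2, "excluded")$gene_id)
})

test_that("low-variance genes dominate the top ranks across replicates", {
  wins <- 0
  for (rep in 1:10) {
    tt <- simulate_timetree(10, 0.4, seed = 330 + rep)
    trees <- list()
    for (i in 1:20) {
      s2 <- if (i <= 10) 0 else 0.5
      r <- simulate_branch_rates(tt, clock_model_spec(
        if (s2 == 0) "STR" else "IR", 0.1, s2), seed = 1000 * rep + i)
      g <- tt$phy
      g$edge.length <- (tt$ages[g$edge[, 1]] - tt$ages[g$edge[, 2]]) * r
      trees[[sprintf("g%02d", i)]] <- g
    }
    top <- rank_clocklike(trees, tt$phy, 10)$gene_id
    if (all(top %in% sprintf("g%02d", 1:10))) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
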