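# Pseudogene screening, missingness filtering, representative selection,
# exon concatenation.

test_that("internal stops are flagged and the terminal stop is exempt", {
  a <- aln_from_strings(c(x = "ATGTAAGGG"))
  f <- screen_premature_stops(a)
  expect_equal(nrow(f), 1)
  expect_equal(f$codon, 2)
  b <- aln_from_strings(c(x = "ATGGGGTAA"))
  expect_equal(nrow(screen_premature_stops(b)), 0)
  # stop at the end of a shorter (gap-padded) CDS is also terminal
  cc <- aln_from_strings(c(x = "ATGTAA---"))
  expect_equal(nrow(screen_premature_stops(cc)), 0)
  # codons containing N or '-' are skipped
  d <- aln_from_strings(c(x = "ATGTA-GGGAAA"))
  expect_equal(nrow(screen_premature_stops(d)), 0)
  expect_error(screen_premature_stops(aln_from_strings(c(x = "AT"))),
               "shorter")
})

test_that("injected stops are recovered exactly on stop-free genes", {
  tt <- simulate_timetree(6, 0.4, seed = 21)
  gs <- simulate_gene_set(tt, 4, clock_model_spec("STR", 0.1), fix_sub(),
                          n_codons = 300, seed = 22)
  out <- corrupt_fixture(gs$alignments,
                         list(stop_genes = "g002", stops_per_gene = 3),
                         seed = 23)
  truth <- out$log[out$log$type == "premature_stop", ]
  flags <- screen_premature_stops(out$alignments[["g002"]])
  expect_setequal(paste(flags$taxon, flags$codon),
                  paste(truth$taxon, truth$codon))
  # no false positives on untouched genes (stop-free by construction)
  for (g in c("g001", "g003", "g004"))
    expect_equal(nrow(screen_premature_stops(out$alignments[[g]])), 0)
})

test_that("frameshift detection flags exactly the non-multiple-of-3 gap runs", {
  a <- aln_from_strings(c(x = "AAA---AAAAAA"))
  expect_equal(nrow(detect_frameshift_indels(a)), 0)
  b <- aln_from_strings(c(x = paste0(strrep("A", 9), "----",
                                     strrep("G", 11))))
  f <- detect_frameshift_indels(b)
  expect_equal(f$site, 10)
  expect_equal(f$length, 4)
  # random gap runs, brute-force recount
  set.seed(24)
  for (rep in 1:5) {
    lens <- sample(1:7, 20, replace = TRUE)
    seqs <- paste(unlist(lapply(lens, function(l)
      c(strrep("A", 5), strrep("-", l)))), collapse = "")
    aln <- aln_from_strings(c(x = seqs))
    f <- detect_frameshift_indels(aln)
    expect_equal(nrow(f), sum(lens %% 3 != 0))
    expect_true(all(f$length %% 3 != 0))
  }
})

test_that("gene-level QC policy drops whole genes; sequence policy drops rows", {
  a <- aln_from_strings(c(x = "ATGTAAGGG", y = "ATGCACGGG"))
  rg <- qc_gene(a, policy = "gene")
  expect_equal(rg$decision, "drop_gene")
  rs <- qc_gene(a, policy = "sequence")
  expect_equal(rs$decision, "drop_sequence")
  expect_equal(rs$drop_taxa, "x")
  clean <- aln_from_strings(c(x = "ATGCACGGG"))
  expect_equal(qc_gene(clean)$decision, "keep")
})

test_that("a 3191-gene fixture with 95 corrupted genes retains 3096", {
  base <- matrix(rep(c("A", "T", "G", "C", "A", "C", "G", "G", "G"),
                     each = 2), 2, 9, byrow = FALSE)
  base <- matrix(c("ATGCACGGGCAT", "ATGCATGGGCAT"), 2, 1)
  mk <- function(id) aln_from_strings(c(a = "ATGCACGGGCAT",
                                        b = "ATGCATGGGCAT"), gene_id = id)
  genes <- lapply(sprintf("g%04d", 1:3191), mk)
  names(genes) <- sprintf("g%04d", 1:3191)
  out <- corrupt_fixture(genes, list(stop_genes = 60,
                                     frameshift_genes =
                                       sprintf("g%04d", 61:95)), seed = 25)
  qc <- qc_gene_set(out$alignments)
  expect_equal(length(qc$dropped), 95)
  expect_equal(length(qc$kept), 3096)
})

test_that("missingness filter keeps taxa at the boundary and drops above it", {
  mk_exon <- function(present, id) {
    m <- matrix("N", 3, 6, dimnames = list(c("a", "b", "c"), NULL))
    m[present, ] <- "A"
    gene_alignment(id, m)
  }
  # a present in 10/10, b in 4/10 (missing 0.6), c in 5/10 (missing 0.5)
  exons <- lapply(1:10, function(i)
    mk_exon(c("a", if (i <= 4) "b", if (i <= 5) "c"), paste0("e", i)))
  names(exons) <- paste0("e", 1:10)
  pm <- presence_matrix(exons)
  expect_equal(unname(attr(pm, "missing_fraction")["b"]), 0.6)
  kept <- filter_taxa_by_missingness(pm, 0.5)
  expect_setequal(kept, c("a", "c"))
  # idempotence: filtering the filtered set changes nothing
  pm2 <- pm[kept, , drop = FALSE]
  attr(pm2, "missing_fraction") <- attr(pm, "missing_fraction")[kept]
  expect_setequal(filter_taxa_by_missingness(pm2, 0.5), kept)
})

test_that("random presence matrices match a brute-force row scan", {
  set.seed(26)
  m <- matrix(runif(50 * 200) > 0.4, 50, 200,
              dimnames = list(paste0("s", 1:50), paste0("e", 1:200)))
  pm <- structure(m, missing_fraction = 1 - rowMeans(m),
                  class = c("presence_matrix", "matrix"))
  kept <- filter_taxa_by_missingness(pm, 0.5)
  brute <- rownames(m)[sapply(seq_len(nrow(m)), function(i)
    mean(!m[i, ]) <= 0.5)]
  expect_setequal(kept, brute)
})

test_that("representative selection keeps the most complete individual", {
  ind <- list(sp1 = list(list("a", 0.9), list("b", 0.7)))
  expect_equal(select_representatives(ind), "a")
  tie <- list(sp1 = list(list("b", 0.8), list("a", 0.8)))
  expect_equal(select_representatives(tie), "a")  # lexicographic tie-break
  expect_setequal(select_representatives(ind, keep_list = "b"), c("a", "b"))
  expect_error(select_representatives(ind, keep_list = "zz"), "not found")
})

test_that("exon concatenation pads, preserves frame, and round-trips", {
  e1 <- aln_from_strings(c(a = "ATGCAC", b = "ATGCAT"), gene_id = "e1")
  e2 <- aln_from_strings(c(a = "GGGCATAAA"), gene_id = "e2")
  gm <- data.frame(exon_id = c("e1", "e2"), gene_id = "g", order = 1:2,
                   frame = c(0, 0))
  genes <- concatenate_exons(list(e1 = e1, e2 = e2), gm)
  g <- genes[["g"]]
  expect_equal(ncol(g$matrix), 15)
  expect_equal(paste(g$matrix["b", 7:15], collapse = ""), "NNNNNNNNN")
  back <- split_concatenation(g)
  expect_equal(back[["e1"]]$matrix["a", ], e1$matrix["a", ])
  expect_equal(back[["e2"]]$matrix["a", ], e2$matrix["a", ])
  # frame discontinuity: exon 2 expected at cumulative length 6 %% 3 = 0
  gm_bad <- transform(gm, frame = c(0, 1))
  expect_error(concatenate_exons(list(e1 = e1, e2 = e2), gm_bad),
               "frame discontinuity")
  # duplicate taxon rows are a data error
  e_dup <- e1
  e_dup$taxa <- c("a", "a")
  rownames(e_dup$matrix) <- c("a", "a")
  expect_error(concatenate_exons(list(e1 = e_dup, e2 = e2), gm),
               "duplicate")
})
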