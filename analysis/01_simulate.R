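#!/usr/bin/env Rscript
# Simulate the synthetic study data: a fossil-calibrated timetree for 16
# taxa, 40 coding genes spanning slow to fast rates under an autocorrelated
# clock, plus a corrupted copy carrying pseudogene artifacts and taxon
# dropout. Everything downstream works from these files.
suppressPackageStartupMessages(library(clockdate))

seed <- 20260101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tt <- simulate_timetree(16, root_age = 0.364, seed = seed)  # 36.4 Ma root
sub <- substitution_params(kappa = 4, base_freqs = c(0.27, 0.23, 0.26, 0.24),
                           gamma_shape = 0.5)
gs <- simulate_gene_set(tt, n_genes = 40,
                        spec = clock_model_spec("AR", mu = 0.1, sigma2 = 0.5),
                        sub = sub, n_codons = 150,
                        gene_rate_range = c(0.3, 3), seed = seed)

stamp <- sprintf("seed=%d ages_in_Ma rates_per_100Myr", seed)
ttma <- tt
ttma$ages <- tt$ages * 100; ttma$root_age <- tt$root_age * 100
ttma$phy$edge.length <- tt$phy$edge.length * 100
write_timetree(ttma, file.path(out, "true_tree.nwk"), stamp)
for (g in names(gs$alignments))
  write_fasta(gs$alignments[[g]], file.path(out, paste0(g, ".fasta")), stamp)
write_tsv_stamped(
  data.frame(gene_id = names(gs$gene_rates), multiplier = gs$gene_rates),
  file.path(out, "gene_rate_multipliers.tsv"), stamp)
# true branch rates per gene (child node id keys the branch)
write_tsv_stamped(
  do.call(rbind, lapply(names(gs$branch_rates), function(g)
    data.frame(gene_id = g, child_node = as.integer(names(gs$branch_rates[[g]])),
               rate = as.numeric(gs$branch_rates[[g]])))),
  file.path(out, "true_branch_rates.tsv"), stamp)

# corrupted copy: stops in 4 genes, frameshifts in 2, one flaky taxon
crp <- corrupt_fixture(gs$alignments,
                       list(stop_genes = c("g003", "g011", "g024", "g037"),
                            stops_per_gene = 2,
                            frameshift_genes = c("g008", "g030"),
                            dropout = c(t13 = 0.6)),
                       seed = seed + 1)
dir.create(file.path(out, "corrupted"), showWarnings = FALSE)
for (g in names(crp$alignments))
  write_fasta(crp$alignments[[g]],
              file.path(out, "corrupted", paste0(g, ".fasta")), stamp)
write_tsv_stamped(crp$log, file.path(out, "corruption_log.tsv"), stamp)

cat(sprintf("simulated %d genes on a %d-taxon tree (root %.1f Ma)\n",
            length(gs$alignments), 16, ttma$root_age))
cat(sprintf("injected %d artifacts (%d stops, %d frameshifts, %d dropouts)\n",
            nrow(crp$log), sum(crp$log$type == "premature_stop"),
            sum(crp$log$type == "frameshift"),
            sum(crp$log$type == "dropout")))
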