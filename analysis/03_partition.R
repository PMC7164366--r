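#!/usr/bin/env Rscript
# Rate-based gene partitioning of the QC-passed genes: pairwise HKY85
# distances for a designated odontocete/mysticete-style taxon pair (with
# fallbacks), 3/6/10-partition schemes, and the partitioned alignment.
suppressPackageStartupMessages(library(clockdate))

data_dir <- "results/data"
out <- "results/partition"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

kept <- read_tsv_stamped("results/qc/qc_decisions.tsv")
keep_ids <- kept$gene_id[kept$decision == "keep"]
genes <- lapply(keep_ids, function(g)
  gene_alignment(g, read_fasta(file.path(data_dir, "corrupted",
                                         paste0(g, ".fasta")))))
names(genes) <- keep_ids

tab <- gene_rate_table(genes, primary_pair = c("t1", "t2"),
                       fallback_taxa = paste0("t", 3:16))
write_tsv_stamped(tab, file.path(out, "gene_rate_table.tsv"))
cat(sprintf("rated %d genes; distances %.4f - %.4f subs/site\n",
            nrow(tab), min(tab$distance), max(tab$distance)))

s3 <- bin_genes(tab, 3)
s6 <- split_codon_positions(s3)
s10 <- bin_genes(tab, min(10, nrow(tab)))
for (sc in list(s3, s6, s10)) {
  df <- do.call(rbind, lapply(seq_along(sc$partitions), function(i)
    data.frame(partition_id = i, cp_class = sc$partitions[[i]]$cp_class,
               gene_id = sc$partitions[[i]]$genes)))
  write_tsv_stamped(df, file.path(out, sprintf("scheme_%s.tsv", sc$label)))
}
blocks <- partition_alignments(s3, genes)
names(blocks) <- sprintf("p%d", seq_along(blocks))
write_relaxed_phylip(blocks, file.path(out, "partitioned_3p.phy"))
cat(sprintf("schemes written: 3p (%d genes/bin), 6p, %s\n",
            length(s3$partitions[[1]]$genes), s10$label))
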