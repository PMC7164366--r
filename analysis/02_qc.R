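#!/usr/bin/env Rscript
# Quality control of the corrupted gene set: pseudogene screening
# (premature stops, frameshift indels), comparison against the injection
# log, and taxon-missingness filtering.
suppressPackageStartupMessages(library(clockdate))

data_dir <- "results/data"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files(file.path(data_dir, "corrupted"), full.names = TRUE)
genes <- lapply(files, function(f)
  gene_alignment(sub("\\.fasta$", "", basename(f)), read_fasta(f)))
names(genes) <- vapply(genes, `[[`, "", "gene_id")
truth <- read_tsv_stamped(file.path(data_dir, "corruption_log.tsv"))

qc <- qc_gene_set(genes)
write_tsv_stamped(
  data.frame(gene_id = names(genes),
             decision = vapply(qc$reports, `[[`, "", "decision")),
  file.path(out, "qc_decisions.tsv"))
if (!is.null(qc$flags) && nrow(qc$flags))
  write_tsv_stamped(qc$flags, file.path(out, "qc_flags.tsv"))

corrupted <- unique(truth$gene_id[truth$type %in%
                                    c("premature_stop", "frameshift")])
cat(sprintf("dropped %d/%d genes; injected-artifact genes recovered: %s\n",
            length(qc$dropped), length(genes),
            ifelse(setequal(qc$dropped, corrupted), "exactly", "NOT exactly")))

pm <- presence_matrix(genes)
kept <- filter_taxa_by_missingness(pm, 0.5)
dropped_taxa <- setdiff(rownames(pm), kept)
write_tsv_stamped(
  data.frame(taxon = rownames(pm),
             missing_fraction = attr(pm, "missing_fraction"),
             kept = rownames(pm) %in% kept),
  file.path(out, "taxon_missingness.tsv"))
cat(sprintf("taxa dropped for >50%% exon missingness: %s\n",
            if (length(dropped_taxa)) paste(dropped_taxa, collapse = ", ")
            else "none"))
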