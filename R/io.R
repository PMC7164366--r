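# Plain-text readers/writers for the pipeline's interchange formats.
# Alignments travel as FASTA ('-' = gap, 'N' = missing), trees as Newick
# (via ape), tables as TSV with '#'-prefixed provenance headers.

#' Write an alignment to FASTA
#'
#' @param aln A `gene_alignment` or a character matrix (rows = taxa).
#' @param file Output path.
#' @param header Optional comment line (written as `; ...`, ignored by
#'   [read_fasta()]).
#' @export
write_fasta <- function(aln, file, header = NULL) {
  m <- if (inherits(aln, "gene_alignment")) aln$matrix else aln
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste(";", header), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  invisible(file)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param file Path to an (aligned) FASTA file.
#' @return Character matrix with taxa as rownames; all rows must share one
#'   length.
#' @export
read_fasta <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^;", lines) & nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  taxa <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("unequal sequence lengths in ", file)
  m <- matrix(toupper(unlist(strsplit(seqs, ""), use.names = FALSE)),
              nrow = length(taxa), byrow = TRUE)
  rownames(m) <- taxa
  m
}

#' Write a partitioned alignment in relaxed PHYLIP format
#'
#' One block per partition; taxon names are padded, sequences follow on the
#' same line (relaxed interleaving is not used).
#'
#' @param blocks Named list of character matrices (one per partition).
#' @param file Output path.
#' @export
write_relaxed_phylip <- function(blocks, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in blocks) {
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    nm <- formatC(rownames(m), width = max(nchar(rownames(m))) + 2, flag = "-")
    for (i in seq_len(nrow(m)))
      writeLines(paste0(nm[i], paste(m[i, ], collapse = "")), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Write a TSV table with provenance header comments
#'
#' @param x Data frame.
#' @param file Output path.
#' @param header Character vector of comment lines (each written as `# ...`).
#' @export
write_tsv_stamped <- function(x, file, header = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV table written by [write_tsv_stamped()]
#' @param file Path.
#' @return Data frame (comment lines skipped).
#' @export
read_tsv_stamped <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Derive a deterministic sub-stream seed
#'
#' Hashes `(seed, label)` into `[0, 2^31)` so that named random streams
#' (per gene, per chain, per stone) are reproducible and independent of
#' generation order. Intermediate products stay below 2^53 and are exact
#' in doubles.
#'
#' @param seed Integer master seed.
#' @param label Character stream label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}
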