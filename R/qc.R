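# Dataset-assembly quality control: pseudogene screening (premature stop
# codons, frameshift indels), taxon-missingness filtering, representative
# selection, and exon -> gene concatenation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Screen an alignment for premature (internal) stop codons
#'
#' Flags every in-frame TAA/TAG/TGA that occurs strictly before the final
#' codon of a sequence's ungapped CDS. The terminal stop codon is exempt;
#' codons containing 'N' or '-' are skipped (conservative).
#'
#' @param aln A [gene_alignment()].
#' @return Data frame of flags: `gene_id`, `taxon`, `type`, `codon`, `site`.
#' @export
screen_premature_stops <- function(aln) {
  m <- aln$matrix
  if (ncol(m) - aln$frame_offset < 3) stop("alignment shorter than one codon")
  n_codon <- (ncol(m) - aln$frame_offset) %/% 3
  rows <- list()
  for (i in seq_len(nrow(m))) {
    seqi <- m[i, ]
    nongap <- which(!(seqi %in% c("-", "N")))
    if (!length(nongap)) next
    # codon index containing the last non-gap site = terminal codon
    last_codon <- ((max(nongap) - 1L - aln$frame_offset) %/% 3L) + 1L
    for (codon in seq_len(n_codon)) {
      if (codon >= last_codon) break
      cols <- aln$frame_offset + (codon - 1L) * 3L + 1:3
      cd <- seqi[cols]
      if (any(cd %in% c("-", "N"))) next
      if (paste(cd, collapse = "") %in% STOP_CODONS) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = aln$gene_id, taxon = rownames(m)[i],
          type = "premature_stop", codon = codon, site = cols[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(), taxon = character(),
                  type = character(), codon = integer(), site = integer(),
                  stringsAsFactors = FALSE)
}

#' Detect frameshift indels (gap runs of length not divisible by 3)
#'
#' Flags every maximal run of '-' whose length is not a multiple of three
#' nucleotides; in-frame (length 3k) deletions are not flagged.
#'
#' @param aln A [gene_alignment()].
#' @return Data frame of flags: `gene_id`, `taxon`, `type`, `site` (run
#'   start), `length`.
#' @export
detect_frameshift_indels <- function(aln) {
  m <- aln$matrix
  rows <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths %% 3L != 0L)
    for (j in bad) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = aln$gene_id, taxon = rownames(m)[i], type = "frameshift",
        site = starts[j], length = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(), taxon = character(),
                  type = character(), site = integer(), length = integer(),
                  stringsAsFactors = FALSE)
}

#' QC a gene: pseudogene evidence and keep/drop decision
#'
#' Premature stop codons or frameshift indels in any sequence are taken as
#' potential pseudogene evidence. Under the default gene-level policy any
#' flag drops the whole gene from dating; `policy = "sequence"` drops only
#' the flagged sequences.
#'
#' @param aln A [gene_alignment()].
#' @param policy `"gene"` (default) or `"sequence"`.
#' @return Object of class `qc_report`: list with `gene_id`, `flags` (data
#'   frame), `decision` (`keep`, `drop_gene`, or `drop_sequence`),
#'   `drop_taxa`, `rationale`.
#' @export
qc_gene <- function(aln, policy = c("gene", "sequence")) {
  policy <- match.arg(policy)
  stops <- screen_premature_stops(aln)
  fs <- detect_frameshift_indels(aln)
  flags <- merge(stops, fs, all = TRUE, sort = FALSE)
  flags <- flags[order(flags$taxon, flags$site), , drop = FALSE]
  decision <- "keep"; drop_taxa <- character(0); why <- "no pseudogene evidence"
  if (nrow(flags)) {
    if (policy == "gene") {
      decision <- "drop_gene"
      why <- sprintf("%d premature-stop and %d frameshift flag(s)",
                     nrow(stops), nrow(fs))
    } else {
      decision <- "drop_sequence"
      drop_taxa <- unique(flags$taxon)
      why <- sprintf("flags in %d sequence(s)", length(drop_taxa))
    }
  }
  structure(list(gene_id = aln$gene_id, flags = flags, decision = decision,
                 drop_taxa = drop_taxa, rationale = why),
            class = "qc_report")
}

#' Apply pseudogene QC across a gene set
#'
#' @param alignments List of [gene_alignment()] objects.
#' @param policy See [qc_gene()].
#' @return List with `reports`, `kept` (gene ids), `dropped` (gene ids),
#'   and `flags` (combined data frame).
#' @export
qc_gene_set <- function(alignments, policy = "gene") {
  reports <- lapply(alignments, qc_gene, policy = policy)
  dec <- vapply(reports, `[[`, "", "decision")
  flags <- do.call(rbind, lapply(reports, function(r)
    if (nrow(r$flags)) r$flags else NULL))
  list(reports = reports,
       kept = names(alignments)[dec != "drop_gene"],
       dropped = names(alignments)[dec == "drop_gene"],
       flags = flags %||% data.frame())
}

#' Taxon x exon presence matrix
#'
#' A taxon is present in an exon if its row exists and is not entirely
#' gap/N.
#'
#' @param exons List of alignments (exons or genes).
#' @param taxa Optional full taxon namespace (default: union over exons).
#' @return Object of class `presence_matrix`: logical matrix taxa x exons
#'   with attribute `missing_fraction`.
#' @export
presence_matrix <- function(exons, taxa = NULL) {
  if (!length(exons)) stop("empty exon list")
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(exons, function(a) a$taxa))))
  pm <- vapply(exons, function(a) {
    pres <- rep(FALSE, length(taxa))
    present_rows <- a$taxa[apply(a$matrix, 1, function(r)
      any(!(r %in% c("-", "N"))))]
    pres[match(present_rows, taxa)] <- TRUE
    pres
  }, logical(length(taxa)))
  pm <- matrix(pm, nrow = length(taxa),
               dimnames = list(taxa, names(exons)))
  structure(pm, missing_fraction = 1 - rowMeans(pm),
            class = c("presence_matrix", "matrix"))
}

#' Filter taxa by exon missingness
#'
#' Keeps exactly the taxa whose missing fraction is at most `threshold`
#' (strictly more than `threshold` missing is dropped, mirroring an
#' "exclude species missing >50% of their exons" rule at the default).
#'
#' @param pm A [presence_matrix()].
#' @param threshold Maximum tolerated missing fraction, in (0, 1].
#' @return Character vector of kept taxa.
#' @export
filter_taxa_by_missingness <- function(pm, threshold = 0.5) {
  if (!nrow(pm) || !ncol(pm)) stop("empty presence matrix")
  stopifnot(threshold > 0, threshold <= 1)
  miss <- attr(pm, "missing_fraction")
  rownames(pm)[miss <= threshold]
}

#' Select one representative individual per species
#'
#' Keeps the most complete individual of each species (ties broken by
#' lexicographically smallest id), plus every individual named in
#' `keep_list` (allowing extra representatives for selected species).
#'
#' @param individuals Named list: species -> data frame or list of
#'   `(individual_id, completeness)` pairs.
#' @param keep_list Individual ids always retained.
#' @return Character vector of selected individual ids (sorted).
#' @export
select_representatives <- function(individuals, keep_list = character()) {
  all_ids <- unlist(lapply(individuals, function(x) {
    if (is.data.frame(x)) x$individual_id else vapply(x, `[[`, "", 1)
  }), use.names = FALSE)
  unknown <- setdiff(keep_list, all_ids)
  if (length(unknown)) stop("keep_list ids not found: ",
                            paste(unknown, collapse = ", "))
  picked <- vapply(individuals, function(x) {
    if (!is.data.frame(x))
      x <- data.frame(individual_id = vapply(x, `[[`, "", 1),
                      completeness = vapply(x, function(e) as.numeric(e[[2]]),
                                            numeric(1)))
    x <- x[order(-x$completeness, x$individual_id), , drop = FALSE]
    x$individual_id[1]
  }, character(1))
  sort(unique(c(picked, keep_list)))
}

#' Concatenate exon alignments into gene alignments
#'
#' Exons are ordered by the gene map; taxa absent from an exon are padded
#' with 'N' over its span. Frame continuity is verified: the expected frame
#' offset of exon k+1 is the cumulative length mod 3.
#'
#' @param exons Named list of [gene_alignment()] objects (exon alignments);
#'   names are exon ids.
#' @param gene_map Data frame with columns `exon_id`, `gene_id`, `order`,
#'   and optionally `frame` (expected frame offset per exon).
#' @return Named list of concatenated [gene_alignment()] objects, each with
#'   attribute `boundaries` (exon spans, for round-trip splitting).
#' @export
concatenate_exons <- function(exons, gene_map) {
  stopifnot(all(c("exon_id", "gene_id", "order") %in% names(gene_map)))
  missing_ex <- setdiff(gene_map$exon_id, names(exons))
  if (length(missing_ex)) stop("exons not supplied: ",
                               paste(missing_ex, collapse = ", "))
  taxa <- sort(unique(unlist(lapply(exons, function(a) a$taxa))))
  out <- list()
  for (g in unique(gene_map$gene_id)) {
    gm <- gene_map[gene_map$gene_id == g, , drop = FALSE]
    gm <- gm[order(gm$order), , drop = FALSE]
    cum <- 0L
    pieces <- list()
    bounds <- data.frame(exon_id = gm$exon_id, start = NA_integer_,
                         end = NA_integer_)
    for (k in seq_len(nrow(gm))) {
      ex <- exons[[gm$exon_id[k]]]
      if (anyDuplicated(ex$taxa))
        stop("conflicting duplicate taxon rows in exon ", gm$exon_id[k])
      if (!is.null(gm$frame) && !is.na(gm$frame[k]) &&
          gm$frame[k] != cum %% 3L)
        stop(sprintf("frame discontinuity at exon %s of gene %s: expected %d, map says %d",
                     gm$exon_id[k], g, cum %% 3L, gm$frame[k]))
      block <- matrix("N", length(taxa), ncol(ex$matrix),
                      dimnames = list(taxa, NULL))
      block[ex$taxa, ] <- ex$matrix
      pieces[[k]] <- block
      bounds$start[k] <- cum + 1L
      bounds$end[k] <- cum + ncol(ex$matrix)
      cum <- cum + ncol(ex$matrix)
    }
    m <- do.call(cbind, pieces)
    aln <- gene_alignment(g, m, frame_offset = 0L)
    attr(aln, "boundaries") <- bounds
    out[[g]] <- aln
  }
  out
}

#' Split a concatenated gene back into its exons
#'
#' Inverse of [concatenate_exons()] using the recorded boundaries.
#'
#' @param gene A concatenated [gene_alignment()] with a `boundaries`
#'   attribute.
#' @return Named list of exon alignments (padded rows included).
#' @export
split_concatenation <- function(gene) {
  b <- attr(gene, "boundaries")
  if (is.null(b)) stop("no boundary record on this alignment")
  out <- lapply(seq_len(nrow(b)), function(k) {
    gene_alignment(b$exon_id[k],
                   gene$matrix[, b$start[k]:b$end[k], drop = FALSE],
                   frame_offset = (b$start[k] - 1L) %% 3L)
  })
  names(out) <- b$exon_id
  out
}
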