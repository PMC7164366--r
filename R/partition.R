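# Rate-based gene partitioning: per-gene relative rates from pairwise HKY85
# distances, contiguous rate bins, codon-position splitting, and
# clocklikeness ranking for reduced-dataset experiments.

#' Per-gene relative rates from a designated taxon pair
#'
#' For each gene computes the pairwise HKY85 maximum-likelihood distance
#' between `primary_pair`; if a member of the pair is absent (or shares no
#' ungapped site), the first available fallback taxon substitutes for it,
#' and the pair actually used is recorded. Genes with no usable pair are
#' excluded and logged.
#'
#' @param genes Named list of [gene_alignment()] objects.
#' @param primary_pair Character vector of two taxon labels.
#' @param fallback_taxa Ordered character vector of substitutes.
#' @param ... Passed to [hky_distance()].
#' @return Object of class `gene_rate_table`: data frame `gene_id`,
#'   `distance`, `taxon_a`, `taxon_b`, `saturated`; attribute `unratable`
#'   lists excluded genes.
#' @export
gene_rate_table <- function(genes, primary_pair, fallback_taxa = character(),
                            ...) {
  usable <- function(aln, tax) {
    tax %in% aln$taxa && any(!(aln$matrix[tax, ] %in% c("-", "N")))
  }
  rows <- list(); unratable <- character(0)
  for (g in names(genes)) {
    aln <- genes[[g]]
    pair <- primary_pair
    for (k in 1:2) {
      if (!usable(aln, pair[k])) {
        subs <- fallback_taxa[vapply(fallback_taxa, function(f)
          usable(aln, f) && !(f %in% pair), logical(1))]
        if (length(subs)) pair[k] <- subs[1] else pair[k] <- NA_character_
      }
    }
    shared <- if (!anyNA(pair)) {
      a <- aln$matrix[pair[1], ]; b <- aln$matrix[pair[2], ]
      sum(!(a %in% c("-", "N")) & !(b %in% c("-", "N")))
    } else 0L
    if (anyNA(pair) || shared < 1) {
      unratable <- c(unratable, g)
      next
    }
    d <- hky_distance(aln$matrix[pair[1], ], aln$matrix[pair[2], ], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, distance = as.numeric(d), taxon_a = pair[1],
      taxon_b = pair[2], saturated = isTRUE(attr(d, "saturated")),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(), distance = numeric(),
                  taxon_a = character(), taxon_b = character(),
                  saturated = logical(), stringsAsFactors = FALSE)
  structure(tab, unratable = unratable,
            class = c("gene_rate_table", "data.frame"))
}

#' Bin genes into k contiguous rate partitions
#'
#' Genes are sorted by ascending distance (ties by gene id) and split into
#' `k` contiguous bins whose sizes differ by at most one; when the gene
#' count is not divisible by `k`, the slower bins receive the remainder
#' first. Saturated genes sort to the fastest bin.
#'
#' @param table A [gene_rate_table()].
#' @param k Number of partitions (1 <= k <= number of genes).
#' @return Object of class `partition_scheme`: list with `partitions` (each
#'   `list(genes, cp_class)`, `cp_class` = `"all"`), `label` (e.g. `"3p"`),
#'   and `rate_table`.
#' @export
bin_genes <- function(table, k) {
  k <- as.integer(k)
  n <- nrow(table)
  if (n == 0) stop("empty rate table")
  if (k < 1 || k > n) stop("k must be between 1 and the number of genes")
  ord <- order(table$distance, table$gene_id)
  sorted <- table[ord, , drop = FALSE]
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L  # slower bins first
  idx <- split(seq_len(n), rep(seq_len(k), sizes))
  partitions <- lapply(seq_len(k), function(i)
    list(genes = sorted$gene_id[idx[[i]]], cp_class = "all"))
  scheme <- structure(list(partitions = partitions,
                           label = paste0(k, "p"),
                           rate_table = sorted),
                      class = "partition_scheme")
  validate_partition_scheme(scheme)
  scheme
}

#' Check the rate-ordering invariant of a partition scheme
#'
#' Asserts that partitions are disjoint, cover all genes of the rate table,
#' and that the maximum distance in bin i does not exceed the minimum in
#' bin i+1.
#'
#' @param scheme A `partition_scheme`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_partition_scheme <- function(scheme) {
  tab <- scheme$rate_table
  gsets <- lapply(scheme$partitions, `[[`, "genes")
  cls <- vapply(scheme$partitions, `[[`, "", "cp_class")
  flat <- unlist(gsets[vapply(scheme$partitions, function(p)
    p$cp_class == cls[1], logical(1))])
  if (anyDuplicated(flat)) stop("partitions are not disjoint")
  if (!setequal(flat, tab$gene_id)) stop("partitions do not cover all genes")
  d <- setNames(tab$distance, tab$gene_id)
  bins <- gsets[vapply(scheme$partitions, function(p)
    p$cp_class == cls[1], logical(1))]
  if (length(bins) > 1) {
    for (i in seq_len(length(bins) - 1L)) {
      if (max(d[bins[[i]]]) > min(d[bins[[i + 1L]]]) + 1e-12)
        stop("rate-ordering invariant violated between bins ", i, " and ", i + 1)
    }
  }
  invisible(TRUE)
}

#' Split a partition scheme by codon position
#'
#' Duplicates each rate bin into a '1st+2nd codon position' class and a
#' '3rd codon position' class (3 partitions become 6, k become 2k); gene
#' membership is unchanged.
#'
#' @param scheme A `partition_scheme` with `cp_class = "all"` throughout.
#' @return A new `partition_scheme` with label `"<2k>p"`.
#' @export
split_codon_positions <- function(scheme) {
  cls <- vapply(scheme$partitions, `[[`, "", "cp_class")
  if (any(cls != "all")) stop("scheme is already split by codon position")
  parts <- list()
  for (p in scheme$partitions) {
    parts[[length(parts) + 1L]] <- list(genes = p$genes, cp_class = "12")
    parts[[length(parts) + 1L]] <- list(genes = p$genes, cp_class = "3")
  }
  structure(list(partitions = parts,
                 label = paste0(length(parts), "p"),
                 rate_table = scheme$rate_table),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition_scheme '%s': %d partitions\n", x$label,
              length(x$partitions)))
  for (i in seq_along(x$partitions)) {
    p <- x$partitions[[i]]
    cat(sprintf("  [%d] %d genes, codon positions %s\n", i,
                length(p$genes), p$cp_class))
  }
  invisible(x)
}

#' Extract the sites of a partition from gene alignments
#'
#' Concatenates the member genes of each partition and keeps the codon
#' positions of its class (`"all"`, `"12"`, or `"3"`).
#'
#' @param scheme A `partition_scheme`.
#' @param genes Named list of [gene_alignment()] objects.
#' @param taxa Optional taxon namespace (default union; absent taxa padded
#'   with 'N').
#' @return List of character matrices, one per partition.
#' @export
partition_alignments <- function(scheme, genes, taxa = NULL) {
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(genes, function(a) a$taxa))))
  lapply(scheme$partitions, function(p) {
    blocks <- lapply(p$genes, function(g) {
      aln <- genes[[g]]
      keep <- switch(p$cp_class,
                     all = seq_along(aln$codon_pos),
                     `12` = which(aln$codon_pos %in% 1:2),
                     `3` = which(aln$codon_pos == 3))
      block <- matrix("N", length(taxa), length(keep),
                      dimnames = list(taxa, NULL))
      block[aln$taxa, ] <- aln$matrix[, keep, drop = FALSE]
      block
    })
    do.call(cbind, blocks)
  })
}

# --- clocklikeness ranking -------------------------------------------------

root_to_tip_variance <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  stats::var(depth[seq_len(n)])
}

# Unordered bipartitions of a tree's internal edges as canonical strings.
bipartitions <- function(phy) {
  n <- ape::Ntip(phy)
  labs <- phy$tip.label
  pp <- ape::prop.part(phy)
  out <- character(0)
  for (i in seq_along(pp)) {
    tips <- sort(labs[pp[[i]]])
    if (length(tips) <= 1 || length(tips) >= n - 1) next  # trivial splits
    comp <- sort(setdiff(labs, tips))
    side <- if (labs[1] %in% tips) tips else comp
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Rank genes by clocklikeness, information content, and agreement
#'
#' Scores each gene tree by (i) root-to-tip path-length variance (lower is
#' more clocklike), (ii) total tree length (higher is more informative),
#' and (iii) the fraction of its non-trivial bipartitions shared with the
#' species tree (restricted to the gene's taxa). Genes below the agreement
#' threshold are filtered out; the rest are sorted by variance ascending
#' with ties broken by tree length descending.
#'
#' @param gene_trees Named list of rooted `phylo` objects with branch
#'   lengths (substitutions/site).
#' @param species_tree A `phylo` whose tips form the reference namespace.
#' @param n_select Number of genes to return.
#' @param agreement_threshold Minimum bipartition agreement (default 0.3).
#' @return Data frame of the selected genes, ordered: `gene_id`,
#'   `rtt_variance`, `tree_length`, `agreement`; attribute `excluded` lists
#'   genes dropped (too few tips or low agreement) with reasons; attribute
#'   `scores` holds the full score table.
#' @export
rank_clocklike <- function(gene_trees, species_tree, n_select,
                           agreement_threshold = 0.3) {
  rows <- list(); excluded <- list()
  for (g in names(gene_trees)) {
    tr <- gene_trees[[g]]
    if (ape::Ntip(tr) < 4) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = g, reason = "fewer than 4 tips")
      next
    }
    sp <- ape::keep.tip(species_tree, intersect(species_tree$tip.label,
                                                tr$tip.label))
    bg <- bipartitions(tr)
    bs <- bipartitions(sp)
    agreement <- if (length(bg)) mean(bg %in% bs) else 1
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, rtt_variance = root_to_tip_variance(tr),
      tree_length = sum(tr$edge.length), agreement = agreement,
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  keep <- scores[scores$agreement >= agreement_threshold, , drop = FALSE]
  low <- scores[scores$agreement < agreement_threshold, , drop = FALSE]
  if (nrow(low))
    excluded[[length(excluded) + 1L]] <-
      data.frame(gene_id = low$gene_id, reason = "agreement below threshold")
  keep <- keep[order(keep$rtt_variance, -keep$tree_length, keep$gene_id), ,
               drop = FALSE]
  out <- utils::head(keep, n_select)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  else data.frame(gene_id = character(), reason = character())
  attr(out, "scores") <- scores
  out
}
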