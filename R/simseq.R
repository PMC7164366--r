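# Sequence simulation: HKY85+Gamma evolution of in-frame coding alignments
# down a timetree, with codon-position rate multipliers.

#' In-frame coding alignment container
#'
#' @param gene_id Gene identifier.
#' @param matrix Character matrix (taxa x sites) over A, C, G, T, '-', 'N'.
#' @param frame_offset Reading-frame offset (0-2): the first complete codon
#'   starts at column `frame_offset + 1`.
#' @return Object of class `gene_alignment` with fields `gene_id`, `taxa`,
#'   `matrix`, `codon_pos` (per-site codon position 1-3), `frame_offset`.
#' @export
gene_alignment <- function(gene_id, matrix, frame_offset = 0L) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1, !is.null(rownames(matrix)))
  frame_offset <- as.integer(frame_offset) %% 3L
  codon_pos <- ((seq_len(ncol(matrix)) - 1L - frame_offset) %% 3L) + 1L
  structure(list(gene_id = gene_id, taxa = rownames(matrix), matrix = matrix,
                 codon_pos = codon_pos, frame_offset = frame_offset),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment '%s': %d taxa x %d sites (frame %d)\n",
              x$gene_id, nrow(x$matrix), ncol(x$matrix), x$frame_offset))
  invisible(x)
}

#' Simulate a coding alignment under HKY85+Gamma on a timetree
#'
#' The root sequence is drawn from the equilibrium base frequencies; sites
#' then evolve independently down the tree. The expected number of
#' substitutions on a branch at a site is
#' `duration x branch rate x codon-position multiplier x gamma-category
#' rate`, with each site assigned one of the equal-probability discrete
#' gamma categories.
#'
#' @param tt A `timetree`.
#' @param rates Branch rates as returned by [simulate_branch_rates()]
#'   (per edge of `tt$phy`, in substitutions/site per the time unit of the
#'   ages in `tt`).
#' @param sub A [substitution_params()].
#' @param n_codons Number of codons (alignment has `3 * n_codons` sites).
#' @param cp_multipliers Relative rates of codon positions 1-3 (positive;
#'   default `c(0.7, 0.3, 2.0)`, the fast-third-position pattern of
#'   protein-coding genes).
#' @param seed Integer seed.
#' @param gene_id Gene identifier for the output.
#' @return A [gene_alignment()] (frame offset 0, no gaps).
#' @export
simulate_alignment <- function(tt, rates, sub, n_codons,
                               cp_multipliers = c(0.7, 0.3, 2.0), seed = 1L,
                               gene_id = "gene") {
  stopifnot(inherits(tt, "timetree"), inherits(sub, "substitution_params"))
  if (n_codons < 1) stop("n_codons must be at least 1")
  if (any(cp_multipliers <= 0)) stop("cp_multipliers must be positive")
  phy <- tt$phy
  n <- ape::Ntip(phy)
  nsite <- 3L * as.integer(n_codons)
  set.seed(seed)
  cat_rates <- gamma_category_rates(sub$gamma_shape, sub$n_categories)
  site_cp <- rep(1:3, n_codons)
  site_cat <- sample.int(sub$n_categories, nsite, replace = TRUE)
  site_mult <- cp_multipliers[site_cp] * cat_rates[site_cat]

  states <- matrix(0L, n + phy$Nnode, nsite)  # 1:4 = A,C,G,T
  root <- n + 1L
  states[root, ] <- sample.int(4L, nsite, replace = TRUE,
                               prob = sub$base_freqs)
  # preorder edge traversal (parents before children)
  ord <- order(tt$ages[phy$edge[, 1]], decreasing = TRUE)
  dur <- tt$ages[phy$edge[, 1]] - tt$ages[phy$edge[, 2]]
  mult_levels <- sort(unique(site_mult))
  site_group <- match(site_mult, mult_levels)
  for (e in ord) {
    b <- dur[e] * rates[e]
    par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    if (b <= 0) { states[child, ] <- states[par, ]; next }
    for (g in seq_along(mult_levels)) {
      idx <- which(site_group == g)
      P <- hky_pmat_cpp(b * mult_levels[g], sub$kappa, sub$base_freqs)
      ps <- states[par, idx]
      u <- stats::runif(length(idx))
      cum <- t(apply(P, 1, cumsum))
      newstate <- integer(length(idx))
      for (s in 1:4) {
        sel <- ps == s
        if (any(sel))
          newstate[sel] <- 1L + findInterval(u[sel], cum[s, ],
                                             rightmost.closed = FALSE)
      }
      newstate[newstate > 4L] <- 4L
      states[child, idx] <- newstate
    }
  }
  m <- matrix(DNA_STATES[states[seq_len(n), ]], nrow = n)
  rownames(m) <- phy$tip.label
  gene_alignment(gene_id, m, frame_offset = 0L)
}

#' Remove internal stop codons from an alignment
#'
#' Recodes the first position of any in-frame internal TAA/TAG/TGA codon to
#' 'C', so simulated genes are coding-like (stop-free except possibly at the
#' terminal codon) and injected stops are the only internal stops present.
#'
#' @param aln A [gene_alignment()].
#' @return The sanitized alignment.
#' @export
remove_internal_stops <- function(aln) {
  m <- aln$matrix
  n_codon <- (ncol(m) - aln$frame_offset) %/% 3
  if (n_codon < 2) return(aln)
  for (i in seq_len(nrow(m))) {
    for (codon in seq_len(n_codon - 1L)) {  # spare the terminal codon
      cols <- aln$frame_offset + (codon - 1L) * 3L + 1:3
      cd <- paste(m[i, cols], collapse = "")
      if (cd %in% c("TAA", "TAG", "TGA")) m[i, cols[1]] <- "C"
    }
  }
  gene_alignment(aln$gene_id, m, aln$frame_offset)
}

#' Simulate a multi-gene set with gene-specific rate multipliers
#'
#' Gene rate multipliers are log-spaced over `gene_rate_range` so the set
#' spans slow to fast genes; per-gene random streams are derived by hashing
#' `(seed, gene_id)`, so a gene's alignment does not depend on the order of
#' generation.
#'
#' @param tt A `timetree`.
#' @param n_genes Number of genes.
#' @param spec A [clock_model_spec()] used for branch rates. Either one set
#'   of branch rates shared by all genes (`per_gene_rates = FALSE`) or
#'   independently drawn per gene.
#' @param sub A [substitution_params()].
#' @param n_codons Codons per gene (recycled).
#' @param gene_rate_range Range `c(lo, hi)` of per-gene rate multipliers.
#' @param per_gene_rates Draw new branch rates for each gene?
#' @param cp_multipliers Codon-position multipliers, see
#'   [simulate_alignment()].
#' @param seed Master integer seed.
#' @param sanitize Remove internal stop codons (see
#'   [remove_internal_stops()])? Default `TRUE`.
#' @return List with `alignments` (list of `gene_alignment`), `gene_rates`
#'   (multipliers), and `branch_rates` (list per gene).
#' @export
simulate_gene_set <- function(tt, n_genes, spec, sub, n_codons = 100,
                              gene_rate_range = c(0.3, 3),
                              per_gene_rates = TRUE,
                              cp_multipliers = c(0.7, 0.3, 2.0), seed = 1L,
                              sanitize = TRUE) {
  n_codons <- rep_len(n_codons, n_genes)
  gmult <- exp(seq(log(gene_rate_range[1]), log(gene_rate_range[2]),
                   length.out = n_genes))
  ids <- sprintf("g%03d", seq_len(n_genes))
  shared_rates <- if (!per_gene_rates)
    simulate_branch_rates(tt, spec, seed = derive_seed(seed, "shared"))
  alns <- vector("list", n_genes)
  brates <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gs <- derive_seed(seed, ids[i])
    base <- if (per_gene_rates)
      simulate_branch_rates(tt, spec, seed = gs)
    else shared_rates
    brates[[i]] <- base * gmult[i]
    alns[[i]] <- simulate_alignment(tt, brates[[i]], sub, n_codons[i],
                                    cp_multipliers,
                                    seed = derive_seed(seed, paste0(ids[i], ".seq")),
                                    gene_id = ids[i])
    if (sanitize) alns[[i]] <- remove_internal_stops(alns[[i]])
  }
  names(alns) <- ids
  list(alignments = alns, gene_rates = setNames(gmult, ids),
       branch_rates = setNames(brates, ids))
}

#' Inject pseudogene artifacts and taxon dropout into alignments
#'
#' Corrupts a gene set with internal stop codons, frameshift gaps (run
#' length not a multiple of 3), and per-taxon random gene dropout, and
#' returns a ground-truth log of every injected artifact.
#'
#' @param alignments List of [gene_alignment()] objects.
#' @param rules List with any of:
#'   \describe{
#'     \item{stop_genes}{character vector of gene ids to receive internal
#'       stop codons (or integer count: that many genes, chosen from the
#'       start of the list)}
#'     \item{stops_per_gene}{number of stop codons injected per corrupted
#'       gene (default 1)}
#'     \item{frameshift_genes}{gene ids (or count) to receive one frameshift
#'       gap each}
#'     \item{frameshift_len}{gap length, must not be a multiple of 3
#'       (default 4)}
#'     \item{dropout}{named numeric vector: per-taxon probability that the
#'       taxon's row in a gene is replaced by all-N}
#'   }
#' @param seed Integer seed.
#' @return List with `alignments` (corrupted copies) and `log` (data frame:
#'   `gene_id`, `taxon`, `type`, `codon`, `site`, `length`).
#' @export
corrupt_fixture <- function(alignments, rules = list(), seed = 1L) {
  set.seed(seed)
  log_rows <- list()
  pick_genes <- function(x) {
    if (is.null(x)) character(0)
    else if (is.numeric(x)) names(alignments)[seq_len(x)]
    else x
  }
  stop_genes <- pick_genes(rules$stop_genes)
  fs_genes <- pick_genes(rules$frameshift_genes)
  spg <- rules$stops_per_gene %||% 1L
  fs_len <- rules$frameshift_len %||% 4L
  if (fs_len %% 3 == 0) stop("frameshift_len must not be a multiple of 3")
  out <- alignments
  stops <- c("TAA", "TAG", "TGA")
  for (g in stop_genes) {
    aln <- out[[g]]
    n_codon <- (ncol(aln$matrix) - aln$frame_offset) %/% 3
    for (k in seq_len(spg)) {
      taxon <- sample(aln$taxa, 1)
      codon <- sample(2:(n_codon - 1), 1)  # internal: not first, not last
      cols <- aln$frame_offset + (codon - 1L) * 3L + 1:3
      aln$matrix[taxon, cols] <- strsplit(sample(stops, 1), "")[[1]]
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        gene_id = g, taxon = taxon, type = "premature_stop", codon = codon,
        site = cols[1], length = 3L, stringsAsFactors = FALSE)
    }
    out[[g]] <- aln
  }
  for (g in fs_genes) {
    aln <- out[[g]]
    taxon <- sample(aln$taxa, 1)
    start <- sample.int(ncol(aln$matrix) - fs_len, 1)
    aln$matrix[taxon, start:(start + fs_len - 1L)] <- "-"
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      gene_id = g, taxon = taxon, type = "frameshift", codon = NA_integer_,
      site = start, length = fs_len, stringsAsFactors = FALSE)
    out[[g]] <- aln
  }
  if (!is.null(rules$dropout)) {
    for (taxon in names(rules$dropout)) {
      pr <- rules$dropout[[taxon]]
      for (g in names(out)) {
        if (stats::runif(1) < pr && taxon %in% out[[g]]$taxa) {
          out[[g]]$matrix[taxon, ] <- "N"
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            gene_id = g, taxon = taxon, type = "dropout", codon = NA_integer_,
            site = NA_integer_, length = ncol(out[[g]]$matrix),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows)
  else data.frame(gene_id = character(), taxon = character(),
                  type = character(), codon = integer(), site = integer(),
                  length = integer(), stringsAsFactors = FALSE)
  list(alignments = out, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
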