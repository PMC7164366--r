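# Timetrees: rooted binary trees with node ages in Ma.

#' Construct a timetree from a dated phylogeny
#'
#' @param phy An `ape::phylo` object, rooted and binary, with edge lengths
#'   in Ma and all tips contemporaneous (age 0).
#' @return Object of class `timetree`: the phylogeny plus a node-age vector
#'   (`ages`, indexed by ape node id, tips = 0) and `root_age` in Ma.
#' @export
timetree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be binary")
  ages <- node_ages_from_lengths(phy)
  structure(list(phy = phy, ages = ages,
                 root_age = ages[ape::Ntip(phy) + 1L]),
            class = "timetree")
}

node_ages_from_lengths <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  tipd <- depth[seq_len(n)]
  if (diff(range(tipd)) > 1e-6 * max(tipd, 1))
    stop("tree is not ultrametric: tips are not contemporaneous")
  ages <- max(tipd) - depth
  ages[seq_len(n)] <- 0
  ages
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("timetree: %d tips, root age %.4g Ma\n",
              ape::Ntip(x$phy), x$root_age))
  invisible(x)
}

#' Validate timetree invariants
#'
#' Checks that every internal node is strictly older than each child, that
#' tips have age 0, and that there are n-1 internal nodes for n tips.
#'
#' @param tt A `timetree`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_timetree <- function(tt) {
  stopifnot(inherits(tt, "timetree"))
  phy <- tt$phy
  n <- ape::Ntip(phy)
  if (phy$Nnode != n - 1L) stop("expected n-1 internal nodes for n tips")
  if (any(tt$ages[seq_len(n)] != 0)) stop("tip ages must all be 0")
  e <- phy$edge
  if (any(tt$ages[e[, 1]] <= tt$ages[e[, 2]]))
    stop("every parent age must exceed its child ages")
  invisible(TRUE)
}

#' Simulate a fossil-record-style timetree
#'
#' Draws non-root internal node ages i.i.d. from the birth-death node-age
#' kernel conditional on the root age, and attaches them by rank to a random
#' labeled history (lineages joined in age order, pairs chosen uniformly).
#' The root age is fixed exactly at `root_age`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in Ma (> 0).
#' @param bd Birth-death parameters `c(lambda, mu_death, rho)`; defaults to
#'   lambda = mu = 1, rho = 0.1, which gives an approximately uniform
#'   node-age density.
#' @param seed Integer seed (deterministic output).
#' @return A `timetree`.
#' @export
simulate_timetree <- function(n_tips, root_age, bd = c(1, 1, 0.1), seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2) stop("n_tips must be at least 2")
  if (!(root_age > 0)) stop("root_age must be positive")
  if (any(bd[1:2] < 0)) stop("birth and death rates must be nonnegative")
  if (!(bd[3] > 0 && bd[3] <= 1)) stop("rho must be in (0, 1]")
  set.seed(seed)
  ages_int <- if (n_tips > 2) {
    sort(bd_kernel_quantile(stats::runif(n_tips - 2L), root_age,
                            bd[1], bd[2], bd[3]))
  } else numeric(0)
  ages_int <- c(ages_int, root_age)  # ascending; root joins last

  # ranked random joining: internal ids assigned so the root is n_tips + 1
  n_int <- n_tips - 1L
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  age_of <- c(rep(0, n_tips), rep(NA_real_, n_int))
  active <- seq_len(n_tips)
  erow <- 0L
  for (j in seq_len(n_int)) {
    new_id <- 2L * n_tips - j  # j-th join; last join gets n_tips + 1 (root)
    pick <- sample(length(active), 2L)
    kids <- active[pick]
    age_of[new_id] <- ages_int[j]
    for (k in kids) {
      erow <- erow + 1L
      edge[erow, ] <- c(new_id, k)
      elen[erow] <- ages_int[j] - age_of[k]
    }
    active <- c(active[-pick], new_id)
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(n_tips)),
                        Nnode = n_int),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  tt <- timetree(phy)
  validate_timetree(tt)
  tt
}

#' Write a timetree to Newick with branch lengths in Ma
#'
#' @param tt A `timetree`.
#' @param file Output path.
#' @param header Optional provenance comment (written in a `[...]` block).
#' @export
write_timetree <- function(tt, file, header = NULL) {
  txt <- ape::write.tree(tt$phy)
  if (!is.null(header)) txt <- paste0("[", header, "]", txt)
  writeLines(txt, file)
  invisible(file)
}

# MRCA node id for a pair of tip labels
mrca_node <- function(phy, tip_a, tip_b) {
  ia <- match(tip_a, phy$tip.label)
  ib <- match(tip_b, phy$tip.label)
  if (is.na(ia) || is.na(ib))
    stop("tip not found in tree: ", if (is.na(ia)) tip_a else tip_b)
  ape::getMRCA(phy, c(ia, ib))
}
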