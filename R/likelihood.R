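# Exact phylogenetic likelihood under HKY85+Gamma (Felsenstein pruning with
# site-pattern compression), branch-length MLEs, and the gradient/Hessian
# quadratic approximation used for fast dating MCMC.

aln_matrix <- function(aln) {
  if (inherits(aln, "gene_alignment")) aln$matrix else aln
}

# Compress an alignment into unique site patterns for the tips of `phy`.
# Tips absent from the alignment are treated as all-missing.
compress_patterns <- function(m, phy) {
  extra <- setdiff(rownames(m), phy$tip.label)
  if (length(extra))
    stop("alignment taxa absent from tree: ", paste(extra, collapse = ", "))
  n <- ape::Ntip(phy)
  codes <- matrix(4L, n, ncol(m))
  present <- match(rownames(m), phy$tip.label)
  codes[present, ] <- matrix(encode_dna(m), nrow(m), ncol(m))
  keys <- apply(codes, 2, paste, collapse = ",")
  first <- !duplicated(keys)
  idx <- which(first)
  w <- as.numeric(table(factor(keys, levels = keys[first])))
  list(tipstate = codes[, idx, drop = FALSE], weights = w,
       n_sites = ncol(m))
}

postorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  storage.mode(po$edge) <- "integer"
  po
}

#' Exact log likelihood by pruning under HKY85+Gamma
#'
#' Sums, over compressed site patterns, the log of the gamma-category-
#' averaged pruning likelihood. Gaps, Ns and tips absent from the alignment
#' are treated as missing data. The model is time-reversible, so the value
#' is invariant to the position of the root.
#'
#' @param aln A [gene_alignment()] or character matrix (taxa x sites).
#' @param tree `phylo` with branch lengths in substitutions/site (rooted or
#'   unrooted).
#' @param sub A [substitution_params()].
#' @return Log likelihood (one number).
#' @export
prune_loglik <- function(aln, tree, sub) {
  m <- aln_matrix(aln)
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  pat <- compress_patterns(m, tree)
  po <- postorder_edges(tree)
  nnode <- ape::Ntip(tree) + tree$Nnode
  prune_loglik_cpp(po$edge, ape::Ntip(tree), nnode, po$edge.length,
                   pat$tipstate, pat$weights, sub$kappa, sub$base_freqs,
                   gamma_category_rates(sub$gamma_shape, sub$n_categories))
}

# loglik as a function of the branch-length vector of `utree` (edge order
# fixed); pattern compression is done once.
make_loglik_fn <- function(m, utree, sub) {
  pat <- compress_patterns(m, utree)
  po <- postorder_edges(utree)
  # postorder reorder permutes edges; track the permutation
  key <- paste(utree$edge[, 1], utree$edge[, 2])
  pkey <- paste(po$edge[, 1], po$edge[, 2])
  perm <- match(pkey, key)
  nnode <- ape::Ntip(utree) + utree$Nnode
  rates <- gamma_category_rates(sub$gamma_shape, sub$n_categories)
  list(
    fn = function(b) {
      prune_loglik_cpp(po$edge, ape::Ntip(utree), nnode, b[perm],
                       pat$tipstate, pat$weights, sub$kappa, sub$base_freqs,
                       rates)
    },
    n_sites = pat$n_sites)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Cyclic one-dimensional (Brent) maximization over branches of the exact
#' pruning likelihood, to a per-site gradient tolerance. Branches are
#' clamped at zero (one-sided gradient retained in the report).
#'
#' @param aln Alignment (matrix or [gene_alignment()]).
#' @param topology `phylo`; a rooted topology is unrooted first (the
#'   reversible likelihood cannot separate the two root-adjacent branches).
#' @param sub A [substitution_params()].
#' @param tol Per-site gradient tolerance (default 1e-6).
#' @param max_rounds Maximum optimization sweeps over all branches.
#' @param b_max Upper bound per branch (substitutions/site).
#' @return List: `tree` (unrooted, MLE lengths), `b_hat`, `logl_hat`,
#'   `gradient`, `converged`, `n_sites`.
#' @export
mle_branch_lengths <- function(aln, topology, sub, tol = 1e-6,
                               max_rounds = 4, b_max = 5) {
  m <- aln_matrix(aln)
  if (ape::Ntip(topology) == 2) {
    # a two-taxon tree has a single identifiable branch (the tip-to-tip
    # path); the second edge is pinned at zero
    utree <- topology
    utree$edge.length <- NULL
    lf <- make_loglik_fn(m, utree, sub)
    o <- stats::optimize(function(x) -lf$fn(c(x, 0)),
                         interval = c(0, b_max), tol = 1e-10)
    b <- c(o$minimum, 0)
    utree$edge.length <- b
    g <- loglik_gradient(lf$fn, b)
    return(list(tree = utree, b_hat = b, logl_hat = -o$objective,
                gradient = g, converged = TRUE, n_sites = lf$n_sites))
  }
  utree <- if (ape::is.rooted(topology)) ape::unroot(topology) else topology
  utree$edge.length <- NULL
  lf <- make_loglik_fn(m, utree, sub)
  nb <- nrow(utree$edge)
  b <- rep(0.05, nb)
  ll <- lf$fn(b)
  brent_round <- function(b, ll, tol1d = 1e-7) {
    for (i in seq_len(nb)) {
      o <- stats::optimize(function(x) {
        bb <- b; bb[i] <- x; -lf$fn(bb)
      }, interval = c(0, b_max), tol = tol1d)
      if (-o$objective > ll) { b[i] <- o$minimum; ll <- -o$objective }
    }
    list(b = b, ll = ll)
  }
  grfun <- function(b) loglik_gradient(lf$fn, pmax(b, 0))
  gmax <- Inf
  for (round in seq_len(max_rounds)) {
    # one coordinate sweep to reach the basin, then quasi-Newton polish
    w <- brent_round(b, ll)
    b <- w$b; ll <- w$ll
    obj <- function(bb) {
      v <- lf$fn(pmax(bb, 0))
      if (!is.finite(v)) 1e10 else -v
    }
    fit <- stats::optim(pmax(b, 1e-8), obj, gr = function(bb) -grfun(bb),
                        method = "L-BFGS-B", lower = 1e-8, upper = b_max,
                        control = list(factr = 10, maxit = 200))
    if (-fit$value > ll) { b <- pmax(fit$par, 0); ll <- -fit$value }
    g <- loglik_gradient(lf$fn, b)
    interior <- b > 1e-8
    gmax <- if (any(interior)) max(abs(g[interior])) else 0
    if (gmax / lf$n_sites < tol) break
  }
  b[b < 1e-9] <- 0
  utree$edge.length <- b
  converged <- (gmax / lf$n_sites < tol)
  if (!converged)
    warning(sprintf("branch-length optimization stopped at per-site gradient %.2e (tol %.0e)",
                    gmax / lf$n_sites, tol))
  list(tree = utree, b_hat = b, logl_hat = lf$fn(b), gradient = g,
       converged = converged, n_sites = lf$n_sites)
}

loglik_gradient <- function(fn, b, h_rule = function(bi) pmax(1e-8, 1e-5 * bi)) {
  g <- numeric(length(b))
  for (i in seq_along(b)) {
    h <- h_rule(b[i])
    bp <- b; bp[i] <- b[i] + h
    if (b[i] - h >= 0) {
      bm <- b; bm[i] <- b[i] - h
      g[i] <- (fn(bp) - fn(bm)) / (2 * h)
    } else {  # one-sided at the zero boundary
      g[i] <- (fn(bp) - fn(b)) / h
    }
  }
  g
}

#' Gradient and Hessian of the log likelihood at the branch-length MLE
#'
#' Central finite differences with per-branch step
#' `h_i = max(1e-4, 1e-2 * b_i)`; one-sided at the zero boundary. The
#' Hessian is symmetrized; a warning (not an error) is raised if it is not
#' negative semi-definite at an interior optimum.
#'
#' @param aln Alignment.
#' @param topology `phylo` (unrooted or rooted; see
#'   [mle_branch_lengths()]).
#' @param sub A [substitution_params()].
#' @param b_hat Branch-length MLEs (edge order of the unrooted topology).
#' @return List `g` (gradient), `H` (symmetrized Hessian), `logl_hat`.
#' @export
hessian_at_mle <- function(aln, topology, sub, b_hat) {
  m <- aln_matrix(aln)
  utree <- if (ape::is.rooted(topology) && ape::Ntip(topology) > 2)
    ape::unroot(topology) else topology
  lf <- make_loglik_fn(m, utree, sub)
  fd_gradient_hessian(lf$fn, b_hat)
}

# shared finite-difference engine (also validated on analytic test functions)
fd_gradient_hessian <- function(fn, b) {
  nb <- length(b)
  h <- pmax(1e-4, 1e-2 * b)
  f0 <- fn(b)
  g <- numeric(nb)
  H <- matrix(0, nb, nb)
  shift <- function(i, s) { bb <- b; bb[i] <- bb[i] + s; bb }
  onesided <- b - h < 0
  fp <- numeric(nb); fm <- numeric(nb)
  for (i in seq_len(nb)) {
    fp[i] <- fn(shift(i, h[i]))
    if (onesided[i]) {
      f2 <- fn(shift(i, 2 * h[i]))
      H[i, i] <- (f2 - 2 * fp[i] + f0) / h[i]^2
    } else {
      fm[i] <- fn(shift(i, -h[i]))
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    }
  }
  # gradient with a finer step than the Hessian rule (second differences
  # tolerate a coarser h than first differences on steep small branches)
  g <- loglik_gradient(fn, b)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      si <- if (onesided[i]) c(h[i], 0) else c(h[i], -h[i])
      sj <- if (onesided[j]) c(h[j], 0) else c(h[j], -h[j])
      bpp <- b; bpp[i] <- bpp[i] + si[1]; bpp[j] <- bpp[j] + sj[1]
      bpm <- b; bpm[i] <- bpm[i] + si[1]; bpm[j] <- bpm[j] + sj[2]
      bmp <- b; bmp[i] <- bmp[i] + si[2]; bmp[j] <- bmp[j] + sj[1]
      bmm <- b; bmm[i] <- bmm[i] + si[2]; bmm[j] <- bmm[j] + sj[2]
      denom <- (si[1] - si[2]) * (sj[1] - sj[2])
      H[i, j] <- H[j, i] <- (fn(bpp) - fn(bpm) - fn(bmp) + fn(bmm)) / denom
    }
  }
  H <- (H + t(H)) / 2
  interior <- !onesided
  if (any(interior)) {
    ev <- eigen(H[interior, interior, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev > 1e-6 * max(abs(ev))))
      warning("Hessian is not negative semi-definite at the interior optimum")
  }
  list(g = g, H = H, logl_hat = f0)
}

# canonical bipartition key of each edge (tip set under the child node,
# reduced to the side containing the first tip label)
edge_split_keys <- function(phy) {
  n <- ape::Ntip(phy)
  labs <- phy$tip.label
  po <- postorder_edges(phy)
  below <- vector("list", n + phy$Nnode)
  for (v in seq_len(n)) below[[v]] <- labs[v]
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1]]] <- c(below[[po$edge[e, 1]]],
                                below[[po$edge[e, 2]]])
  vapply(seq_len(nrow(phy$edge)), function(e) {
    tips <- sort(below[[phy$edge[e, 2]]])
    side <- if (labs[1] %in% tips) tips else sort(setdiff(labs, tips))
    paste(side, collapse = "|")
  }, character(1))
}

#' Build the quadratic (approximate) likelihood surface for one partition
#'
#' Estimates MLE branch lengths on the unrooted topology, then the gradient
#' and Hessian there. The rooted tree's two root-adjacent branches map to a
#' single unrooted branch (their length contributions add), the standard
#' identifiability workaround under reversible models.
#'
#' @param aln Alignment for this partition.
#' @param rooted_topology The fixed rooted species topology (`phylo`).
#' @param sub A [substitution_params()].
#' @param ... Passed to [mle_branch_lengths()].
#' @return Object of class `approx_surface`: `b_hat`, `logl_hat`, `g`, `H`,
#'   `emap` (rooted edge -> unrooted branch index), `splits` (branch
#'   labels), `utree`, `sub`, `n_sites`.
#' @export
build_approx_surface <- function(aln, rooted_topology, sub, ...) {
  fit <- mle_branch_lengths(aln, rooted_topology, sub, ...)
  gh <- hessian_at_mle(aln, rooted_topology, sub, fit$b_hat)
  ukeys <- edge_split_keys(fit$tree)
  rkeys <- edge_split_keys(rooted_topology)
  emap <- match(rkeys, ukeys)
  if (anyNA(emap)) stop("failed to map rooted edges onto unrooted branches")
  structure(list(b_hat = fit$b_hat, logl_hat = fit$logl_hat, g = gh$g,
                 H = gh$H, emap = emap, splits = ukeys, utree = fit$tree,
                 sub = sub, n_sites = fit$n_sites),
            class = "approx_surface")
}

#' Approximate log likelihood from the quadratic surface
#'
#' Evaluates `logl_hat + g'(b - b_hat) + (b - b_hat)'H(b - b_hat)/2` where
#' `b` are unrooted branch lengths. Supply either `b` directly or node
#' `ages` plus branch `rates` (per rooted edge), from which
#' `b = duration x rate` is assembled through the branch index map.
#'
#' @param surf An `approx_surface`.
#' @param b Unrooted branch lengths (substitutions/site), or `NULL`.
#' @param ages Node ages (ape node order) of the rooted topology.
#' @param rates Branch rates per rooted edge.
#' @param rooted_topology The rooted `phylo` matching `surf$emap`.
#' @return Approximate log likelihood.
#' @export
approx_loglik <- function(surf, b = NULL, ages = NULL, rates = NULL,
                          rooted_topology = NULL) {
  if (is.null(b)) {
    if (is.null(ages) || is.null(rates) || is.null(rooted_topology))
      stop("supply either b or (ages, rates, rooted_topology)")
    dur <- ages[rooted_topology$edge[, 1]] - ages[rooted_topology$edge[, 2]]
    if (any(dur < 0)) stop("negative branch durations")
    br <- dur * rates
    b <- numeric(length(surf$b_hat))
    for (e in seq_along(br)) b[surf$emap[e]] <- b[surf$emap[e]] + br[e]
  }
  if (length(b) != length(surf$b_hat)) stop("branch-length dimension mismatch")
  d <- b - surf$b_hat
  as.numeric(surf$logl_hat + sum(surf$g * d) + 0.5 * crossprod(d, surf$H %*% d))
}

#' Serialize an approximate-likelihood surface to a text bundle
#'
#' Writes a version-stamped TSV bundle (branch map with `b_hat` and
#' gradient, then the Hessian row-major), analogous in role to the
#' branch-length/Hessian files consumed by approximate-likelihood dating
#' tools.
#'
#' @param surf An `approx_surface`.
#' @param file Output path.
#' @export
write_surface <- function(surf, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# clockdate approx_surface v1", con)
  writeLines(sprintf("# kappa=%.10g alpha=%.10g ncat=%d n_sites=%d logl_hat=%.10f",
                     surf$sub$kappa, surf$sub$gamma_shape,
                     surf$sub$n_categories, surf$n_sites, surf$logl_hat), con)
  writeLines(sprintf("# base_freqs=%s",
                     paste(sprintf("%.10g", surf$sub$base_freqs),
                           collapse = ",")), con)
  writeLines(sprintf("# newick=%s", ape::write.tree(surf$utree)), con)
  df <- data.frame(branch = seq_along(surf$b_hat), split = surf$splits,
                   b_hat = surf$b_hat, g = surf$g)
  writeLines("[branches]", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("[hessian]", con)
  utils::write.table(format(surf$H, digits = 12), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a surface bundle written by [write_surface()]
#' @param file Path.
#' @param rooted_topology Rooted topology used to rebuild the edge map.
#' @return An `approx_surface`.
#' @export
read_surface <- function(file, rooted_topology) {
  lines <- readLines(file)
  if (!grepl("approx_surface v1", lines[1])) stop("not a surface bundle")
  hdr <- strsplit(sub("^# ", "", lines[2]), " ")[[1]]
  getv <- function(k) as.numeric(sub(paste0(k, "="), "",
                                     hdr[grepl(paste0("^", k, "="), hdr)]))
  freqs <- as.numeric(strsplit(sub("^# base_freqs=", "", lines[3]), ",")[[1]])
  utree <- ape::read.tree(text = sub("^# newick=", "", lines[4]))
  ib <- which(lines == "[branches]")
  ih <- which(lines == "[hessian]")
  df <- utils::read.delim(text = paste(lines[(ib + 1):(ih - 1)],
                                       collapse = "\n"))
  H <- as.matrix(utils::read.delim(text = paste(lines[(ih + 1):length(lines)],
                                                collapse = "\n"),
                                   header = FALSE))
  dimnames(H) <- NULL
  sub <- substitution_params(kappa = getv("kappa"), base_freqs = freqs,
                             gamma_shape = getv("alpha"),
                             n_categories = as.integer(getv("ncat")))
  rkeys <- edge_split_keys(rooted_topology)
  emap <- match(rkeys, df$split)
  if (anyNA(emap)) stop("surface does not match the supplied topology")
  structure(list(b_hat = df$b_hat, logl_hat = getv("logl_hat"), g = df$g,
                 H = H, emap = emap, splits = df$split, utree = utree,
                 sub = sub, n_sites = as.integer(getv("n_sites"))),
            class = "approx_surface")
}
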