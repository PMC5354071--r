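# Tree utilities: ML pairwise distances + neighbour joining for a start
# tree, outgroup rooting, and majority-rule consensus. Trees are ape::phylo
# objects throughout; node supports live in node.label.

#' Neighbour-joining start tree from ML pairwise distances
#'
#' For each taxon pair a one-parameter maximum-likelihood distance under the
#' supplied model is fitted to the columns where both sequences are
#' unambiguous; the distance matrix is handed to neighbour joining and
#' negative NJ branch lengths are clamped to zero.
#'
#' @param aln A `partitioned_alignment` with at least 3 taxa.
#' @param model An `aa_model`.
#' @param max_distance Upper bound for the pairwise distance search.
#' @return Unrooted `phylo` tree.
#' @export
nj_start_tree <- function(aln, model, max_distance = 10) {
  enc <- encode_alignment(aln)
  states <- do.call(cbind, lapply(enc$parts, `[[`, "states"))
  wts <- unlist(lapply(enc$parts, `[[`, "weights"))
  n <- length(aln$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  logpi <- log(model$freqs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    si <- states[i, ]; sj <- states[j, ]
    ok <- si > 0L & sj > 0L
    if (!any(ok))
      stop(sprintf("no shared unambiguous columns between %s and %s",
                   aln$taxa[i], aln$taxa[j]))
    N <- matrix(0, 20L, 20L)
    idx <- cbind(si[ok], sj[ok])
    for (r in seq_len(nrow(idx))) N[idx[r, 1L], idx[r, 2L]] <- N[idx[r, 1L], idx[r, 2L]] + wts[ok][r]
    f <- function(d) {
      P <- transition_prob(model, d)
      sum(N * (logpi + log(P + 1e-300)))
    }
    D[i, j] <- D[j, i] <- stats::optimize(f, c(1e-8, max_distance),
                                          maximum = TRUE, tol = 1e-8)$maximum
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge; node
#' supports are carried across the rerooting.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_taxon Tip label to root on.
#' @return Rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_taxon) {
  if (!outgroup_taxon %in% tree$tip.label)
    stop(sprintf("outgroup '%s' not among tip labels", outgroup_taxon))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rt <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE,
                  edgelabel = TRUE)
  if (!is.null(rt$edge.length)) {
    tip <- match(outgroup_taxon, rt$tip.label)
    root_node <- length(rt$tip.label) + 1L
    e_out <- which(rt$edge[, 1L] == root_node & rt$edge[, 2L] == tip)
    e_in <- which(rt$edge[, 1L] == root_node & rt$edge[, 2L] != tip)
    if (length(e_out) == 1L && length(e_in) == 1L) {
      total <- rt$edge.length[e_out] + rt$edge.length[e_in]
      rt$edge.length[e_out] <- total / 2
      rt$edge.length[e_in] <- total / 2
    }
  }
  rt
}

#' Majority-rule consensus tree with posterior probabilities
#'
#' Builds the 50%-majority-rule consensus of a set of trees (for example the
#' post-burn-in MCMC sample) and labels each internal node with the
#' frequency of its bipartition in the input set, in `[0, 1]`.
#'
#' @param trees A `multiPhylo` list of trees on one leaf set.
#' @return `phylo` consensus tree; node labels are bipartition frequencies.
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  ref <- sort(trees[[1L]]$tip.label)
  for (t in trees) if (!identical(sort(t$tip.label), ref))
    stop("inconsistent leaf sets among trees")
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- formatC(counts / length(trees), digits = 3, format = "f")
  cons
}

# count how many trees contain each bipartition of `tree` (unrooted)
bipartition_counts <- function(tree, trees) {
  counts <- ape::prop.clades(tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  counts
}

#' Does an unrooted tree contain a given clade (bipartition)?
#' @param tree A `phylo` tree.
#' @param taxa Tip labels forming one side of the split.
#' @return TRUE if the split `taxa | rest` is an edge of the unrooted tree.
#' @export
has_clade <- function(tree, taxa) {
  tree <- ape::unroot(tree)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  target <- sort(match(taxa, labs))
  if (anyNA(target)) stop("clade taxa not all present in tree")
  comp <- sort(setdiff(seq_along(labs), target))
  for (p in bp) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Robinson-Foulds style topology identity for unrooted trees
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return TRUE if the unrooted topologies are identical.
#' @export
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1L] == 0
}
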