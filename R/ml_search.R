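# Maximum-likelihood tree search: round-robin branch-length optimisation on
# cached partials, nearest-neighbour-interchange hill climbing, per-gene rate
# multiplier estimation, and nonparametric bootstrap supports.

BL_MIN <- 1e-9
BL_MAX <- 10

#' Optimise branch lengths of a fixed topology
#'
#' Round-robin bounded scalar optimisation of every branch length using
#' cached inside/outside partial likelihoods; iterated until the
#' log-likelihood improves by less than `tol`.
#'
#' @param tree `phylo` tree with branch lengths (start values).
#' @param aln A `partitioned_alignment`.
#' @param model An `aa_model`.
#' @param rates Optional per-partition rate multipliers.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_rounds Maximum optimisation sweeps.
#' @return List with `tree` (updated branch lengths) and `lnl`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, rates = NULL,
                                    tol = 1e-6, max_rounds = 50) {
  enc <- encode_alignment(aln)
  res <- .opt_bl_tf(tree_eval_form(tree, enc$taxa), enc, model, rates,
                    tol = tol, max_rounds = max_rounds)
  list(tree = res$tf$phy, lnl = res$lnl)
}

.opt_bl_tf <- function(tf, enc, model, rates, tol = 1e-6, max_rounds = 50) {
  lnl <- lnl_tf(tf, enc, model, rates)
  for (round in seq_len(max_rounds)) {
    cache <- build_caches(tf, enc, model, rates)
    old_el <- tf$el
    new_el <- old_el
    for (e in seq_along(old_el)) {
      op <- stats::optimize(function(t) edge_lnl(cache, e, t),
                            c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-7)
      cur <- edge_lnl(cache, e, old_el[e])
      if (op$objective > cur) new_el[e] <- op$maximum
    }
    tf$el <- new_el
    tf$phy$edge.length <- new_el
    new_lnl <- lnl_tf(tf, enc, model, rates)
    # simultaneous updates can in principle overshoot; back off halfway
    tries <- 0L
    while (new_lnl < lnl && tries < 12L) {
      new_el <- (new_el + old_el) / 2
      tf$el <- new_el
      tf$phy$edge.length <- new_el
      new_lnl <- lnl_tf(tf, enc, model, rates)
      tries <- tries + 1L
    }
    if (new_lnl < lnl) {  # give up on this sweep
      tf$el <- old_el
      tf$phy$edge.length <- old_el
      break
    }
    improved <- new_lnl - lnl
    lnl <- new_lnl
    if (improved < tol) break
  }
  list(tf = tf, lnl = lnl)
}

# internal NNI machinery ------------------------------------------------------

# internal edges eligible for NNI in a postorder eval-form tree
internal_edges <- function(tf) {
  root <- tf$edge[nrow(tf$edge), 1L]
  which(tf$edge[, 2L] > tf$ntip)
}

# child edges per node for the current edge matrix
edges_by_parent <- function(tf) {
  ce <- vector("list", tf$ntip + tf$nnode)
  for (e in seq_len(nrow(tf$edge))) {
    p <- tf$edge[e, 1L]
    ce[[p]] <- c(ce[[p]], e)
  }
  ce
}

# evaluate both NNI candidates around internal edge e using cached partials;
# returns list of (which, lnl, t_opt) sorted as candidate 1, 2
nni_candidates <- function(cache, tf, e, ce) {
  p <- tf$edge[e, 1L]; v <- tf$edge[e, 2L]
  vkids <- ce[[v]]
  if (length(vkids) != 2L) return(NULL)
  sibs <- setdiff(ce[[p]], e)
  if (length(sibs) < 1L) return(NULL)
  s_edge <- sibs[1L]
  rest_edges <- sibs[-1L]
  out <- vector("list", 2L)
  for (cand in 1:2) {
    moved <- vkids[cand]        # child of v swapped up to p
    kept <- vkids[3L - cand]    # child of v that stays
    # per-partition pieces of the candidate likelihood, built once
    pieces <- lapply(seq_along(cache$parts), function(k) {
      cp <- cache$parts[[k]]
      sc <- tf$edge[s_edge, 2L]
      mc <- tf$edge[moved, 2L]
      kc <- tf$edge[kept, 2L]
      # rest of the tree seen at p, excluding s and v subtrees
      R <- cp$Up[[p]]; Rl <- cp$Ul[[p]]
      for (re in rest_edges) {
        rc <- tf$edge[re, 2L]
        R <- R * cp$C[[rc]]; Rl <- Rl + cp$Cl[[rc]]
      }
      A <- sweep(R * cp$C[[mc]], 2L, cache$model$freqs, `*`)
      B <- cp$C[[sc]] * cp$C[[kc]]
      Bl <- cp$Cl[[sc]] + cp$Cl[[kc]]
      list(A = A, Al = Rl + cp$Cl[[mc]], B = B, Bl = Bl, w = cp$weights)
    })
    g <- function(t) {
      tot <- 0
      for (k in seq_along(pieces)) {
        pc <- pieces[[k]]
        P <- transition_prob(cache$model, t * cache$rates[k])
        site <- log(rowSums((pc$A %*% P) * pc$B)) + pc$Al + pc$Bl
        tot <- tot + sum(pc$w * site)
      }
      tot
    }
    op <- stats::optimize(g, c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-7)
    out[[cand]] <- list(cand = cand, lnl = op$objective, t = op$maximum,
                        s_edge = s_edge, moved = moved, kept = kept, e = e)
  }
  out
}

# apply an accepted NNI: swap the children (and lengths) of s_edge and moved
apply_nni <- function(tf, nni) {
  edge <- tf$edge; el <- tf$el
  s_child <- edge[nni$s_edge, 2L]
  m_child <- edge[nni$moved, 2L]
  edge[nni$s_edge, 2L] <- m_child
  edge[nni$moved, 2L] <- s_child
  tmp <- el[nni$s_edge]; el[nni$s_edge] <- el[nni$moved]; el[nni$moved] <- tmp
  el[nni$e] <- nni$t
  phy <- tf$phy
  phy$edge <- edge
  phy$edge.length <- el
  phy <- ape::reorder.phylo(phy, "postorder")
  tree_eval_form(phy, phy$tip.label)
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Starting from a neighbour-joining tree (or a supplied start tree),
#' alternates full branch-length optimisation with evaluation of every
#' nearest-neighbour interchange; the best strictly improving rearrangement
#' is accepted each round (ties broken by first-encountered edge order),
#' until no rearrangement improves the likelihood or `max_rounds` is hit.
#' Deterministic given its inputs.
#'
#' @param aln A `partitioned_alignment` with >= 4 taxa.
#' @param model An `aa_model`.
#' @param start Optional start `phylo` tree (default [nj_start_tree()]).
#' @param rates Optional per-partition rate multipliers.
#' @param max_rounds Maximum accepted rearrangements.
#' @param bl_tol Branch-length optimisation tolerance.
#' @return List with `tree` (unrooted ML tree), `lnl`, and `n_moves`.
#' @export
ml_search <- function(aln, model, start = NULL, rates = NULL,
                      max_rounds = 50, bl_tol = 1e-6) {
  if (length(aln$taxa) < 4L) stop("need at least 4 taxa for tree search")
  enc <- encode_alignment(aln)
  if (is.null(start)) start <- nj_start_tree(aln, model)
  start$edge.length[start$edge.length < BL_MIN] <- BL_MIN
  res <- .opt_bl_tf(tree_eval_form(start, enc$taxa), enc, model, rates,
                    tol = bl_tol)
  tf <- res$tf; lnl <- res$lnl
  n_moves <- 0L
  for (round in seq_len(max_rounds)) {
    cache <- build_caches(tf, enc, model, rates)
    ce <- edges_by_parent(tf)
    best <- NULL
    for (e in internal_edges(tf)) {
      cands <- nni_candidates(cache, tf, e, ce)
      for (cd in cands) {
        if (!is.null(cd) && cd$lnl > lnl + 1e-9 &&
            (is.null(best) || cd$lnl > best$lnl)) best <- cd
      }
    }
    if (is.null(best)) break
    tf <- apply_nni(tf, best)
    res <- .opt_bl_tf(tf, enc, model, rates, tol = bl_tol)
    if (res$lnl < lnl) break  # safeguard: reject non-improving move
    tf <- res$tf; lnl <- res$lnl
    n_moves <- n_moves + 1L
  }
  list(tree = tf$phy, lnl = lnl, n_moves = n_moves)
}

#' Estimate per-partition rate multipliers
#'
#' Maximises the log-likelihood over each gene partition's rate multiplier
#' by bounded scalar optimisation on a fixed tree, then renormalises the
#' multipliers to mean 1. A partition with no unambiguous data keeps
#' multiplier 1 with a warning. A single partition returns 1 exactly.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param aln A `partitioned_alignment`.
#' @param model An `aa_model`.
#' @return Named numeric vector of multipliers (mean 1).
#' @export
estimate_partition_rates <- function(tree, aln, model) {
  enc <- encode_alignment(aln)
  genes <- vapply(enc$parts, `[[`, character(1), "gene")
  if (length(enc$parts) == 1L) return(stats::setNames(1, genes))
  tf <- tree_eval_form(tree, enc$taxa)
  r <- vapply(enc$parts, function(part) {
    if (all(part$states == 0L)) {
      warning(sprintf("partition %s has no unambiguous data; rate fixed to 1",
                      part$gene))
      return(NA_real_)
    }
    stats::optimize(function(lr) .part_lnl(tf, part, model, exp(lr)),
                    c(log(0.02), log(50)), maximum = TRUE, tol = 1e-6)$maximum
  }, numeric(1))
  r <- exp(r)
  fixed <- is.na(r)
  if (any(!fixed)) r[!fixed] <- r[!fixed] / mean(r[!fixed])
  r[fixed] <- 1
  stats::setNames(r, genes)
}

#' Nonparametric bootstrap support values
#'
#' Resamples alignment columns with replacement within each partition
#' (preserving partition sizes), reruns the ML search on every replicate
#' starting from the full-data ML tree, and reports for each internal edge
#' of the ML tree the percentage of replicates containing that bipartition.
#'
#' @param aln A `partitioned_alignment`.
#' @param model An `aa_model`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the run is reproducible given it.
#' @param ml_tree Optional precomputed ML tree (computed if missing).
#' @param rates Optional per-partition rate multipliers.
#' @param max_rounds NNI rounds per replicate search.
#' @return List with `tree` (ML tree, `node.label` = percent support),
#'   `supports` (per internal node), and `replicates` (`multiPhylo`).
#' @export
bootstrap_support <- function(aln, model, n_replicates = 1000, seed = 1,
                              ml_tree = NULL, rates = NULL, max_rounds = 10) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(ml_tree)) ml_tree <- ml_search(aln, model, rates = rates)$tree
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    mat <- aln$matrix
    for (k in seq_len(nrow(aln$partitions))) {
      cols <- aln$partitions$start[k]:aln$partitions$end[k]
      mat[, cols] <- aln$matrix[, sample(cols, length(cols), replace = TRUE)]
    }
    baln <- structure(list(taxa = aln$taxa, matrix = mat,
                           partitions = aln$partitions),
                      class = "partitioned_alignment")
    reps[[b]] <- ml_search(baln, model, start = ml_tree, rates = rates,
                           max_rounds = max_rounds)$tree
  }
  class(reps) <- "multiPhylo"
  counts <- bipartition_counts(ml_tree, reps)
  supports <- 100 * counts / n_replicates
  out <- ml_tree
  out$node.label <- formatC(supports, format = "f", digits = 1)
  list(tree = out, supports = supports, replicates = reps)
}
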