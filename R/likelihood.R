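# Partitioned amino-acid likelihood under a reversible model, computed by
# Felsenstein pruning with per-node scaling and site-pattern compression.
# X and "-" are treated as fully ambiguous states. Branch lengths of each
# partition are scaled by that partition's rate multiplier.

row_max <- function(M) pmax(M[cbind(seq_len(nrow(M)), max.col(M, "first"))], 1e-300)

# ---- alignment encoding ----------------------------------------------------

# integer-encode and pattern-compress each partition; 0 = ambiguous
encode_alignment <- function(aln) {
  validate_partitioned_alignment(aln)
  idx <- match(aln$matrix, AA20)
  idx[is.na(idx)] <- 0L
  dim(idx) <- dim(aln$matrix)
  rownames(idx) <- aln$taxa
  parts <- vector("list", nrow(aln$partitions))
  for (k in seq_len(nrow(aln$partitions))) {
    cols <- aln$partitions$start[k]:aln$partitions$end[k]
    sub <- idx[, cols, drop = FALSE]
    keys <- apply(sub, 2L, paste, collapse = ",")
    first <- !duplicated(keys)
    weights <- as.numeric(table(factor(keys, levels = keys[first])))
    parts[[k]] <- list(states = sub[, first, drop = FALSE],
                       weights = weights,
                       nsites = length(cols),
                       gene = aln$partitions$gene[k])
  }
  list(parts = parts, taxa = aln$taxa)
}

# internal tree representation for repeated likelihood evaluation
tree_eval_form <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa))
    stop("tree tip labels do not match alignment taxa")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, el = po$edge.length, ntip = length(po$tip.label),
       tip.label = po$tip.label, nnode = po$Nnode, phy = po)
}

# pruning log-likelihood for one partition given an eval-form tree
# (compiled kernel; .part_lnl_r is the pure-R reference implementation)
.part_lnl <- function(tf, part, model, rate) {
  states <- part$states
  if (!identical(rownames(states), tf$tip.label))
    states <- states[tf$tip.label, , drop = FALSE]
  prune_lnl_cpp(tf$edge, tf$el, tf$ntip, tf$nnode, states, part$weights,
                model$eig$V, model$eig$Vinv, model$eig$values,
                model$freqs, rate)
}

.part_lnl_r <- function(tf, part, model, rate) {
  states <- part$states
  if (!identical(rownames(states), tf$tip.label))
    states <- states[tf$tip.label, , drop = FALSE]
  npat <- ncol(states)
  nn <- tf$ntip + tf$nnode
  partial <- vector("list", nn)
  plog <- vector("list", nn)
  edge <- tf$edge
  el <- tf$el * rate
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    tP <- t.default(transition_prob(model, el[e]))
    if (ch <= tf$ntip) {
      s <- states[ch, ]
      C <- matrix(1, npat, 20L)
      known <- base::which(s > 0L)
      if (length(known)) C[known, ] <- tP[s[known], , drop = FALSE]
      Cl <- NULL
    } else {
      D <- partial[[ch]]
      m <- row_max(D)
      D <- D / m
      C <- D %*% tP
      Cl <- plog[[ch]] + log(m)
    }
    if (is.null(partial[[par]])) {
      partial[[par]] <- C
      plog[[par]] <- if (is.null(Cl)) numeric(npat) else Cl
    } else {
      partial[[par]] <- partial[[par]] * C
      if (!is.null(Cl)) plog[[par]] <- plog[[par]] + Cl
    }
  }
  root <- edge[nrow(edge), 1L]
  site <- log(as.vector(partial[[root]] %*% model$freqs)) + plog[[root]]
  sum(part$weights * site)
}

#' Partitioned log-likelihood of a tree
#'
#' Computes the pruning (Felsenstein) log-likelihood of an amino-acid
#' alignment on a tree, summed over gene partitions, with each partition's
#' branch lengths scaled by its rate multiplier. `X` and `-` contribute a
#' uniform partial-likelihood vector (fully missing).
#'
#' @param tree An `ape::phylo` tree whose tip labels equal the alignment
#'   taxa; branch lengths in expected substitutions per site.
#' @param aln A `partitioned_alignment`.
#' @param model An `aa_model`, e.g. [dayhoff_model()].
#' @param rates Optional numeric vector of per-partition rate multipliers
#'   (default all 1).
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(tree, aln, model, rates = NULL) {
  enc <- encode_alignment(aln)
  lnl_encoded(tree, enc, model, rates)
}

lnl_encoded <- function(tree, enc, model, rates = NULL) {
  tf <- tree_eval_form(tree, enc$taxa)
  lnl_tf(tf, enc, model, rates)
}

lnl_tf <- function(tf, enc, model, rates = NULL) {
  if (is.null(rates)) rates <- rep(1, length(enc$parts))
  stopifnot(length(rates) == length(enc$parts), all(rates > 0))
  tot <- 0
  for (k in seq_along(enc$parts))
    tot <- tot + .part_lnl(tf, enc$parts[[k]], model, rates[k])
  tot
}

# ---- cached partials for fast per-edge work --------------------------------
#
# For every edge (p, v) we cache, per partition:
#   D[v]  : conditional likelihood of the subtree below v, seen at v
#   C[v]  : D[v] propagated through v's edge to p
#   Out[v]: likelihood of everything outside subtree(v), seen at p
# so that  lnL(t_v) = sum_pat w * log( (pi .* Out[v]) %*% P(t) . D[v] )
# evaluates in a single small matrix product. Relies on model reversibility.

build_caches <- function(tf, enc, model, rates) {
  nparts <- length(enc$parts)
  if (is.null(rates)) rates <- rep(1, nparts)
  edge <- tf$edge
  nn <- tf$ntip + tf$nnode
  root <- edge[nrow(edge), 1L]
  caches <- vector("list", nparts)
  for (k in seq_len(nparts)) {
    part <- enc$parts[[k]]
    states <- part$states[tf$tip.label, , drop = FALSE]
    npat <- ncol(states)
    el <- tf$el * rates[k]
    P <- lapply(el, function(t) transition_prob(model, t))
    D <- vector("list", nn); Dl <- vector("list", nn)
    C <- vector("list", nn); Cl <- vector("list", nn)
    child_edges <- vector("list", nn)
    parent_edge <- integer(nn)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]; ch <- edge[e, 2L]
      parent_edge[ch] <- e
      child_edges[[par]] <- c(child_edges[[par]], e)
      if (ch <= tf$ntip) {
        s <- states[ch, ]
        Dv <- matrix(0, npat, 20L)
        known <- which(s > 0L)
        if (length(known)) Dv[cbind(known, s[known])] <- 1
        if (length(known) < npat) Dv[setdiff(seq_len(npat), known), ] <- 1
        Dlv <- numeric(npat)
      } else {
        Dv <- D[[ch]]; Dlv <- Dl[[ch]]
      }
      Cv <- Dv %*% t(P[[e]])
      m <- row_max(Cv)
      Cv <- Cv / m
      Clv <- Dlv + log(m)
      C[[ch]] <- Cv; Cl[[ch]] <- Clv
      D[[ch]] <- Dv; Dl[[ch]] <- Dlv
      if (is.null(D[[par]])) {
        D[[par]] <- Cv; Dl[[par]] <- Clv
      } else {
        D[[par]] <- D[[par]] * Cv; Dl[[par]] <- Dl[[par]] + Clv
      }
    }
    # preorder pass: Out/Up
    Out <- vector("list", nn); Ol <- vector("list", nn)
    Up <- vector("list", nn); Ul <- vector("list", nn)
    Up[[root]] <- matrix(1, npat, 20L); Ul[[root]] <- numeric(npat)
    for (e in rev(seq_len(nrow(edge)))) {
      par <- edge[e, 1L]; ch <- edge[e, 2L]
      sibs <- setdiff(child_edges[[par]], e)
      O <- Up[[par]]; Olg <- Ul[[par]]
      for (se in sibs) {
        sc <- edge[se, 2L]
        O <- O * C[[sc]]
        Olg <- Olg + Cl[[sc]]
      }
      m <- row_max(O)
      O <- O / m; Olg <- Olg + log(m)
      Out[[ch]] <- O; Ol[[ch]] <- Olg
      if (ch > tf$ntip) {
        Up[[ch]] <- O %*% t(P[[e]])
        Ul[[ch]] <- Olg
      }
    }
    caches[[k]] <- list(D = D, Dl = Dl, C = C, Cl = Cl, Out = Out, Ol = Ol,
                        Up = Up, Ul = Ul,
                        weights = part$weights, P = P,
                        child_edges = child_edges)
  }
  list(parts = caches, edge = edge, el = tf$el, root = root,
       ntip = tf$ntip, rates = rates, model = model)
}

# lnL as a function of one edge's length, all else cached
edge_lnl <- function(cache, e, t) {
  edge <- cache$edge
  ch <- edge[e, 2L]
  model <- cache$model
  tot <- 0
  for (k in seq_along(cache$parts)) {
    cp <- cache$parts[[k]]
    P <- transition_prob(model, t * cache$rates[k])
    A <- sweep(cp$Out[[ch]], 2L, model$freqs, `*`)
    site <- log(rowSums((A %*% P) * cp$D[[ch]])) + cp$Ol[[ch]] + cp$Dl[[ch]]
    tot <- tot + sum(cp$weights * site)
  }
  tot
}

# total cached lnL (any edge at its current length)
cache_lnl <- function(cache) edge_lnl(cache, 1L, cache$el[1L])
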