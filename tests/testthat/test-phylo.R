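model <- dayhoff_model()

test_that("the Dayhoff rate matrix satisfies the reversible-model contract", {
  Q <- model$Q
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_lt(max(abs(model$freqs * Q - t(model$freqs * Q))), 1e-12)  # balance
  expect_equal(sum(model$freqs), 1, tolerance = 1e-12)
  expect_equal(-sum(model$freqs * diag(Q)), 1, tolerance = 1e-9)   # scaling
  for (t in c(0, 0.01, 0.1, 1, 10)) {
    P <- transition_prob(model, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }
  expect_lt(max(abs(transition_prob(model, 0) - diag(20))), 1e-12)
  expect_error(transition_prob(model, -0.1), "negative")
})

test_that("pruning equals closed forms, brute force and an external engine", {
  # two identical single-residue taxa joined by zero branch length
  tr2 <- ape::read.tree(text = "(A:0,B:0);")
  a2 <- palaeoprot:::make_partitioned(c(A = "W", B = "W"))
  expect_equal(log_likelihood(tr2, a2, model),
               log(model$freqs[match("W", palaeoprot:::AA20)]),
               tolerance = 1e-12)

  # randomized tiny instances vs exhaustive state enumeration
  for (seed in 1:25) {
    cs <- random_tiny_case(seed)
    expect_lt(abs(log_likelihood(cs$tree, cs$aln, model) -
                    brute_force_lnl(cs$tree, cs$aln, model)), 1e-10)
  }

  # reversibility: re-rooting leaves the likelihood unchanged
  set.seed(5)
  tr <- ape::rtree(6)
  seqs <- stats::setNames(vapply(1:6, function(i)
    paste(sample(c(AAOK, "X"), 40, TRUE), collapse = ""), character(1)),
    tr$tip.label)
  aln <- palaeoprot:::make_partitioned(seqs)
  l0 <- log_likelihood(tr, aln, model)
  for (og in tr$tip.label[1:3])
    expect_equal(log_likelihood(root_with_outgroup(tr, og), aln, model), l0,
                 tolerance = 1e-8)

  # independent implementation: phangorn's pml on the same model
  pd <- phangorn::phyDat(t(vapply(strsplit(seqs, ""), identity,
                                  character(40))), type = "AA")
  expect_equal(l0, phangorn::pml(tr, pd, model = "Dayhoff")$logLik,
               tolerance = 1e-6)

  # the pure-R pruning and the compiled kernel agree
  enc <- palaeoprot:::encode_alignment(aln)
  tf <- palaeoprot:::tree_eval_form(tr, enc$taxa)
  expect_equal(palaeoprot:::.part_lnl(tf, enc$parts[[1]], model, 1.3),
               palaeoprot:::.part_lnl_r(tf, enc$parts[[1]], model, 1.3),
               tolerance = 1e-10)

  expect_error(log_likelihood(ape::rtree(5), aln, model), "match")
})

test_that("partition rate multipliers are recovered and normalised", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  g <- simulate_alignment(tr, model, c(g1 = 5000L, g2 = 5000L),
                          c(g1 = 0.5, g2 = 1.5), seed = 21)
  aln <- concatenate_partitions(list(gene_alignment("g1", g$g1),
                                     gene_alignment("g2", g$g2)))
  r <- estimate_partition_rates(ape::unroot(tr), aln, model)
  expect_equal(mean(r), 1, tolerance = 1e-6)
  expect_equal(unname(r / r[1]), c(1, 3), tolerance = 0.1 * 3)
  expect_lt(abs(r[["g1"]] / r[["g2"]] - 1 / 3), 0.1)

  # a single partition is pinned to 1; identical partitions tie
  one <- concatenate_partitions(list(gene_alignment("g1", g$g1)))
  expect_equal(unname(estimate_partition_rates(ape::unroot(tr), one, model)), 1)
  dup <- concatenate_partitions(list(gene_alignment("a", g$g1),
                                     gene_alignment("b", g$g1)))
  rd <- estimate_partition_rates(ape::unroot(tr), dup, model)
  expect_equal(unname(rd[1]), unname(rd[2]), tolerance = 1e-4)
})

test_that("NJ start trees behave on clean, degenerate and broken inputs", {
  # 3 taxa: the single unrooted topology
  a3 <- palaeoprot:::make_partitioned(c(A = "GANGKWEDF", B = "GANGKWEDF",
                                        C = "GVNGKWEDM"))
  t3 <- nj_start_tree(a3, model)
  expect_equal(ape::Ntip(t3), 3L)

  # identical sequences: all distances (and internal branches) collapse
  same <- palaeoprot:::make_partitioned(
    stats::setNames(rep("GANGKWEDFGHIKMNPQRST", 4), LETTERS[1:4]))
  ts <- nj_start_tree(same, model)
  expect_lt(sum(ts$edge.length), 1e-6)

  # simulated data: NJ recovers the generating split
  tr <- ape::read.tree(text = "((A:0.08,B:0.08):0.1,(C:0.08,D:0.08):0.1);")
  g <- simulate_alignment(tr, model, c(g = 2000L), seed = 31)
  aln <- concatenate_partitions(list(gene_alignment("g", g$g)))
  expect_true(same_topology(nj_start_tree(aln, model), tr))

  # a pair sharing no unambiguous columns is reported by name
  bad <- palaeoprot:::make_partitioned(c(A = "GAXX", B = "XXGA",
                                         C = "GAGA"))
  expect_error(nj_start_tree(bad, model), "A and B")
})

test_that("NNI hill climbing recovers the generating topology", {
  tr <- ape::read.tree(text = "((A:0.06,B:0.06):0.04,(C:0.06,D:0.06):0.04);")
  g <- simulate_alignment(tr, model, c(g = 2000L), seed = 41)
  aln <- concatenate_partitions(list(gene_alignment("g", g$g)))
  res <- ml_search(aln, model)
  expect_true(same_topology(res$tree, tr))
  # restarting from the optimum is a fixed point
  res2 <- ml_search(aln, model, start = res$tree)
  expect_true(same_topology(res2$tree, res$tree))
  expect_equal(res2$n_moves, 0L)
  expect_gte(res2$lnl, res$lnl - 1e-6)
  # branch-length optimisation alone never worsens the likelihood
  start <- nj_start_tree(aln, model)
  l_start <- log_likelihood(start, aln, model)
  ob <- optimize_branch_lengths(start, aln, model)
  expect_gte(ob$lnl, l_start)
  expect_error(ml_search(a3 <- palaeoprot:::make_partitioned(
    c(A = "GANGK", B = "GANGK", C = "GVNGK")), model), "4 taxa")
})

test_that("bootstrap supports are reproducible and count bipartitions", {
  tr <- ape::read.tree(text = "((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06);")
  g <- simulate_alignment(tr, model, c(g = 1500L), seed = 51)
  aln <- concatenate_partitions(list(gene_alignment("g", g$g)))
  ml <- ml_search(aln, model)
  b1 <- bootstrap_support(aln, model, n_replicates = 10, seed = 9,
                          ml_tree = ml$tree)
  b2 <- bootstrap_support(aln, model, n_replicates = 10, seed = 9,
                          ml_tree = ml$tree)
  expect_identical(b1$supports, b2$supports)
  # a clade present in every replicate scores 100%
  expect_true(all(b1$supports == 100))
  expect_error(bootstrap_support(aln, model, n_replicates = 0, seed = 1),
               ">= 1")
})

test_that("the MH rule, ESS estimator and trace bookkeeping are sound", {
  # equal posterior, symmetric kernel: accepted with probability 1
  expect_equal(palaeoprot:::.mh_alpha(-123.4, -123.4), 1)
  expect_lt(palaeoprot:::.mh_alpha(-124.4, -123.4), 1)

  set.seed(13)
  x <- stats::rnorm(1000)
  e <- ess(x)
  expect_gte(e, 800); expect_lte(e, 1200)
  expect_warning(ec <- ess(rep(1, 50)), "constant")
  expect_equal(ec, 1)
  expect_error(ess(stats::rnorm(5)), "at least 10")
  # strongly autocorrelated chains report much smaller ESS
  ar <- stats::filter(stats::rnorm(1000), 0.95, method = "recursive")
  expect_lt(ess(as.numeric(ar)), 300)

  st <- tiny_study()
  aln <- concatenate_partitions(lapply(names(st$gene_seqs), function(g)
    gene_alignment(g, st$gene_seqs[[g]])))
  tr <- mcmc_sample(aln, model, generations = 5000, sample_interval = 500,
                    seed = 2)
  expect_length(tr$lnl, 5000 / 500 + 1)
  expect_equal(tr$generation[1L], 0L)
  tr_b <- discard_burnin(tr)
  expect_length(tr_b$lnl, 10L)
  # determinism
  tr2 <- mcmc_sample(aln, model, generations = 5000, sample_interval = 500,
                     seed = 2)
  expect_identical(tr$lnl, tr2$lnl)
  expect_error(mcmc_sample(aln, model, generations = 5300,
                           sample_interval = 500, seed = 1), "multiple")
  expect_error(mcmc_sample(aln, model, generations = 5000,
                           sample_interval = 500, burn_in_fraction = 1.5,
                           seed = 1), "burn_in")
})

test_that("majority consensus and outgroup rooting follow the conventions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  trees <- c(rep(list(t1), 6), rep(list(t2), 4))
  class(trees) <- "multiPhylo"
  cons <- majority_consensus(trees)
  # the contested clade carries its 0.6 frequency; sub-majority splits absent
  expect_true(has_clade(cons, c("A", "B")))
  expect_false(has_clade(cons, c("A", "C")))
  expect_true("0.600" %in% cons$node.label)
  same <- majority_consensus(c(rep(list(t1), 5)))
  expect_true(same_topology(same, t1))
  expect_true(all(setdiff(same$node.label, "") %in% c("1.000")))
  expect_error(majority_consensus(list(t1, ape::rtree(5))), "leaf sets")

  tru <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):1);")
  rt <- root_with_outgroup(ape::unroot(tru), "D")
  expect_true(ape::is.rooted(rt))
  # D pendant edge split at its midpoint around the root
  root_node <- ape::Ntip(rt) + 1L
  kids <- rt$edge[rt$edge[, 1] == root_node, 2]
  expect_true(match("D", rt$tip.label) %in% kids)
  el <- rt$edge.length[rt$edge[, 1] == root_node]
  expect_equal(el[1], el[2])
  # rooting twice is a fixed point topologically
  expect_true(same_topology(root_with_outgroup(rt, "D"), rt))
  expect_error(root_with_outgroup(tru, "Z"), "Z")
})
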