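# Shared fixtures and independent oracles, built in code at test time.

AAOK <- setdiff(palaeoprot:::AA20, "L")  # letters legal in collapsed space

# write a proteome FASTA (+ optional telopeptide side-table) to tempfiles
write_test_proteome <- function(seqs, contaminants = character(),
                                telo = NULL) {
  fa <- tempfile(fileext = ".fasta")
  hdr <- vapply(names(seqs), function(a)
    paste0(">", a, " gene=", a,
           if (a %in% contaminants) " contaminant=1" else ""), character(1))
  writeLines(as.vector(rbind(hdr, unname(seqs))), fa)
  tt <- NULL
  if (!is.null(telo)) {
    tt <- tempfile(fileext = ".tsv")
    utils::write.table(telo, tt, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(fasta = fa, telo = tt)
}

# minimal PSM data.frame with sensible defaults
make_psms <- function(peptide, mods = "", accession = "P1", sample_id = "S1",
                      score = 50, alc = NA_real_, is_decoy = FALSE,
                      is_de_novo = FALSE, spectrum_id = NULL) {
  n <- length(peptide)
  if (is.null(spectrum_id)) spectrum_id <- sprintf("SP%04d", seq_len(n))
  data.frame(spectrum_id = spectrum_id, sample_id = rep_len(sample_id, n),
             peptide = peptide, mods = rep_len(mods, n),
             protein_accession = rep_len(accession, n),
             psm_score = rep_len(score, n), alc = rep_len(alc, n),
             is_decoy = rep_len(is_decoy, n),
             is_de_novo = rep_len(is_de_novo, n), stringsAsFactors = FALSE)
}

# brute-force target-decoy FDR: for every distinct score threshold count
# decoys/targets at or above it, take the minimum achievable at or below
# each PSM's score (q-value), independent of the implementation's sort
brute_force_retained <- function(score, is_decoy, threshold) {
  q <- vapply(seq_along(score), function(i) {
    cand <- unique(score[score <= score[i]])
    min(vapply(cand, function(s) {
      dec <- sum(is_decoy & score >= s)
      tar <- sum(!is_decoy & score >= s)
      if (tar == 0L) Inf else dec / tar
    }, numeric(1)))
  }, numeric(1))
  q <= threshold
}

# brute-force likelihood by enumerating all internal-node state assignments
brute_force_lnl <- function(tree, aln, model, rate = 1) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  idx <- match(aln$matrix, palaeoprot:::AA20)
  idx[is.na(idx)] <- 0L
  dim(idx) <- dim(aln$matrix)
  rownames(idx) <- rownames(aln$matrix)
  idx <- idx[po$tip.label, , drop = FALSE]
  nint <- po$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  P <- lapply(po$edge.length * rate, function(t) transition_prob(model, t))
  total <- 0
  for (site in seq_len(ncol(idx))) {
    s <- 0
    grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
    for (g in seq_len(nrow(grid))) {
      assign_int <- grid[g, ]
      state_of <- function(node) {
        if (node <= ntip) idx[node, site] else assign_int[node - ntip]
      }
      p <- model$freqs[state_of(root)]
      if (state_of(root) == 0L) next
      for (e in seq_len(nrow(po$edge))) {
        a <- state_of(po$edge[e, 1L]); b <- state_of(po$edge[e, 2L])
        p <- p * if (b == 0L) 1 else P[[e]][a, b]
      }
      s <- s + p
    }
    total <- total + log(s)
  }
  total
}

# random collapsed-space alignment on a random tree (for oracle trials)
random_tiny_case <- function(seed) {
  set.seed(seed)
  ntaxa <- sample(3:4, 1)
  nsites <- sample(1:3, 1)
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 0.8)
  seqs <- stats::setNames(vapply(seq_len(ntaxa), function(i)
    paste(sample(c(AAOK, "X"), nsites, TRUE,
                 prob = c(rep(1, 19), 0.5)), collapse = ""), character(1)),
    tr$tip.label)
  list(tree = tr, aln = palaeoprot:::make_partitioned(seqs))
}

# the packaged 12-taxon study, built once per test run
rhino_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- make_study("rhino12", seed = 1)
    st
  }
})

tiny_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- make_study("tiny4", seed = 1)
    st
  }
})

# run one sample's PSMs through filtering, grouping and deamidation
authenticate_sample <- function(psms, proteome, seed) {
  f <- filter_psms(psms)
  g <- group_proteins(f, proteome)
  sm <- deamidation_summaries(g, proteome)
  el <- sm[sm$eligible, , drop = FALSE]
  fit <- fit_mixture_1d(el$frequency, seed = seed)
  sm[sm$eligible, ] <- assign_membership(el, fit)
  list(summaries = sm, fit = fit)
}
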