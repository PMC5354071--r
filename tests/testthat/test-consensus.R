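test_that("peptide placement finds unique best positions in collapsed space", {
  ref <- "GPAGKPAGERGAPGPIGKGANGK"
  pr <- write_test_proteome(c(P1 = ref))
  proteome <- read_fasta_proteome(pr$fasta)

  # exact match
  pl <- place_peptides(make_psms("PAGER"), proteome)
  expect_equal(pl$start, 6L)
  expect_equal(pl$n_mismatches, 0L)
  expect_false(pl$ambiguous)
  expect_equal(nrow(pl$substitutions[[1L]]), 0L)

  # one mismatch, unique placement; brute-force scan confirms uniqueness
  pl2 <- place_peptides(make_psms("PAGEK"), proteome)
  expect_equal(pl2$start, 6L)
  expect_equal(pl2$n_mismatches, 1L)
  subs <- pl2$substitutions[[1L]]
  expect_equal(subs$ref_pos, 10L)
  expect_equal(subs$ref_aa, "R"); expect_equal(subs$obs_aa, "K")
  rc <- strsplit(ref, "")[[1L]]
  mm <- vapply(seq_len(nchar(ref) - 4L), function(o)
    sum(rc[o:(o + 4L)] != strsplit("PAGEK", "")[[1L]]), integer(1))
  expect_equal(sum(mm <= 1L), 1L)

  # repeated motif -> ambiguous
  pl3 <- place_peptides(make_psms("PAG"), proteome)
  expect_true(pl3$ambiguous)

  # I/L collapse: an L-containing peptide matches the reference I exactly
  pl4 <- place_peptides(make_psms("GPLGK"), proteome)
  expect_equal(pl4$n_mismatches, 0L)
  expect_equal(pl4$start, 14L)

  # peptide longer than the protein: warning, no placement
  expect_warning(pl5 <- place_peptides(
    make_psms(strrep("GA", 20)), proteome), "longer")
  expect_equal(nrow(pl5), 0L)
})

test_that("consensus calling uses spectral majority with the SAAV threshold", {
  ref <- "GANGKWEDFR"
  pr <- write_test_proteome(c(P1 = ref))
  proteome <- read_fasta_proteome(pr$fasta)
  entry <- proteome$entries$P1

  # one peptide covering 1-5 exactly -> first half called, rest X
  pl <- place_peptides(make_psms("GANGK"), proteome)
  cs <- build_consensus(pl, entry, "S1", "P1")
  expect_equal(cs$sequence, "GANGKXXXXX")
  expect_equal(cs$coverage_fraction, 0.5)
  expect_equal(unname(cs$depth[1:5]), rep(1, 5))

  # 3 spectra reading V vs reference A at position 2 -> SAAV called
  pl2 <- place_peptides(make_psms(rep("GVNGK", 3)), proteome)
  cs2 <- build_consensus(pl2, entry, "S1", "P1")
  expect_equal(substr(cs2$sequence, 2, 2), "V")
  expect_equal(cs2$saavs$ref_pos, 2L)
  expect_equal(cs2$saavs$n_spectra, 3L)

  # single supporting spectrum -> reference retained, variant logged
  pl3 <- place_peptides(rbind(make_psms("GVNGK"),
                              make_psms("GANGK", spectrum_id = "SPX")),
                        proteome)
  # tie 1:1 at position 2 -> X (no reference fill)
  cs3 <- build_consensus(pl3, entry, "S1", "P1")
  expect_equal(substr(cs3$sequence, 2, 2), "X")
  pl4 <- place_peptides(make_psms("GVNGK"), proteome)
  cs4 <- build_consensus(pl4, entry, "S1", "P1")
  expect_equal(substr(cs4$sequence, 2, 2), "A")
  expect_equal(cs4$low_support$obs_aa, "V")

  # input order never matters
  set.seed(1)
  cs5 <- build_consensus(pl3[sample(nrow(pl3)), ], entry, "S1", "P1")
  expect_equal(cs5$sequence, cs3$sequence)

  # placements from two proteins are refused
  pl_mix <- pl3
  pl_mix$accession[1L] <- "OTHER"
  expect_error(build_consensus(pl_mix, entry, "S1", "P1"), "multiple")

  # no consensus letter can be L
  expect_false(grepl("L", cs2$sequence))
})

test_that("coverage report computes COL1 coverage outside telopeptides", {
  mk <- function(sid, gene, seq, telo = NULL) {
    structure(list(sample_id = sid, gene_symbol = gene, sequence = seq,
                   depth = rep(1, nchar(seq)),
                   coverage_fraction = mean(strsplit(seq, "")[[1L]] != "X"),
                   saavs = data.frame(), low_support = data.frame(),
                   telopeptides = palaeoprot:::as_ranges(telo)),
              class = "consensus_sequence")
  }
  # 303 of 1000 positions called -> 30.3% and a low-coverage flag
  seq303 <- paste0(strrep("G", 303), strrep("X", 697))
  expect_warning(
    rep1 <- coverage_report(list(mk("SCH2", "COL1A1", seq303))), "SCH2")
  expect_equal(rep1$col1$col1_coverage, 0.303)
  expect_true(rep1$col1$flagged)

  # full-length match -> 100%, telopeptides excluded from the basis
  full <- mk("S1", "COL1A1", strrep("G", 100),
             telo = data.frame(start = c(1, 91), end = c(10, 100)))
  rep2 <- coverage_report(list(full))
  expect_equal(rep2$col1$col1_length, 80L)
  expect_equal(rep2$col1$col1_coverage, 1)

  # all-X consensus -> 0%
  expect_warning(rep3 <- coverage_report(list(mk("S1", "COL1A2",
                                                 strrep("X", 50)))))
  expect_equal(rep3$col1$col1_coverage, 0)
})

test_that("consensus round-trip recovers the derived sequence and SAAVs", {
  st <- tiny_study()
  sid <- st$config$samples$sample_id[1L]
  f <- filter_psms(st$psms[[sid]])
  g <- group_proteins(f, st$proteome)
  for (gene in names(st$config$gene_lengths)) {
    acc <- paste0("REF_", gene)
    rows <- which(g$accession == acc & g$status == "accepted")
    expect_true(length(rows) == 1L)
    pl <- place_peptides(g$psm_rows[[rows]], st$proteome)
    pl <- pl[pl$accession == acc, , drop = FALSE]
    cs <- build_consensus(pl, st$proteome$entries[[acc]], sid, gene)
    truth <- collapse_isobaric(st$derived[[sid]][[gene]])
    got <- strsplit(cs$sequence, "")[[1L]]
    want <- strsplit(truth, "")[[1L]]
    deep <- cs$depth >= 2
    # every position with >= 2 supporting spectra matches the true sequence
    expect_true(all(got[deep] == want[deep]))
    # SAAV calls are true substitutions; well-covered substitutions called
    ref <- strsplit(collapse_isobaric(
      st$proteome$entries[[acc]]$sequence), "")[[1L]]
    true_subs <- which(want != ref)
    if (nrow(cs$saavs)) expect_true(all(cs$saavs$ref_pos %in% true_subs))
    called_deep <- intersect(true_subs, which(deep))
    expect_true(all(called_deep %in% c(cs$saavs$ref_pos)))
  }
})
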