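test_that("proteome FASTA parsing, telopeptide merge and validation", {
  pr <- write_test_proteome(
    c(COL1A1 = "GPAGKPAGERGAPGPAG", KRT1 = "ACDEFGHIK"),
    contaminants = "KRT1",
    telo = data.frame(accession = "COL1A1", start = 1, end = 4))
  p <- read_fasta_proteome(pr$fasta, pr$telo)
  expect_length(p$entries, 2L)
  expect_true(p$entries$KRT1$is_contaminant)
  expect_false(p$entries$COL1A1$is_contaminant)
  expect_equal(p$entries$COL1A1$telopeptides,
               data.frame(start = 1L, end = 4L))
  expect_equal(nrow(p$entries$KRT1$telopeptides), 0L)

  # interval beyond the sequence end is rejected
  bad <- write_test_proteome(c(A1 = "ACDEF"),
                             telo = data.frame(accession = "A1",
                                               start = 2, end = 9))
  expect_error(read_fasta_proteome(bad$fasta, bad$telo), "out of bounds")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">A1", "ACDEF", ">A1", "GHIKM"), dup)
  expect_error(read_fasta_proteome(dup), "duplicate accession")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta_proteome(empty))

  # round trip through the writer
  out <- tempfile(fileext = ".fasta")
  write_proteome_fasta(p, out)
  p2 <- read_fasta_proteome(out)
  expect_equal(p2$entries$COL1A1$sequence, p$entries$COL1A1$sequence)
  expect_true(p2$entries$KRT1$is_contaminant)
})

test_that("PSM table parsing validates modification strings per row", {
  tab <- make_psms(c("GANGK", "GANGK", "GANGK"),
                   mods = c("deamidation-N@3", "deamidation-Q@3", ""))
  f <- tempfile(fileext = ".tsv")
  write_psm_table(tab, f)
  expect_warning(got <- read_psm_table(f), "row")
  expect_equal(nrow(got), 2L)  # the deamidation-Q on an N is rejected
  expect_warning(read_psm_table(f), "2")

  m <- palaeoprot:::parse_mods("deamidation-N@3;oxidation-M@1", "MANGK")
  expect_equal(m$position, c(3L, 1L))
  expect_error(palaeoprot:::parse_mods(paste(rep("deamidation-N@3", 7),
                                             collapse = ";"), "GANGK"),
               "six")

  # header-only table
  f2 <- tempfile(fileext = ".tsv")
  write_psm_table(tab[0, ], f2)
  expect_equal(nrow(read_psm_table(f2)), 0L)

  # missing column
  f3 <- tempfile(fileext = ".tsv")
  utils::write.table(tab[, -3], f3, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(read_psm_table(f3), "peptide")
})

test_that("target-decoy filtering matches brute-force FDR counting", {
  # deterministic example: 100 targets all scoring above 100 decoys
  ps <- rbind(make_psms(rep("PEPTIDEK", 100), score = 100 + 1:100),
              make_psms(rep("KEDITPEP", 100), score = 1:100,
                        is_decoy = TRUE, spectrum_id = sprintf("D%03d", 1:100)))
  kept <- filter_psms(ps, fdr_threshold = 0.01)
  expect_equal(sum(!kept$is_decoy), 100L)

  # randomized property: retained targets equal brute-force q <= threshold
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    sc <- round(stats::rnorm(n, 50, 15), sample(0:1, 1))  # ties likely
    dec <- stats::runif(n) < 0.4
    q <- psm_qvalues(sc, dec)
    expect_true(all(diff(q[order(sc, decreasing = TRUE)]) >= -1e-12))
    for (thr in c(0.01, 0.05, 0.2)) {
      expect_equal(q <= thr, brute_force_retained(sc, dec, thr),
                   info = sprintf("seed %d thr %.2f", seed, thr))
    }
  }
})

test_that("filtering is idempotent, honours the ALC boundary, needs decoys", {
  # a decoy that passes the 1% FDR (one decoy under 100 better targets)
  ps <- rbind(make_psms(rep("PEPTIDEK", 120), score = c(101:200, 1:20)),
              make_psms("KEDITPEP", score = 100.5, is_decoy = TRUE,
                        spectrum_id = "D001"),
              make_psms(c("AAAGGGKR", "CCCGGGKR"), is_de_novo = TRUE,
                        alc = c(50, 49), score = NA,
                        spectrum_id = c("N1", "N2")))
  f1 <- filter_psms(ps)
  expect_true("D001" %in% f1$spectrum_id)  # passing decoys are retained
  f2 <- filter_psms(f1)
  expect_equal(f1[names(f1) != "row.names"], f2[names(f2) != "row.names"],
               ignore_attr = TRUE)
  # ALC 50 inclusive, 49 excluded
  expect_true("N1" %in% f1$spectrum_id)
  expect_false("N2" %in% f1$spectrum_id)
  expect_equal(attr(f1, "manual_inspection")$spectrum_id, "N1")

  expect_error(filter_psms(make_psms("PEPTIDEK")), "decoy")
  expect_equal(nrow(filter_psms(ps[0, ])), 0L)
})

test_that("protein grouping enforces unique-peptide and score rules", {
  pr <- write_test_proteome(c(P1 = "GANGKPEPTIDEKAAAGGGKR"))
  proteome <- read_fasta_proteome(pr$fasta)
  # two unique peptides at exactly score 20 -> accepted
  g <- group_proteins(make_psms(c("GANGK", "PEPTIDEK"), score = 20),
                      proteome)
  expect_equal(g$status, "accepted")
  expect_equal(g$n_unique_peptides, 2L)
  # I/L collapse: PEPTLDEK and PEPTIDEK are one peptide
  g2 <- group_proteins(make_psms(c("PEPTLDEK", "PEPTIDEK", "PEPTIDEK")),
                       proteome)
  expect_equal(g2$n_unique_peptides, 1L)
  expect_equal(g2$status, "rejected")
  # score below 20 rejected even with 2 unique peptides
  g3 <- group_proteins(make_psms(c("GANGK", "PEPTIDEK"), score = 19.9),
                       proteome)
  expect_equal(g3$status, "rejected")
  # precomputed protein score wins over max PSM score
  g4 <- group_proteins(make_psms(c("GANGK", "PEPTIDEK"), score = 5), proteome,
                       protein_scores = data.frame(sample_id = "S1",
                                                   accession = "P1",
                                                   score = 25))
  expect_equal(g4$status, "accepted")
  expect_equal(nrow(group_proteins(make_psms(character(0)), proteome)), 0L)
  # PSM conservation: every PSM lands in exactly one (sample, accession) group
  ps <- rbind(make_psms(c("GANGK", "PEPTIDEK"), sample_id = "S1"),
              make_psms("GANGK", sample_id = "S2", spectrum_id = "SP9"))
  g5 <- group_proteins(ps, proteome)
  expect_equal(sum(vapply(g5$psm_rows, nrow, integer(1))), nrow(ps))
  expect_warning(group_proteins(make_psms("GANGK", accession = "NOPE"),
                                proteome), "NOPE")
})

test_that("contaminant flagging uses blank and catalogue, keeps PSM content", {
  pr <- write_test_proteome(c(COL1A1 = "GANGKPEPTIDEKR",
                              TRYP = "AAAGGGKRCCCGGGKR"),
                            contaminants = "TRYP")
  proteome <- read_fasta_proteome(pr$fasta)
  groups <- group_proteins(rbind(make_psms(c("GANGK", "PEPTIDEK"),
                                           accession = "COL1A1"),
                                 make_psms(c("AAAGGGK", "CCCGGGK"),
                                           accession = "TRYP",
                                           spectrum_id = c("T1", "T2"))),
                           proteome)
  blank <- group_proteins(make_psms(c("AAAGGGK", "CCCGGGK"),
                                    accession = "TRYP", sample_id = "BLANK"),
                          proteome)
  out <- remove_contaminants(groups, blank, character(), proteome)
  expect_equal(out$status[out$accession == "TRYP"], "contaminant")
  expect_equal(out$status[out$accession == "COL1A1"], "accepted")
  # PSM content untouched
  expect_identical(out$psm_rows, groups$psm_rows)
  # empty blank: catalogue only
  out2 <- remove_contaminants(groups, NULL, c("TRYP"), proteome)
  expect_equal(out2$status[out2$accession == "TRYP"], "contaminant")
  out3 <- remove_contaminants(groups, NULL, character(), proteome)
  expect_false(any(out3$status == "contaminant"))
})
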