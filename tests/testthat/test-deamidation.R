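test_that("deamidation frequency counts spectra over reference Q/N sites", {
  pr <- write_test_proteome(c(P1 = "GANGKGQNGKWEDFGK"))
  proteome <- read_fasta_proteome(pr$fasta)
  # 4 spectra covering Q/N sites, 3 with a deamidation mod -> 0.75;
  # one extra spectrum on a Q/N-free peptide stays out of the denominator
  ps <- rbind(make_psms(rep("GANGK", 2), mods = "deamidation-N@3"),
              make_psms("GQNGK", mods = "deamidation-Q@2",
                        spectrum_id = "SP10"),
              make_psms("GQNGK", spectrum_id = "SP11"),
              make_psms("WEDFGK", spectrum_id = "SP12"))
  g <- group_proteins(ps, proteome, min_unique = 1)
  sm <- deamidation_frequency(g[1, ], proteome)
  expect_equal(sm$n_spectra_covering_QN, 4L)
  expect_equal(sm$n_spectra_with_deamidation, 3L)
  expect_equal(sm$frequency, 0.75)
  expect_equal(sm$n_distinct_QN_positions, 3L)  # N3 and Q7/N8
  expect_true(sm$eligible)
  expect_false(sm$fully_deamidated_flag)

  # all covering spectra deamidated -> frequency 1 and the audit flag
  ps2 <- make_psms(rep("GANGK", 3), mods = "deamidation-N@3")
  g2 <- group_proteins(ps2, proteome, min_unique = 1)
  sm2 <- deamidation_frequency(g2[1, ], proteome)
  expect_equal(sm2$frequency, 1)
  expect_true(sm2$fully_deamidated_flag)
  # only 1 distinct Q/N position covered -> ineligible at the default 3
  expect_false(sm2$eligible)

  # duplicated spectrum rows are collapsed before counting
  sm3 <- deamidation_frequency(
    group_proteins(rbind(ps2, ps2), proteome, min_unique = 1)[1, ], proteome)
  expect_equal(sm3$n_spectra_covering_QN, 3L)
})

test_that("EM mixture fitting separates two known components", {
  set.seed(99)
  vals <- c(stats::rnorm(20, 0.10, 0.03), stats::rnorm(20, 0.85, 0.05))
  truth <- rep(1:2, each = 20)
  fit <- fit_mixture_1d(vals, seed = 42)
  expect_equal(fit$k, 2L)
  ord <- order(fit$means)
  assign <- ord[max.col(fit$responsibilities)]
  expect_equal(assign, truth)
  # EM log-likelihood is non-decreasing along the trace
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_true(is.finite(fit$bic))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # cross-check against mclust (the reference model-based clustering tool)
  suppressMessages(library(mclust))
  mc <- mclust::Mclust(vals, G = 1:3, verbose = FALSE)
  expect_equal(mc$G, 2L)
  expect_equal(unname(mc$classification), assign)

  # degenerate and error cases
  same <- fit_mixture_1d(rep(0.5, 10), seed = 1)
  expect_equal(same$k, 1L)
  expect_equal(same$variances[1L], 1e-4)  # clamped to the floor
  expect_error(fit_mixture_1d(c(0.1, 0.9), seed = 1), "at least 3")
})

test_that("membership labels follow the larger-mean rule, permutation-stably", {
  sm <- data.frame(sample_id = "S1",
                   accession = c("CSN2", "CSN1S1", "COL1A1", "COL1A2", "AHSG"),
                   frequency = c(0.05, 0.12, 0.88, 0.91, 0.80),
                   eligible = TRUE, cluster_label = "unassigned",
                   stringsAsFactors = FALSE)
  fit <- fit_mixture_1d(sm$frequency, seed = 7)
  out <- assign_membership(sm, fit)
  expect_equal(out$cluster_label,
               c("contaminant", "contaminant", "endogenous", "endogenous",
                 "endogenous"))
  # permuting the fitted components must not change the calls
  perm <- fit
  p <- rev(seq_len(fit$k))
  perm$means <- fit$means[p]; perm$weights <- fit$weights[p]
  perm$variances <- fit$variances[p]
  perm$responsibilities <- fit$responsibilities[, p, drop = FALSE]
  expect_equal(assign_membership(sm, perm)$cluster_label, out$cluster_label)

  # k = 1: threshold rule plus a warning
  sm_hi <- sm
  sm_hi$frequency <- 0.9 + seq(-0.01, 0.01, length.out = 5)
  one <- fit_mixture_1d(sm_hi$frequency, k_candidates = 1, seed = 1)
  expect_warning(lab1 <- assign_membership(sm_hi, one), "single")
  expect_true(all(lab1$cluster_label == "endogenous"))

  # ineligible rows stay unassigned; empty eligible set passes through
  sm2 <- sm; sm2$eligible <- FALSE
  expect_equal(assign_membership(sm2, fit)$cluster_label,
               rep("unassigned", 5))
})

test_that("paired sample comparison applies the shared-peptide rule", {
  sm <- data.frame(
    sample_id = rep(c("OLD", "YOUNG"), each = 3),
    accession = c("A", "B", "C", "A", "B", "D"),
    frequency = c(0.9, 0.8, 0.7, 0.7, 0.75, 0.5),
    n_QN_peptides = c(4, 1, 3, 5, 2, 4),
    stringsAsFactors = FALSE)
  cmp <- compare_samples(sm, c("OLD", "YOUNG"))
  # B fails the rule in OLD (1 peptide); C and D are present in one sample
  expect_equal(cmp$accession, "A")
  expect_equal(cmp$difference, 0.2, tolerance = 1e-12)
  expect_error(compare_samples(sm[sm$sample_id == "OLD", ]), "two samples")
})

test_that("well-separated mixtures are recovered across many replicates", {
  # components 4+ sigma apart, 15 points each
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    vals <- c(stats::rnorm(15, 0.2, 0.05), stats::rnorm(15, 0.8, 0.05))
    fit <- fit_mixture_1d(vals, n_restarts = 4, seed = seed)
    if (fit$k >= 2L) {
      lab <- max.col(fit$responsibilities)
      hi <- which.max(fit$means)
      pred <- lab == hi
      hits <- hits + sum(pred == rep(c(FALSE, TRUE), each = 15))
    }
  }
  expect_gte(hits / (100 * 30), 0.95)
})
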