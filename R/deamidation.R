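# Deamidation-based authentication: per-protein spectral deamidation
# frequencies, eligibility, univariate Gaussian-mixture clustering with BIC
# model selection, endogenous/contaminant membership assignment, and the
# paired two-sample comparison.
#
# Counting is spectrum-level and binary: a spectrum either contains at least
# one deamidated Q/N or it does not, and it enters the denominator as soon
# as its peptide spans at least one reference Q/N site. Spectra are
# deduplicated by spectrum_id before counting.

#' Per-protein spectral deamidation summary
#'
#' For one protein group: the deamidation frequency is the number of spectra
#' containing a deamidated Gln/Asn divided by the number of spectra whose
#' peptide covers at least one reference Gln/Asn position (deamidated or
#' not). Proteins covering fewer than `min_positions` distinct reference Q/N
#' sites are ineligible for cluster analysis. A frequency of exactly 1 sets
#' `fully_deamidated_flag` — such sites are interpreted as completely
#' deamidated residues rather than Glu/Asp substitutions, and the flag is
#' surfaced so users can audit them.
#'
#' @param group One row of [group_proteins()] output (with `psm_rows`).
#' @param proteome A `reference_proteome`.
#' @param min_positions Minimum distinct covered Q/N sites (default 3).
#' @return One-row data.frame (`deamidation_summary` fields).
#' @export
deamidation_frequency <- function(group, proteome, min_positions = 3) {
  psms <- group$psm_rows[[1L]]
  psms <- psms[!duplicated(psms$spectrum_id), , drop = FALSE]
  pl <- place_peptides(psms, proteome)
  if (nrow(pl) == 0L)
    stop(sprintf("protein group %s has no placeable PSMs", group$accession))
  ref <- strsplit(toupper(proteome$entries[[group$accession]]$sequence), "")[[1L]]
  is_qn_ref <- ref == "Q" | ref == "N"
  # per distinct (peptide, start): which reference Q/N sites are spanned
  pkey <- paste(pl$peptide, pl$start)
  upos <- which(!duplicated(pkey))
  cov_sites <- lapply(upos, function(i) {
    span <- pl$start[i]:(pl$start[i] + nchar(pl$peptide[i]) - 1L)
    span[is_qn_ref[span]]
  })
  names(cov_sites) <- pkey[upos]
  sites_per_row <- cov_sites[pkey]
  covering <- lengths(sites_per_row) > 0L
  deamidated <- grepl("deamidation", pl$mods, fixed = TRUE)
  n_cov <- sum(covering)
  n_deam <- sum(covering & deamidated)
  qn_sites <- unique(unlist(sites_per_row[covering]))
  qn_peptides <- unique(collapse_peptide(pl$peptide[grepl("[QN]", pl$peptide)]))
  npos <- length(qn_sites)
  freq <- if (n_cov > 0L) n_deam / n_cov else NA_real_
  data.frame(sample_id = group$sample_id, accession = group$accession,
             n_spectra_covering_QN = n_cov,
             n_spectra_with_deamidation = n_deam,
             frequency = freq,
             n_distinct_QN_positions = npos,
             n_QN_peptides = length(qn_peptides),
             eligible = npos >= min_positions && n_cov > 0L,
             fully_deamidated_flag = isTRUE(freq == 1),
             cluster_label = "unassigned",
             stringsAsFactors = FALSE)
}

#' Deamidation summaries for a set of protein groups
#' @param groups [group_proteins()] output.
#' @param proteome A `reference_proteome`.
#' @param min_positions Minimum distinct covered Q/N sites (default 3).
#' @return data.frame, one row per group.
#' @export
deamidation_summaries <- function(groups, proteome, min_positions = 3) {
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i)
    deamidation_frequency(groups[i, , drop = FALSE], proteome, min_positions)))
  rownames(out) <- NULL
  out
}

# log-density of a Gaussian mixture, by component (n x k matrix)
.mix_logdens <- function(x, w, mu, sigma2) {
  k <- length(w)
  ld <- vapply(seq_len(k), function(j)
    log(w[j]) + stats::dnorm(x, mu[j], sqrt(sigma2[j]), log = TRUE),
    numeric(length(x)))
  matrix(ld, ncol = k)
}

.logsumexp_rows <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

#' Fit a univariate Gaussian mixture by EM with BIC selection
#'
#' Runs expectation-maximisation to convergence (log-likelihood change below
#' `tol` or `max_iter` iterations) for every combination of component count,
#' variance model (equal or unequal) and random restart, keeps the best
#' restart per combination, and selects the overall fit by minimal BIC
#' (`-2 lnL + p ln n`). Variances are clamped to `var_floor`, which keeps
#' boundary-heavy frequency data (values at 0 or 1) well behaved without a
#' logit transform. Deterministic given `seed`; the per-iteration
#' log-likelihood trace of the winning fit is retained.
#'
#' @param values Numeric observations (here: frequencies in `[0, 1]`);
#'   at least 3.
#' @param k_candidates Component counts to try (default 1:3).
#' @param variance_models Subset of `c("equal", "unequal")`.
#' @param n_restarts Random restarts per candidate (default 10).
#' @param seed Integer seed.
#' @param var_floor Lower bound on component variances (default 1e-4).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A `mixture_fit`: `k`, `weights`, `means`, `variances`,
#'   `variance_model`, `loglik`, `bic`, `responsibilities`, `loglik_trace`,
#'   and `bic_table` for all candidates.
#' @export
fit_mixture_1d <- function(values, k_candidates = c(1, 2, 3),
                           variance_models = c("equal", "unequal"),
                           n_restarts = 10, seed = 1, var_floor = 1e-4,
                           tol = 1e-8, max_iter = 500) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop("need at least 3 values to fit a mixture")
  if (n < min(k_candidates)) stop("fewer observations than components")
  variance_models <- match.arg(variance_models, several.ok = TRUE)
  set.seed(seed)
  run_em <- function(k, vmodel, mu0) {
    w <- rep(1 / k, k); mu <- mu0
    s2 <- rep(max(stats::var(x), var_floor), k)
    ll_trace <- numeric()
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      ld <- .mix_logdens(x, w, mu, s2)
      ll <- sum(.logsumexp_rows(ld))
      ll_trace <- c(ll_trace, ll)
      r <- exp(ld - .logsumexp_rows(ld))
      nk <- pmax(colSums(r), 1e-10)
      w <- nk / n
      mu <- colSums(r * x) / nk
      if (vmodel == "unequal") {
        s2 <- pmax(colSums(r * (outer(x, mu, `-`)^2)) / nk, var_floor)
      } else {
        s2tot <- sum(vapply(seq_len(k), function(j)
          sum(r[, j] * (x - mu[j])^2), numeric(1))) / n
        s2 <- rep(max(s2tot, var_floor), k)
      }
      if (is.finite(ll_old) && ll - ll_old < tol && ll >= ll_old) break
      ll_old <- ll
    }
    ld <- .mix_logdens(x, w, mu, s2)
    ll <- sum(.logsumexp_rows(ld))
    list(w = w, mu = mu, s2 = s2, ll = ll, trace = ll_trace,
         resp = exp(ld - .logsumexp_rows(ld)))
  }
  best <- NULL
  bic_rows <- list()
  for (k in sort(k_candidates)) {
    if (k > n) next
    for (vmodel in variance_models) {
      cand <- NULL
      for (r in seq_len(n_restarts)) {
        mu0 <- if (r == 1L) stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                            names = FALSE)
               else sort(sample(x, k, replace = k > n))
        fit <- run_em(k, vmodel, mu0)
        if (is.null(cand) || fit$ll > cand$ll) cand <- fit
      }
      p <- (k - 1) + k + if (vmodel == "unequal") k else 1
      bic <- -2 * cand$ll + p * log(n)
      bic_rows[[length(bic_rows) + 1L]] <-
        data.frame(k = k, variance_model = vmodel, loglik = cand$ll,
                   bic = bic, stringsAsFactors = FALSE)
      if (is.null(best) || bic < best$bic - 1e-9) {
        best <- list(k = k, weights = cand$w, means = cand$mu,
                     variances = cand$s2, variance_model = vmodel,
                     loglik = cand$ll, bic = bic,
                     responsibilities = cand$resp,
                     loglik_trace = cand$trace)
      }
    }
  }
  best$bic_table <- do.call(rbind, bic_rows)
  best$values <- x
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k=%d (%s variance), lnL=%.3f, BIC=%.3f\n",
              x$k, x$variance_model, x$loglik, x$bic))
  cat("  means:", format(x$means, digits = 4), "\n")
  invisible(x)
}

#' Assign endogenous/contaminant membership from a mixture fit
#'
#' Each eligible protein is labelled by its maximum-responsibility
#' component; components whose mean lies closer to the largest component
#' mean than to the smallest are labelled endogenous, the others
#' contaminant (for k = 2 this is simply the larger-mean component). With a
#' single component all proteins are labelled by comparing its mean against
#' `prior_threshold` and a warning is emitted. Ineligible proteins stay
#' `unassigned`. Labels are invariant to permuting the fit's components.
#'
#' @param summaries Deamidation summary rows; the eligible subset, in the
#'   order whose frequencies produced `fit`.
#' @param fit A `mixture_fit` on exactly those frequencies.
#' @param prior_threshold Endogenous/contaminant boundary used when k = 1
#'   (default 0.5).
#' @return `summaries` with `cluster_label` filled in.
#' @export
assign_membership <- function(summaries, fit, prior_threshold = 0.5) {
  el <- which(summaries$eligible)
  if (length(el) == 0L) return(summaries)
  if (length(el) != nrow(fit$responsibilities))
    stop("mixture fit size does not match number of eligible summaries")
  if (max(abs(summaries$frequency[el] - fit$values)) > 1e-12)
    stop("mixture fit was not produced on these summaries' frequencies")
  if (fit$k == 1L) {
    lab <- if (fit$means[1L] >= prior_threshold) "endogenous" else "contaminant"
    warning(sprintf(
      "single mixture component (mean %.3f); all eligible proteins labelled %s",
      fit$means[1L], lab))
    summaries$cluster_label[el] <- lab
  } else {
    comp_lab <- ifelse(abs(fit$means - max(fit$means)) <=
                         abs(fit$means - min(fit$means)),
                       "endogenous", "contaminant")
    assign <- max.col(fit$responsibilities, ties.method = "first")
    summaries$cluster_label[el] <- comp_lab[assign]
  }
  summaries
}

#' Paired deamidation comparison between two samples
#'
#' Restricts to proteins with at least `min_qn_peptides` distinct
#' Q/N-containing peptides in both samples, and tabulates both frequencies
#' and their difference (first sample minus second).
#'
#' @param summaries Deamidation summaries for exactly two samples.
#' @param sample_ids Length-2 character vector giving the order (first minus
#'   second); defaults to order of appearance.
#' @param min_qn_peptides Minimum Q/N-containing peptides per sample
#'   (default 2).
#' @return data.frame: accession, frequency in each sample, `difference`.
#' @export
compare_samples <- function(summaries, sample_ids = NULL, min_qn_peptides = 2) {
  if (is.null(sample_ids)) sample_ids <- unique(summaries$sample_id)
  if (length(sample_ids) != 2L) stop("need exactly two samples to compare")
  a <- summaries[summaries$sample_id == sample_ids[1L], , drop = FALSE]
  b <- summaries[summaries$sample_id == sample_ids[2L], , drop = FALSE]
  shared <- intersect(a$accession[a$n_QN_peptides >= min_qn_peptides],
                      b$accession[b$n_QN_peptides >= min_qn_peptides])
  out <- data.frame(accession = shared,
                    freq_1 = a$frequency[match(shared, a$accession)],
                    freq_2 = b$frequency[match(shared, b$accession)],
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("freq_", sample_ids)
  out$difference <- out[[2L]] - out[[3L]]
  out
}
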