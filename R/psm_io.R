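# PSM-table and reference-proteome I/O plus the acceptance filters:
# target-decoy FDR with q-value monotonisation for database matches, the ALC
# rule for de novo matches, two-unique-peptide / protein-score acceptance,
# and blank/catalogue contaminant flagging.
#
# PSM TSV dialect: tab-separated with a header; canonical columns are
#   spectrum_id, sample_id, peptide, mods, protein_accession, psm_score,
#   alc, is_decoy, is_de_novo
# and `dialect` maps canonical names to the file's column names.
# Modification strings are "type@pos" items joined by ";", with type one of
# oxidation-M, hydroxylation-P, deamidation-N, deamidation-Q and pos a
# 1-based index into the peptide whose residue must match the type's letter.

MOD_TYPES <- c("oxidation-M" = "M", "hydroxylation-P" = "P",
               "deamidation-N" = "N", "deamidation-Q" = "Q")

#' Read a reference proteome from FASTA
#'
#' Headers are parsed as `>accession [gene=SYMBOL] [contaminant=1] ...`;
#' a missing gene tag falls back to the accession. An optional telopeptide
#' side-table (TSV: accession, start, end; 1-based inclusive) annotates the
#' non-helical collagen termini.
#'
#' @param path FASTA file.
#' @param telopeptide_annotation Optional side-table path.
#' @return A `reference_proteome`: list `entries`, one per accession, each
#'   with `sequence`, `gene_symbol`, `is_contaminant`, `telopeptides`.
#' @export
read_fasta_proteome <- function(path, telopeptide_annotation = NULL) {
  xss <- Biostrings::readAAStringSet(path)
  if (length(xss) == 0L) stop("empty proteome FASTA")
  headers <- names(xss)
  acc <- sub("\\s.*$", "", headers)
  dup <- acc[duplicated(acc)]
  if (length(dup)) stop(sprintf("duplicate accession(s): %s",
                                paste(unique(dup), collapse = ", ")))
  gene <- ifelse(grepl("gene=(\\S+)", headers),
                 sub(".*gene=(\\S+).*", "\\1", headers), acc)
  contam <- grepl("contaminant=1", headers, fixed = TRUE)
  entries <- list()
  for (i in seq_along(xss)) {
    s <- as.character(xss[[i]])
    if (!nzchar(s)) stop(sprintf("empty sequence for %s", acc[i]))
    entries[[acc[i]]] <- list(sequence = s, gene_symbol = gene[i],
                              is_contaminant = contam[i],
                              telopeptides = as_ranges(NULL))
  }
  if (!is.null(telopeptide_annotation)) {
    tt <- utils::read.delim(telopeptide_annotation, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tt))) {
      a <- tt$accession[i]
      if (!a %in% names(entries))
        stop(sprintf("telopeptide annotation for unknown accession %s", a))
      n <- nchar(entries[[a]]$sequence)
      if (tt$start[i] < 1L || tt$end[i] > n || tt$start[i] > tt$end[i])
        stop(sprintf("telopeptide interval [%d,%d] out of bounds for %s",
                     tt$start[i], tt$end[i], a))
      entries[[a]]$telopeptides <- rbind(entries[[a]]$telopeptides,
                                         data.frame(start = tt$start[i],
                                                    end = tt$end[i]))
    }
    for (a in names(entries)) {
      r <- entries[[a]]$telopeptides
      if (nrow(r) > 1L) {
        r <- r[order(r$start), , drop = FALSE]
        if (any(r$start[-1L] <= r$end[-nrow(r)]))
          stop(sprintf("overlapping telopeptide ranges for %s", a))
        entries[[a]]$telopeptides <- r
      }
    }
  }
  structure(list(entries = entries), class = "reference_proteome")
}

#' Write a reference proteome as FASTA
#' @param proteome A `reference_proteome`.
#' @param path Output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- vapply(proteome$entries, `[[`, character(1), "sequence")
  hdr <- vapply(names(proteome$entries), function(a) {
    e <- proteome$entries[[a]]
    paste0(a, " gene=", e$gene_symbol,
           if (isTRUE(e$is_contaminant)) " contaminant=1" else "")
  }, character(1))
  xss <- Biostrings::AAStringSet(stats::setNames(seqs, hdr))
  Biostrings::writeXStringSet(xss, path, width = 60L)
  invisible(path)
}

default_psm_dialect <- function() {
  nm <- c("spectrum_id", "sample_id", "peptide", "mods", "protein_accession",
          "psm_score", "alc", "is_decoy", "is_de_novo")
  stats::setNames(nm, nm)
}

parse_mods <- function(mods, peptide) {
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(position = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  items <- strsplit(mods, ";", fixed = TRUE)[[1L]]
  m <- regmatches(items, regexec("^([a-z]+-[A-Z])@(\\d+)$", items))
  if (any(lengths(m) != 3L)) stop("malformed modification string")
  type <- vapply(m, `[[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[[`, character(1), 3L))
  if (!all(type %in% names(MOD_TYPES))) stop("unknown modification type")
  if (length(pos) > 6L) stop("more than six modifications on one peptide")
  if (any(pos < 1L | pos > nchar(peptide))) stop("modification position out of range")
  res <- substring(peptide, pos, pos)
  if (!all(res == MOD_TYPES[type]))
    stop("modification type does not match peptide residue")
  data.frame(position = pos, type = type, stringsAsFactors = FALSE)
}

#' Read a PSM table
#'
#' Reads a tab-separated PSM table, validates every row's modification
#' string against its peptide (a deamidation-N must sit on an N, and so on,
#' at most six modifications), and drops malformed rows with a warning that
#' lists their row numbers.
#'
#' @param path TSV file with header.
#' @param dialect Named character vector mapping canonical column names to
#'   the file's column names (default: identity).
#' @return data.frame of PSM records (canonical columns).
#' @export
read_psm_table <- function(path, dialect = default_psm_dialect()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- default_psm_dialect()
  dialect <- c(dialect, need[!names(need) %in% names(dialect)])
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing))
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  tab <- stats::setNames(raw[, unname(dialect[names(need)])], names(need))
  tab$is_decoy <- as.logical(tab$is_decoy)
  tab$is_de_novo <- as.logical(tab$is_de_novo)
  tab$mods <- ifelse(is.na(tab$mods), "", as.character(tab$mods))
  bad <- integer()
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({
      parse_mods(tab$mods[i], tab$peptide[i])
      nchar(tab$peptide[i]) >= 1L
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) bad <- c(bad, i)
  }
  if (length(bad)) {
    warning(sprintf("rejected %d malformed PSM row(s): %s", length(bad),
                    paste(bad, collapse = ", ")))
    tab <- tab[-bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a PSM table
#' @param psms PSM data.frame.
#' @param path Output TSV.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter PSMs by target-decoy FDR and de novo ALC
#'
#' Database-search PSMs (targets and decoys alike) are retained when their
#' q-value is at or below `fdr_threshold`. The q-value at a score s is the
#' smallest decoy/target ratio achievable at any score threshold <= s
#' (sort by decreasing score, running #decoys / #targets, monotonised from
#' the bottom). Substitution-bearing PSMs pass through the same FDR. De novo
#' PSMs are retained when their average local confidence (ALC, percent) is
#' at or above `alc_threshold`; they are additionally flagged in
#' `manual_inspection` for human review. Retaining passing decoys makes the
#' operation idempotent.
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @param fdr_threshold PSM-level FDR, as a fraction (default 0.01).
#' @param alc_threshold De novo ALC cut-off in percent, inclusive (default 50).
#' @return Filtered data.frame with attributes `qvalues` (for the database
#'   subset) and `manual_inspection` (retained de novo PSMs).
#' @export
filter_psms <- function(psms, fdr_threshold = 0.01, alc_threshold = 50) {
  if (nrow(psms) == 0L) return(psms)
  db <- !psms$is_de_novo
  keep <- logical(nrow(psms))
  if (any(db)) {
    if (!any(psms$is_decoy[db]))
      stop("no decoy PSMs present; target-decoy FDR is undefined")
    q <- psm_qvalues(psms$psm_score[db], psms$is_decoy[db])
    keep[db] <- q <= fdr_threshold
    attr_q <- q
  } else attr_q <- numeric()
  dn <- psms$is_de_novo
  keep[dn] <- !is.na(psms$alc[dn]) & psms$alc[dn] >= alc_threshold
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qvalues") <- attr_q
  attr(out, "manual_inspection") <- out[out$is_de_novo, , drop = FALSE]
  out
}

#' Target-decoy q-values
#'
#' @param score Numeric search scores.
#' @param is_decoy Logical decoy flags.
#' @return q-value per input PSM (same order as input).
#' @export
psm_qvalues <- function(score, is_decoy) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  dec <- cumsum(is_decoy[ord])
  tar <- cumsum(!is_decoy[ord])
  # tied scores share one threshold: use the counts at the block end
  be <- stats::ave(seq_along(s), factor(s), FUN = max)
  fdr <- ifelse(tar[be] == 0L, Inf, dec[be] / tar[be])
  q <- rev(cummin(rev(fdr)))
  q[order(ord)]
}

collapse_peptide <- function(p) gsub("L", "I", toupper(p), fixed = TRUE)

#' Group filtered PSMs into protein groups
#'
#' PSMs are grouped by (sample, accession); decoy PSMs are ignored. The
#' unique-peptide count is the number of distinct peptide strings after I/L
#' collapse (modifications ignored). The protein score is a precomputed
#' per-protein aggregate when supplied, otherwise the maximum PSM score of
#' the group (absolute score scales are dialect-specific). A group is
#' `accepted` when it has at least `min_unique` unique peptides and a score
#' at or above `min_score`, else `rejected`. Groups whose accession is not
#' in the proteome are excluded with a warning.
#'
#' @param psms Filtered PSM data.frame.
#' @param proteome A `reference_proteome`.
#' @param min_unique Minimum distinct collapsed peptides (default 2).
#' @param min_score Minimum protein score (default 20).
#' @param protein_scores Optional data.frame (sample_id, accession, score)
#'   of precomputed per-protein scores.
#' @return data.frame of protein groups with list-column `psm_rows` holding
#'   each group's PSM rows.
#' @export
group_proteins <- function(psms, proteome, min_unique = 2, min_score = 20,
                           protein_scores = NULL) {
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  if (nrow(psms) == 0L) {
    return(data.frame(sample_id = character(), accession = character(),
                      n_psms = integer(), n_unique_peptides = integer(),
                      protein_score = numeric(), status = character()))
  }
  unmapped <- !psms$protein_accession %in% names(proteome$entries)
  if (any(unmapped)) {
    warning(sprintf("excluding %d PSM(s) with accession(s) absent from proteome: %s",
                    sum(unmapped),
                    paste(unique(psms$protein_accession[unmapped]), collapse = ", ")))
    psms <- psms[!unmapped, , drop = FALSE]
  }
  key <- interaction(psms$sample_id, psms$protein_accession, drop = TRUE)
  groups <- lapply(split(seq_len(nrow(psms)), key), function(idx) {
    sub <- psms[idx, , drop = FALSE]
    score <- NULL
    if (!is.null(protein_scores)) {
      hit <- protein_scores$sample_id == sub$sample_id[1L] &
        protein_scores$accession == sub$protein_accession[1L]
      if (any(hit)) score <- protein_scores$score[which(hit)[1L]]
    }
    if (is.null(score)) score <- max(sub$psm_score, na.rm = TRUE)
    nuniq <- length(unique(collapse_peptide(sub$peptide)))
    data.frame(sample_id = sub$sample_id[1L],
               accession = sub$protein_accession[1L],
               n_psms = nrow(sub), n_unique_peptides = nuniq,
               protein_score = score,
               status = if (nuniq >= min_unique && score >= min_score)
                 "accepted" else "rejected",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, groups)
  out$psm_rows <- lapply(split(seq_len(nrow(psms)), key),
                         function(idx) psms[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Flag contaminant protein groups
#'
#' A group whose accession or gene symbol also appears among the extraction
#' blank's protein groups, or in the contaminant catalogue, has its status
#' set to `contaminant`. Flagged groups are retained (their deamidation is
#' still informative) but are excluded from consensus building and
#' phylogenetics downstream. PSM content is never altered.
#'
#' @param groups Protein-group data.frame from [group_proteins()].
#' @param blank_groups Protein groups of the extraction blank (may be NULL
#'   or empty; then only the catalogue applies).
#' @param catalogue Character vector of contaminant accessions or gene
#'   symbols.
#' @param proteome A `reference_proteome` (for gene-symbol lookup).
#' @return `groups` with updated `status`.
#' @export
remove_contaminants <- function(groups, blank_groups = NULL,
                                catalogue = character(), proteome) {
  if (nrow(groups) == 0L) return(groups)
  genes <- vapply(groups$accession, function(a)
    proteome$entries[[a]]$gene_symbol %||% a, character(1))
  blank_ids <- character()
  if (!is.null(blank_groups) && nrow(blank_groups) > 0L) {
    bg <- vapply(blank_groups$accession, function(a)
      (proteome$entries[[a]]$gene_symbol) %||% a, character(1))
    blank_ids <- c(blank_groups$accession, bg)
  }
  hit <- groups$accession %in% c(blank_ids, catalogue) |
    genes %in% c(blank_ids, catalogue)
  groups$status[hit] <- "contaminant"
  groups
}

`%||%` <- function(a, b) if (is.null(a)) b else a
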