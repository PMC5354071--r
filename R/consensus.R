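# Peptide placement against the reference proteome and per-gene consensus
# reconstruction. All sequence comparison happens in I/L-collapsed space;
# coordinates are 1-based inclusive throughout.

#' Place peptides on the reference proteome
#'
#' Scans every reference offset of the PSM's assigned protein (or of every
#' protein with `proteome_wide = TRUE`) for matches with at most
#' `max_mismatches` substitutions, in I/L-collapsed space. The unique best
#' placement is kept; equally good multiple placements are flagged
#' `ambiguous` (and later excluded from consensus with a warning).
#'
#' @param psms PSM data.frame (decoys are skipped).
#' @param proteome A `reference_proteome`.
#' @param max_mismatches Maximum substitutions per placement (default 1).
#' @param proteome_wide Search every protein instead of the assigned one.
#' @return data.frame: one row per placeable PSM with `start`,
#'   `n_mismatches`, `ambiguous` and a list-column `substitutions` of
#'   (ref_pos, ref_aa, obs_aa).
#' @export
place_peptides <- function(psms, proteome, max_mismatches = 1,
                           proteome_wide = FALSE) {
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  ref_str <- new.env(parent = emptyenv())
  ref_chr <- new.env(parent = emptyenv())
  get_str <- function(acc) {
    if (is.null(ref_str[[acc]]))
      ref_str[[acc]] <- collapse_peptide(proteome$entries[[acc]]$sequence)
    ref_str[[acc]]
  }
  get_chr <- function(acc) {
    if (is.null(ref_chr[[acc]]))
      ref_chr[[acc]] <- strsplit(get_str(acc), "")[[1L]]
    ref_chr[[acc]]
  }
  # one placement computation per distinct (peptide, search-space) pair
  search_key <- if (proteome_wide) rep("*", nrow(psms))
                else psms$protein_accession
  keys <- paste(psms$peptide, search_key, sep = "\r")
  uniq <- !duplicated(keys)
  place_one <- function(peptide, target_acc) {
    accs <- if (identical(target_acc, "*")) names(proteome$entries)
            else intersect(target_acc, names(proteome$entries))
    if (!length(accs)) return(NULL)
    pep_s <- collapse_peptide(peptide)
    pep <- strsplit(pep_s, "")[[1L]]
    best <- NULL; best_mm <- max_mismatches + 1L; nbest <- 0L
    for (acc in accs) {
      rs <- get_str(acc)
      if (nchar(rs) < length(pep)) {
        warning(sprintf("peptide longer than protein %s; no placement", acc))
        next
      }
      hits <- gregexpr(pep_s, rs, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L) {                 # exact matches (mm = 0)
        if (0L < best_mm) {
          best_mm <- 0L; nbest <- length(hits)
          best <- list(acc = acc, start = as.integer(hits[1L]))
        } else nbest <- nbest + length(hits) # best_mm already 0 elsewhere
      }
      if (best_mm > 0L && max_mismatches > 0L) {  # no exact hit anywhere yet
        ref <- get_chr(acc)
        for (off in seq_len(length(ref) - length(pep) + 1L)) {
          mm <- sum(ref[off:(off + length(pep) - 1L)] != pep)
          if (mm < best_mm) {
            best_mm <- mm; nbest <- 1L
            best <- list(acc = acc, start = off)
          } else if (mm == best_mm) nbest <- nbest + 1L
        }
      }
    }
    if (is.null(best) || best_mm > max_mismatches) return(NULL)
    ref <- get_chr(best$acc)
    span <- best$start:(best$start + length(pep) - 1L)
    mmpos <- which(ref[span] != pep)
    list(accession = best$acc, start = best$start, n_mismatches = best_mm,
         ambiguous = nbest > 1L,
         substitutions = data.frame(ref_pos = span[mmpos],
                                    ref_aa = ref[span][mmpos],
                                    obs_aa = pep[mmpos],
                                    stringsAsFactors = FALSE))
  }
  placed <- lapply(which(uniq), function(i)
    place_one(psms$peptide[i], search_key[i]))
  names(placed) <- keys[uniq]
  hit <- placed[keys]
  ok <- !vapply(hit, is.null, logical(1))
  if (!any(ok)) {
    return(data.frame(spectrum_id = character(), sample_id = character(),
                      peptide = character(), mods = character(),
                      is_de_novo = logical(), accession = character(),
                      start = integer(), n_mismatches = integer(),
                      ambiguous = logical()))
  }
  res <- data.frame(
    spectrum_id = psms$spectrum_id[ok], sample_id = psms$sample_id[ok],
    peptide = psms$peptide[ok], mods = psms$mods[ok],
    is_de_novo = psms$is_de_novo[ok],
    accession = vapply(hit[ok], `[[`, character(1), "accession"),
    start = vapply(hit[ok], `[[`, integer(1), "start"),
    n_mismatches = vapply(hit[ok], `[[`, integer(1), "n_mismatches"),
    ambiguous = vapply(hit[ok], `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE)
  res$substitutions <- lapply(hit[ok], `[[`, "substitutions")
  rownames(res) <- NULL
  res
}

#' Build a per-gene per-sample consensus sequence
#'
#' Per reference position the consensus residue is the spectral-majority
#' letter among unambiguous placements; a tie or zero depth yields `X`
#' (avoiding reference bias). A single-amino-acid variant (SAAV) is called
#' when the majority letter differs from the reference and is supported by
#' at least `saav_min_spectra` spectra; otherwise the reference letter is
#' retained and the variant logged as low-support.
#'
#' @param placements Placement rows (one gene, one sample) from
#'   [place_peptides()]; ambiguous rows are dropped with a warning.
#' @param reference_entry The proteome entry for this gene's accession.
#' @param sample_id,gene_symbol Identifiers recorded on the result.
#' @param saav_min_spectra Minimum spectra backing a SAAV call (default 2).
#' @return A `consensus_sequence`: `sequence` (I/L-collapsed, `X` unknown),
#'   `depth`, `coverage_fraction`, `saavs`, `low_support`.
#' @export
build_consensus <- function(placements, reference_entry, sample_id,
                            gene_symbol, saav_min_spectra = 2) {
  if (nrow(placements) > 0L) {
    accs <- unique(placements$accession)
    if (length(accs) > 1L)
      stop("placements from multiple proteins passed to build_consensus")
    if (any(placements$ambiguous)) {
      warning(sprintf("dropping %d ambiguous placement(s)",
                      sum(placements$ambiguous)))
      placements <- placements[!placements$ambiguous, , drop = FALSE]
    }
    # one vote per spectrum
    placements <- placements[!duplicated(placements$spectrum_id), , drop = FALSE]
  }
  ref <- strsplit(collapse_peptide(reference_entry$sequence), "")[[1L]]
  n <- length(ref)
  counts <- matrix(0L, 20L, n, dimnames = list(AA20, NULL))
  for (i in seq_len(nrow(placements))) {
    pep <- strsplit(collapse_peptide(placements$peptide[i]), "")[[1L]]
    span <- placements$start[i]:(placements$start[i] + length(pep) - 1L)
    idx <- match(pep, AA20)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], span[ok])] <-
      counts[cbind(idx[ok], span[ok])] + 1L
  }
  depth <- colSums(counts)
  cons <- rep("X", n)
  saavs <- list(); low <- list()
  covered <- which(depth > 0L)
  for (p in covered) {
    mx <- max(counts[, p])
    winners <- which(counts[, p] == mx)
    if (length(winners) > 1L) next  # tie -> X
    letter <- AA20[winners]
    if (letter == ref[p]) {
      cons[p] <- letter
    } else if (mx >= saav_min_spectra) {
      cons[p] <- letter
      saavs[[length(saavs) + 1L]] <- data.frame(
        ref_pos = p, ref_aa = ref[p], obs_aa = letter, n_spectra = mx,
        stringsAsFactors = FALSE)
    } else {
      cons[p] <- ref[p]
      low[[length(low) + 1L]] <- data.frame(
        ref_pos = p, ref_aa = ref[p], obs_aa = letter, n_spectra = mx,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(ref_pos = integer(), ref_aa = character(),
                      obs_aa = character(), n_spectra = integer())
  structure(list(sample_id = sample_id, gene_symbol = gene_symbol,
                 sequence = paste(cons, collapse = ""),
                 depth = depth,
                 coverage_fraction = mean(cons != "X"),
                 saavs = if (length(saavs)) do.call(rbind, saavs) else empty,
                 low_support = if (length(low)) do.call(rbind, low) else empty,
                 telopeptides = reference_entry$telopeptides),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("Consensus %s / %s: %d aa, coverage %.1f%%, %d SAAV(s)\n",
              x$sample_id, x$gene_symbol, nchar(x$sequence),
              100 * x$coverage_fraction, nrow(x$saavs)))
  invisible(x)
}

#' Per-gene and COL1 coverage report
#'
#' Tabulates per-gene coverage per sample and the combined COL1 coverage
#' over the concatenated non-telopeptide lengths of the two type I collagen
#' chains. Samples whose COL1 coverage falls below `warn_threshold` are
#' flagged for review (incomplete, conserved-region-dominated sequences can
#' attract an erroneous basal placement in the tree); exclusion is left to
#' configuration rather than automatic.
#'
#' @param consensus_list List of `consensus_sequence` objects.
#' @param col1_genes The two COL1 chain gene symbols.
#' @param warn_threshold COL1 coverage fraction below which a sample is
#'   flagged (default 0.40).
#' @return List: `per_gene` data.frame and `col1` data.frame with `flagged`.
#' @export
coverage_report <- function(consensus_list,
                            col1_genes = c("COL1A1", "COL1A2"),
                            warn_threshold = 0.40) {
  per_gene <- do.call(rbind, lapply(consensus_list, function(cs) {
    data.frame(sample_id = cs$sample_id, gene = cs$gene_symbol,
               length = nchar(cs$sequence),
               coverage = cs$coverage_fraction, stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  samples <- unique(per_gene$sample_id)
  col1 <- do.call(rbind, lapply(samples, function(sid) {
    tot <- 0L; cov <- 0L
    for (cs in consensus_list) {
      if (cs$sample_id != sid || !cs$gene_symbol %in% col1_genes) next
      chars <- strsplit(cs$sequence, "")[[1L]]
      keep <- rep(TRUE, length(chars))
      tl <- as_ranges(cs$telopeptides)
      for (i in seq_len(nrow(tl))) keep[tl$start[i]:tl$end[i]] <- FALSE
      tot <- tot + sum(keep)
      cov <- cov + sum(chars[keep] != "X")
    }
    data.frame(sample_id = sid,
               col1_length = tot,
               col1_coverage = if (tot > 0L) cov / tot else 0,
               stringsAsFactors = FALSE)
  }))
  col1$flagged <- col1$col1_coverage < warn_threshold
  if (any(col1$flagged))
    warning(sprintf(paste0("sample(s) %s below %.0f%% COL1 coverage; ",
                           "sequence may be dominated by conserved regions ",
                           "and mislead tree placement"),
                    paste(col1$sample_id[col1$flagged], collapse = ", "),
                    100 * warn_threshold))
  list(per_gene = per_gene, col1 = col1)
}
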