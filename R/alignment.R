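# Gene alignments and the concatenated, gene-partitioned matrix handed to the
# phylogenetic engine. Sequences live in I/L-collapsed space: the residue
# alphabet is the 20 amino acids minus L, plus X (unknown). Gaps "-" are
# accepted on input but converted to X.

#' Collapse isobaric leucine/isoleucine
#'
#' Leucine and isoleucine have identical mass and cannot be distinguished by
#' standard mass spectrometry, so every L becomes I. Idempotent.
#'
#' @param seq Character vector of amino-acid strings.
#' @return Strings with all `L` replaced by `I`.
#' @examples collapse_isobaric("LEVEL")  # "IEVEI"
#' @export
collapse_isobaric <- function(seq) gsub("L", "I", seq, fixed = TRUE)

#' Remove telopeptide regions from a collagen sequence
#'
#' Deletes the residues inside the given 1-based inclusive intervals (the
#' non-helical collagen termini) and concatenates the remainder in order.
#'
#' @param seq Single amino-acid string.
#' @param telopeptide_ranges Two-column matrix or data.frame (start, end),
#'   1-based inclusive; may have zero rows.
#' @return The sequence with telopeptide residues removed.
#' @export
remove_telopeptides <- function(seq, telopeptide_ranges) {
  stopifnot(length(seq) == 1L)
  r <- as_ranges(telopeptide_ranges)
  if (nrow(r) == 0L) return(seq)
  n <- nchar(seq)
  if (any(r$start < 1L | r$end > n | r$start > r$end))
    stop("telopeptide range outside sequence bounds")
  if (nrow(r) > 1L) {
    r <- r[order(r$start), , drop = FALSE]
    if (any(r$start[-1L] <= r$end[-nrow(r)])) stop("overlapping telopeptide ranges")
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(r))) keep[r$start[i]:r$end[i]] <- FALSE
  if (!any(keep)) warning("telopeptide removal left an empty sequence")
  paste(strsplit(seq, "")[[1]][keep], collapse = "")
}

as_ranges <- function(x) {
  if (is.null(x)) return(data.frame(start = integer(), end = integer()))
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(data.frame(start = integer(), end = integer()))
  names(x)[1:2] <- c("start", "end")
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x
}

#' Single-gene amino-acid alignment
#'
#' @param gene_symbol Gene name.
#' @param seqs Named character vector of equal-length sequences (names =
#'   taxa). `L` is collapsed to `I`; gaps `-` become `X` with a warning.
#' @param source `"consensus"` (reconstructed here) or `"database"`.
#' @return A `gene_alignment` object.
#' @export
gene_alignment <- function(gene_symbol, seqs, source = c("database", "consensus")) {
  source <- match.arg(source)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must be uniquely named by taxon")
  if (length(unique(nchar(seqs))) > 1L)
    stop(sprintf("unequal sequence lengths in gene %s", gene_symbol))
  seqs <- collapse_isobaric(toupper(seqs))
  if (any(grepl("-", seqs, fixed = TRUE))) {
    warning(sprintf("gap characters in gene %s converted to X", gene_symbol))
    seqs <- gsub("-", "X", seqs, fixed = TRUE)
  }
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), c(AA20, "X"))
  if (length(bad)) stop(sprintf("invalid residue(s) in gene %s: %s",
                                gene_symbol, paste(bad, collapse = "")))
  structure(list(gene_symbol = gene_symbol, taxa = names(seqs),
                 seqs = seqs, source = source),
            class = "gene_alignment")
}

#' Concatenate gene alignments into a partitioned matrix
#'
#' Taxa are the union over genes; a taxon missing from a gene has that
#' partition filled with `X` (fully missing). Partition boundaries are
#' recorded 1-based inclusive and tile the columns exactly.
#'
#' @param gene_alignments List of [gene_alignment()] objects, in the desired
#'   partition order.
#' @return A `partitioned_alignment`: list with `taxa`, `matrix` (character
#'   matrix taxa x columns) and `partitions` (data.frame gene, start, end).
#' @export
concatenate_partitions <- function(gene_alignments) {
  stopifnot(length(gene_alignments) >= 1L)
  taxa <- unique(unlist(lapply(gene_alignments, `[[`, "taxa")))
  widths <- vapply(gene_alignments, function(g) nchar(g$seqs[[1L]]), integer(1))
  genes <- vapply(gene_alignments, `[[`, character(1), "gene_symbol")
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mat <- matrix("X", nrow = length(taxa), ncol = sum(widths),
                dimnames = list(taxa, NULL))
  for (k in seq_along(gene_alignments)) {
    g <- gene_alignments[[k]]
    rows <- do.call(rbind, strsplit(g$seqs, ""))
    mat[g$taxa, starts[k]:ends[k]] <- rows
  }
  out <- structure(list(taxa = taxa, matrix = mat,
                        partitions = data.frame(gene = genes, start = starts,
                                                end = ends,
                                                stringsAsFactors = FALSE)),
                   class = "partitioned_alignment")
  validate_partitioned_alignment(out)
  out
}

validate_partitioned_alignment <- function(x) {
  p <- x$partitions
  stopifnot(nrow(p) >= 1L, p$start[1L] == 1L,
            p$end[nrow(p)] == ncol(x$matrix),
            all(p$start <= p$end))
  if (nrow(p) > 1L && !all(p$start[-1L] == p$end[-nrow(p)] + 1L))
    stop("partitions must tile the alignment contiguously")
  invisible(x)
}

#' Append externally sourced gene partitions
#'
#' Adds further gene alignments (for example translated nuclear genes from a
#' prior study) as new partitions after the existing columns. Taxon names in
#' the extra data may be reconciled to the base alignment's names via
#' `taxon_map`; taxa absent from the extra data are X-filled.
#'
#' @param base A `partitioned_alignment`.
#' @param extra List of [gene_alignment()] objects.
#' @param taxon_map Optional named character vector mapping extra-data taxon
#'   names to base taxon names; unmapped names must already match a base
#'   taxon or an error lists them.
#' @return The extended `partitioned_alignment`.
#' @export
append_external_partitions <- function(base, extra, taxon_map = NULL) {
  validate_partitioned_alignment(base)
  if (length(extra) == 0L) return(base)
  extra <- lapply(extra, function(g) {
    if (!is.null(taxon_map)) {
      hit <- names(g$seqs) %in% names(taxon_map)
      names(g$seqs)[hit] <- taxon_map[names(g$seqs)[hit]]
      g$taxa <- names(g$seqs)
    }
    unknown <- setdiff(g$taxa, base$taxa)
    if (length(unknown))
      stop(sprintf("unmappable taxon name(s) in gene %s: %s",
                   g$gene_symbol, paste(unknown, collapse = ", ")))
    g
  })
  widths <- vapply(extra, function(g) nchar(g$seqs[[1L]]), integer(1))
  genes <- vapply(extra, `[[`, character(1), "gene_symbol")
  off <- ncol(base$matrix)
  ends <- off + cumsum(widths)
  starts <- c(off + 1L, utils::head(ends, -1L) + 1L)
  add <- matrix("X", nrow = length(base$taxa), ncol = sum(widths),
                dimnames = list(base$taxa, NULL))
  for (k in seq_along(extra)) {
    g <- extra[[k]]
    rows <- do.call(rbind, strsplit(g$seqs, ""))
    add[g$taxa, (starts[k] - off):(ends[k] - off)] <- rows
  }
  out <- base
  out$matrix <- cbind(base$matrix, add)
  out$partitions <- rbind(base$partitions,
                          data.frame(gene = genes, start = starts, end = ends,
                                     stringsAsFactors = FALSE))
  validate_partitioned_alignment(out)
  out
}

#' Select phylogenetically informative non-collagen genes
#'
#' A non-COL1 gene enters the phylogenetic alignment only when at least one
#' study taxon carries at least one called amino-acid substitution (SAAV) in
#' it relative to the reference; the two COL1 chains are always included.
#' For included non-collagenous genes only the peptide-covered blocks carry
#' residues (uncovered columns are already X in consensus sequences).
#'
#' @param saav_table data.frame with columns `gene` and `sample_id` (one row
#'   per called SAAV), as produced by [build_consensus()] summaries.
#' @param genes Character vector of candidate gene symbols, in order.
#' @param study_taxa Sample ids of the study specimens.
#' @param col1_genes Gene symbols always retained.
#' @return Character vector: the included genes, preserving input order.
#' @export
select_variable_ncp_genes <- function(saav_table, genes, study_taxa,
                                      col1_genes = c("COL1A1", "COL1A2")) {
  has_saav <- vapply(genes, function(g) {
    any(saav_table$gene == g & saav_table$sample_id %in% study_taxa)
  }, logical(1))
  genes[genes %in% col1_genes | has_saav]
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("Partitioned amino-acid alignment: %d taxa, %d columns, %d partition(s)\n",
              length(x$taxa), ncol(x$matrix), nrow(x$partitions)))
  for (i in seq_len(nrow(x$partitions)))
    cat(sprintf("  %-10s %6d-%6d\n", x$partitions$gene[i],
                x$partitions$start[i], x$partitions$end[i]))
  invisible(x)
}
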