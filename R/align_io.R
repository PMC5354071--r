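# Alignment readers/writers: FASTA, relaxed PHYLIP, NEXUS with charsets, and
# RAxML-style partition files. Writers and readers round-trip exactly.

#' Write a partitioned alignment as FASTA
#' @param aln A `partitioned_alignment` or `gene_alignment`.
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- alignment_strings(aln)
  xss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(xss, path, width = 60L)
  invisible(path)
}

#' Read an alignment from FASTA
#' @param path FASTA file of equal-length amino-acid sequences.
#' @param partitions Optional partition data.frame (gene, start, end) to
#'   attach; default one partition spanning all columns.
#' @return A `partitioned_alignment`.
#' @export
read_alignment_fasta <- function(path, partitions = NULL) {
  xss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(xss)
  names(seqs) <- sub("\\s.*$", "", names(xss))
  make_partitioned(seqs, partitions)
}

make_partitioned <- function(seqs, partitions = NULL) {
  if (length(unique(nchar(seqs))) != 1L) stop("unequal sequence lengths")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  if (is.null(partitions))
    partitions <- data.frame(gene = "all", start = 1L, end = ncol(mat),
                             stringsAsFactors = FALSE)
  out <- structure(list(taxa = names(seqs), matrix = mat,
                        partitions = partitions),
                   class = "partitioned_alignment")
  validate_partitioned_alignment(out)
  out
}

alignment_strings <- function(aln) {
  if (inherits(aln, "gene_alignment")) return(aln$seqs)
  stopifnot(inherits(aln, "partitioned_alignment"))
  stats::setNames(apply(aln$matrix, 1L, paste, collapse = ""), aln$taxa)
}

#' Write a relaxed-PHYLIP alignment
#' @param aln A `partitioned_alignment`.
#' @param path Output file.
#' @export
write_alignment_phylip <- function(aln, path) {
  seqs <- alignment_strings(aln)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(seqs), nchar(seqs[[1L]])), con)
  writeLines(paste(names(seqs), seqs), con)
  invisible(path)
}

#' Read a relaxed-PHYLIP alignment
#' @param path PHYLIP file (relaxed names, sequences on one line).
#' @param partitions Optional partition table to attach.
#' @return A `partitioned_alignment`.
#' @export
read_alignment_phylip <- function(path, partitions = NULL) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) != hdr[1L]) stop("PHYLIP taxon count mismatch")
  parts <- strsplit(trimws(body), "\\s+")
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
  names(seqs) <- vapply(parts, `[[`, character(1), 1L)
  if (any(nchar(seqs) != hdr[2L])) stop("PHYLIP column count mismatch")
  make_partitioned(seqs, partitions)
}

#' Write a RAxML-style partition file
#'
#' One line per partition: `MODEL, gene = start-end`.
#' @param aln A `partitioned_alignment`.
#' @param path Output file.
#' @param model Model name written on each line.
#' @export
write_raxml_partitions <- function(aln, path, model = "DAYHOFF") {
  p <- aln$partitions
  writeLines(sprintf("%s, %s = %d-%d", model, p$gene, p$start, p$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#' @param path Partition file written by [write_raxml_partitions()].
#' @return data.frame with columns gene, start, end (and model).
#' @export
read_raxml_partitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^,]+),\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)$", lines))
  if (any(lengths(m) != 5L)) stop("malformed partition line")
  data.frame(gene = vapply(m, `[[`, character(1), 3L),
             start = as.integer(vapply(m, `[[`, character(1), 4L)),
             end = as.integer(vapply(m, `[[`, character(1), 5L)),
             model = trimws(vapply(m, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Write a NEXUS data file with charsets for the Bayesian engine
#' @param aln A `partitioned_alignment`.
#' @param path Output file.
#' @export
write_nexus_alignment <- function(aln, path) {
  seqs <- alignment_strings(aln)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("begin data;", con)
  writeLines(sprintf("  dimensions ntax=%d nchar=%d;", length(seqs),
                     nchar(seqs[[1L]])), con)
  writeLines("  format datatype=protein missing=X gap=-;", con)
  writeLines("  matrix", con)
  writeLines(sprintf("    %s  %s", names(seqs), seqs), con)
  writeLines("  ;", con)
  writeLines("end;", con)
  writeLines("begin sets;", con)
  p <- aln$partitions
  writeLines(sprintf("  charset %s = %d-%d;", p$gene, p$start, p$end), con)
  writeLines("end;", con)
  invisible(path)
}
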