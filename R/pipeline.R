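# End-to-end orchestration: one YAML configuration drives
# filter -> deamidation -> consensus -> alignment -> ML + bootstrap -> MCMC
# -> consensus tree, with per-stage counts collected into a machine-readable
# run report. Subcommand-style wrappers back the thin command-line script.

#' Validate a pipeline configuration
#'
#' Checks threshold bounds and required fields before any stage runs.
#'
#' @param config Configuration list (see [run_pipeline()]).
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  ph <- config$phylo
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("config validation: ", msg)
  chk(!is.null(config$paths$proteome), "paths$proteome missing")
  chk(is.numeric(th$fdr) && th$fdr > 0 && th$fdr <= 0.5,
      "thresholds$fdr must be in (0, 0.5]")
  chk(is.numeric(th$alc) && th$alc >= 0 && th$alc <= 100,
      "thresholds$alc must be in [0, 100]")
  chk(th$min_unique >= 1, "thresholds$min_unique must be >= 1")
  chk(th$min_qn_positions >= 1, "thresholds$min_qn_positions must be >= 1")
  chk(th$saav_min_spectra >= 1, "thresholds$saav_min_spectra must be >= 1")
  chk(th$coverage_warn >= 0 && th$coverage_warn <= 1,
      "thresholds$coverage_warn must be in [0, 1]")
  chk(ph$burn_in >= 0 && ph$burn_in < 1, "phylo$burn_in must be in [0, 1)")
  chk(ph$bootstrap >= 1, "phylo$bootstrap must be >= 1")
  chk(ph$generations >= ph$sample_interval &&
        ph$generations %% ph$sample_interval == 0,
      "phylo$generations must be a multiple of phylo$sample_interval")
  chk(!is.null(config$seed), "seed missing")
  invisible(config)
}

.stage <- function(name, report, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE))
  report$stages[[name]] <- "complete"
  list(value = res, report = report)
}

#' Run the whole pipeline from a configuration
#'
#' Executes PSM filtering, protein grouping and contaminant removal,
#' deamidation authentication, consensus reconstruction, alignment assembly,
#' maximum-likelihood inference with bootstrap, Bayesian MCMC with
#' diagnostics, and consensus-tree construction; writes the main artefacts
#' and a JSON run report into `out_dir`. Any stage failure aborts with a
#' stage-named error.
#'
#' @param config Path to a YAML configuration or an equivalent list. Paths
#'   inside the config are resolved against `base_dir`.
#' @param base_dir Directory against which config paths resolve (defaults
#'   to the config file's directory, or `"."` for a list).
#' @param out_dir Output directory (default `file.path(base_dir, "out")`).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, base_dir = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (is.null(out_dir)) out_dir <- file.path(base_dir, "out")
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rp <- function(p) file.path(base_dir, p)
  th <- config$thresholds; ph <- config$phylo
  seed <- as.integer(config$seed)
  report <- list(package_version = as.character(utils::packageVersion("palaeoprot")),
                 seed = seed, stages = list(), counts = list())
  model <- dayhoff_model()

  # --- load inputs
  st <- .stage("load", report, {
    proteome <- read_fasta_proteome(rp(config$paths$proteome),
                                    telopeptide_annotation =
                                      if (!is.null(config$paths$telopeptides))
                                        rp(config$paths$telopeptides))
    psms <- lapply(config$paths$psm_tables, function(p) read_psm_table(rp(p)))
    blank <- if (!is.null(config$paths$blank)) read_psm_table(rp(config$paths$blank))
    list(proteome = proteome, psms = psms, blank = blank)
  })
  report <- st$report; inputs <- st$value
  samples <- names(inputs$psms)

  # --- PSM filtering
  st <- .stage("filter", report, {
    filt <- lapply(inputs$psms, filter_psms, fdr_threshold = th$fdr,
                   alc_threshold = th$alc)
    blank_filt <- if (!is.null(inputs$blank))
      filter_psms(inputs$blank, th$fdr, th$alc)
    list(filt = filt, blank = blank_filt)
  })
  report <- st$report; filt <- st$value
  report$counts$psms_in <- vapply(inputs$psms, nrow, integer(1))
  report$counts$psms_retained <- vapply(filt$filt, nrow, integer(1))

  # --- protein grouping + contaminants
  st <- .stage("group", report, {
    catalogue <- names(inputs$proteome$entries)[vapply(
      inputs$proteome$entries, `[[`, logical(1), "is_contaminant")]
    blank_groups <- if (!is.null(filt$blank) && nrow(filt$blank) > 0L)
      group_proteins(filt$blank, inputs$proteome, th$min_unique, th$min_score)
    groups <- lapply(filt$filt, function(f) {
      g <- group_proteins(f, inputs$proteome, th$min_unique, th$min_score)
      remove_contaminants(g, blank_groups, catalogue, inputs$proteome)
    })
    list(groups = groups, blank_groups = blank_groups)
  })
  report <- st$report; grp <- st$value
  report$counts$proteins_accepted <- vapply(grp$groups, function(g)
    sum(g$status == "accepted"), integer(1))
  report$counts$proteins_contaminant <- vapply(grp$groups, function(g)
    sum(g$status == "contaminant"), integer(1))

  # --- deamidation authentication
  st <- .stage("deamidate", report, {
    out <- lapply(samples, function(sid) {
      g <- grp$groups[[sid]]
      g <- g[g$status %in% c("accepted", "contaminant"), , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      sm <- deamidation_summaries(g, inputs$proteome, th$min_qn_positions)
      el <- sm[sm$eligible, , drop = FALSE]
      if (nrow(el) >= 3L) {
        fit <- fit_mixture_1d(el$frequency, seed = seed)
        sm[sm$eligible, ] <- assign_membership(el, fit)
      }
      utils::write.table(sm, file.path(out_dir,
                                       paste0("deamidation_", sid, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      sm
    })
    stats::setNames(out, samples)
  })
  report <- st$report; deam <- st$value

  # --- consensus reconstruction
  genes <- as.character(ph$gene_order)
  st <- .stage("consensus", report, {
    cons <- list()
    saav_rows <- list()
    for (sid in samples) {
      g <- grp$groups[[sid]]
      keep <- g$status == "accepted"
      for (gene in genes) {
        acc <- names(inputs$proteome$entries)[vapply(
          inputs$proteome$entries, function(e) e$gene_symbol == gene, logical(1))]
        rows <- which(keep & g$accession %in% acc)
        if (!length(rows)) next
        psms <- do.call(rbind, g$psm_rows[rows])
        pl <- place_peptides(psms, inputs$proteome)
        pl <- pl[pl$accession %in% acc, , drop = FALSE]
        cs <- build_consensus(pl, inputs$proteome$entries[[acc[1L]]], sid,
                              gene, th$saav_min_spectra)
        cons[[paste(sid, gene, sep = "/")]] <- cs
        if (nrow(cs$saavs))
          saav_rows[[length(saav_rows) + 1L]] <-
            cbind(sample_id = sid, gene = gene, cs$saavs)
      }
    }
    saavs <- if (length(saav_rows)) do.call(rbind, saav_rows)
             else data.frame(sample_id = character(), gene = character())
    utils::write.table(saavs, file.path(out_dir, "saavs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cov <- coverage_report(cons, warn_threshold = th$coverage_warn)
    utils::write.table(cov$per_gene, file.path(out_dir, "coverage.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(cons = cons, saavs = saavs, coverage = cov)
  })
  report <- st$report; cons <- st$value

  # --- alignment assembly
  st <- .stage("align", report, {
    sample_taxa <- stats::setNames(config$samples$taxon, config$samples$sample_id)
    included <- select_variable_ncp_genes(cons$saavs, genes, samples)
    gas <- lapply(included, function(gene) {
      db <- read_alignment_fasta(rp(file.path(config$paths$genes_dir,
                                              paste0(gene, ".fasta"))))
      seqs <- alignment_strings(db)
      seqs <- seqs[setdiff(names(seqs), unname(sample_taxa))]
      for (sid in samples) {
        cs <- cons$cons[[paste(sid, gene, sep = "/")]]
        if (is.null(cs)) next
        s <- remove_telopeptides(cs$sequence, cs$telopeptides)
        seqs[[unname(sample_taxa[sid])]] <- s
      }
      gene_alignment(gene, collapse_isobaric(seqs))
    })
    aln <- concatenate_partitions(gas)
    write_alignment_fasta(aln, file.path(out_dir, "alignment.fasta"))
    write_raxml_partitions(aln, file.path(out_dir, "partitions.txt"),
                           model = ph$model)
    write_nexus_alignment(aln, file.path(out_dir, "alignment.nex"))
    aln
  })
  report <- st$report; aln <- st$value
  report$counts$alignment_columns <- ncol(aln$matrix)
  report$counts$alignment_taxa <- length(aln$taxa)

  # --- ML + bootstrap
  st <- .stage("tree_ml", report, {
    ml <- ml_search(aln, model)
    rates <- estimate_partition_rates(ml$tree, aln, model)
    bs <- bootstrap_support(aln, model, n_replicates = ph$bootstrap,
                            seed = seed, ml_tree = ml$tree, rates = rates)
    rooted <- root_with_outgroup(bs$tree, ph$outgroup)
    ape::write.tree(rooted, file.path(out_dir, "ml_tree.nwk"))
    list(ml = ml, rates = rates, bs = bs, rooted = rooted)
  })
  report <- st$report; ml <- st$value
  report$counts$ml_lnl <- ml$ml$lnl
  report$counts$partition_rates <- as.list(ml$rates)

  # --- MCMC
  st <- .stage("tree_mcmc", report, {
    trace <- mcmc_sample(aln, model, generations = ph$generations,
                         sample_interval = ph$sample_interval,
                         burn_in_fraction = ph$burn_in, seed = seed,
                         start_tree = ml$ml$tree)
    diag <- mcmc_diagnostics(trace)
    utils::write.table(
      data.frame(generation = trace$generation, lnl = trace$lnl,
                 tree_length = trace$tree_length, trace$rates),
      file.path(out_dir, "mcmc_trace.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    list(trace = trace, diag = diag)
  })
  report <- st$report; mc <- st$value
  report$ess <- stats::setNames(as.list(mc$diag$ess), mc$diag$parameter)

  # --- consensus tree
  st <- .stage("tree_consensus", report, {
    post <- discard_burnin(mc$trace)
    cons_tree <- majority_consensus(post$trees)
    rooted <- root_with_outgroup(cons_tree, ph$outgroup)
    ape::write.tree(rooted, file.path(out_dir, "mcmc_consensus_tree.nwk"))
    rooted
  })
  report <- st$report

  files <- c("alignment.fasta", "partitions.txt", "ml_tree.nwk",
             "mcmc_consensus_tree.nwk")
  report$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(report$checksums) <- files
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
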