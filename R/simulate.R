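# Synthetic-data generation: protein sequences evolved along a known tree
# under the substitution model, tryptic in-silico digestion, and simulated
# PSM tables with age-dependent Gln/Asn deamidation for endogenous proteins
# versus low, age-independent deamidation for contaminants. Every generated
# label is kept in a truth record so downstream recovery can be scored.

#' Simulate per-gene alignments along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies and then
#' evolved edge-wise through `P(t * rate)`. Deterministic for a given seed.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param model An `aa_model`.
#' @param lengths Named integer vector: columns per gene.
#' @param rates Optional named per-gene rate multipliers (default 1).
#' @param seed Integer seed.
#' @return Named list (per gene) of named character vectors taxon -> sequence
#'   (raw 20-letter alphabet, L included).
#' @export
simulate_alignment <- function(tree, model, lengths, rates = NULL, seed) {
  set.seed(seed)
  if (is.null(names(lengths))) names(lengths) <- paste0("g", seq_along(lengths))
  if (is.null(rates)) rates <- stats::setNames(rep(1, length(lengths)), names(lengths))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  out <- vector("list", length(lengths))
  names(out) <- names(lengths)
  for (g in names(lengths)) {
    L <- lengths[[g]]
    states <- matrix(0L, nn, L)
    states[root, ] <- sample.int(20L, L, replace = TRUE, prob = model$freqs)
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
      par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      P <- transition_prob(model, po$edge.length[e] * rates[[g]])
      s <- states[par, ]
      new <- integer(L)
      for (st in unique(s)) {
        idx <- which(s == st)
        new[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[st, ])
      }
      states[ch, ] <- new
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                  function(r) paste(AA20[r], collapse = ""))
    names(seqs) <- po$tip.label
    out[[g]] <- seqs
  }
  out
}

#' Tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P, enumerates
#' missed-cleavage variants, and drops peptides outside the length bounds.
#'
#' @param sequence Amino-acid string.
#' @param min_len,max_len Peptide length bounds.
#' @param missed_cleavages Maximum number of internal missed cleavage sites.
#' @return data.frame: peptide, start, end (1-based in the protein), missed.
#' @export
in_silico_digest <- function(sequence, min_len = 6, max_len = 30,
                             missed_cleavages = 2) {
  n <- nchar(sequence)
  if (n == 0L) return(data.frame(peptide = character(), start = integer(),
                                 end = integer(), missed = integer()))
  chars <- strsplit(sequence, "")[[1L]]
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > nfrag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, s, e), start = s, end = e, missed = mc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(peptide = character(), start = integer(),
                                      end = integer(), missed = integer()))
  do.call(rbind, out)
}

#' Study configuration for the PSM simulator
#'
#' Bundles the degradation and acquisition parameters of a simulated
#' two-sample ancient-bone study. Defaults follow the packaged
#' Middle-vs-Late-Pleistocene design: per-spectrum Gln/Asn deamidation
#' probability 0.85 for the older age class and 0.65 for the younger one,
#' 0.10 for contaminant proteins regardless of age.
#'
#' @param tree Newick string or `phylo` with branch lengths.
#' @param gene_lengths Named integer vector (phylogenetic gene partitions).
#' @param gene_rates Named per-gene rate multipliers.
#' @param samples data.frame: sample_id, taxon, age_class.
#' @param outgroup Outgroup taxon name.
#' @param endogenous_deamidation Named per-age-class per-spectrum Q/N
#'   deamidation probabilities.
#' @param contaminant_deamidation Contaminant per-spectrum probability.
#' @param spectra_per_peptide Poisson mean spectral count per detected peptide.
#' @param detect_prob Per-peptide detection probability (endogenous).
#' @param contaminant_detect_prob Per-peptide detection probability
#'   (contaminants).
#' @param decoy_fraction Decoy PSMs added as a fraction of target PSMs.
#' @param de_novo_fraction Fraction of PSMs flagged as de novo sequencing
#'   results (given an ALC instead of a decoy-calibrated score).
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Search-score distribution parameters (arbitrary dialect scale).
#' @param seed Integer seed (mandatory).
#' @return A `study_config` list.
#' @export
study_config <- function(tree, gene_lengths, gene_rates, samples, outgroup,
                         endogenous_deamidation = c(old = 0.85, young = 0.65),
                         contaminant_deamidation = 0.10,
                         spectra_per_peptide = 6,
                         detect_prob = 0.8,
                         contaminant_detect_prob = 0.25,
                         decoy_fraction = 0.5,
                         de_novo_fraction = 0.05,
                         target_score_mean = 45, target_score_sd = 8,
                         decoy_score_mean = 24, decoy_score_sd = 5,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(all(samples$taxon %in% tree$tip.label),
            all(samples$age_class %in% names(endogenous_deamidation)),
            all(endogenous_deamidation >= 0 & endogenous_deamidation <= 1),
            contaminant_deamidation >= 0, contaminant_deamidation <= 1,
            all(gene_lengths >= 1))
  structure(list(tree = tree, gene_lengths = gene_lengths,
                 gene_rates = gene_rates, samples = samples,
                 outgroup = outgroup,
                 endogenous_deamidation = endogenous_deamidation,
                 contaminant_deamidation = contaminant_deamidation,
                 spectra_per_peptide = spectra_per_peptide,
                 detect_prob = detect_prob,
                 contaminant_detect_prob = contaminant_detect_prob,
                 decoy_fraction = decoy_fraction,
                 de_novo_fraction = de_novo_fraction,
                 target_score_mean = target_score_mean,
                 target_score_sd = target_score_sd,
                 decoy_score_mean = decoy_score_mean,
                 decoy_score_sd = decoy_score_sd,
                 seed = seed), class = "study_config")
}

# random protein sequence with roughly physiological composition
.random_protein <- function(len, model) {
  paste(sample(AA20, len, replace = TRUE, prob = model$freqs), collapse = "")
}

#' Simulate a PSM study from derived true sequences
#'
#' For every sample: digests each endogenous protein (the sample taxon's
#' evolved sequence for phylogenetic genes, the reference sequence for the
#' other bone proteins), samples detected peptides and per-peptide spectral
#' counts, flips each spectrum's Q/N sites to deamidated with the sample
#' age-class probability, and adds contaminant PSMs (low, age-independent
#' deamidation) plus reversed-sequence decoy PSMs for the FDR machinery.
#' The extraction blank contains only contaminant and enzyme PSMs.
#'
#' @param config A [study_config()].
#' @param proteome A `reference_proteome` (see [read_fasta_proteome()]).
#' @param derived List per sample_id: named list gene -> true amino-acid
#'   sequence for that sample's taxon (phylogenetic genes only).
#' @return List: `psms` (data.frame per sample, incl. `"BLANK"`), and
#'   `truth` (list with `proteins` and `deamidation` data.frames).
#' @export
simulate_psm_study <- function(config, proteome, derived) {
  stopifnot(inherits(config, "study_config"))
  if (!setequal(names(derived), config$samples$sample_id))
    stop("derived sequences do not match the configured samples")
  set.seed(config$seed)
  pr <- proteome$entries
  endo_acc <- names(pr)[!vapply(pr, `[[`, logical(1), "is_contaminant")]
  cont_acc <- names(pr)[vapply(pr, `[[`, logical(1), "is_contaminant")]
  phylo_genes <- names(config$gene_lengths)
  all_psms <- list()
  truth_prot <- list()
  spectrum_counter <- 0L

  emit <- function(sample_id, accession, seqs, detect_prob, deam_prob) {
    pep_v <- character(); acc_v <- character(); mods_v <- character()
    for (acc in accession) {
      trueseq <- seqs[[acc]]
      peps <- in_silico_digest(trueseq)
      if (!nrow(peps)) next
      det <- stats::runif(nrow(peps)) < detect_prob
      peps <- peps[det, , drop = FALSE]
      if (!nrow(peps)) next
      nspec <- stats::rpois(nrow(peps), config$spectra_per_peptide)
      for (i in seq_len(nrow(peps))) {
        if (nspec[i] == 0L) next
        pep <- peps$peptide[i]
        pc <- strsplit(pep, "")[[1L]]
        qn <- which(pc == "Q" | pc == "N")
        mpos <- which(pc == "M"); ppos <- which(pc == "P")
        qn_lab <- if (length(qn)) sprintf("deamidation-%s@%d", pc[qn], qn)
        m_lab <- if (length(mpos)) sprintf("oxidation-M@%d", mpos)
        p_lab <- if (length(ppos)) sprintf("hydroxylation-P@%d", ppos)
        for (s in seq_len(nspec[i])) {
          # deamidation is drawn per spectrum (so the spectrum-level
          # frequency converges to deam_prob); within a deamidated
          # spectrum each Q/N site is modified with the same probability,
          # conditioned on at least one
          deam_sites <- integer()
          if (length(qn) && stats::runif(1) < deam_prob) {
            hit <- which(stats::runif(length(qn)) < deam_prob)
            if (!length(hit)) hit <- sample.int(length(qn), 1L)
            deam_sites <- hit
          }
          mods <- c(
            qn_lab[deam_sites],
            if (length(mpos)) m_lab[stats::runif(length(mpos)) < 0.10],
            if (length(ppos)) p_lab[stats::runif(length(ppos)) < 0.15])
          if (length(mods) > 6L) mods <- mods[1:6]
          n <- length(pep_v) + 1L
          pep_v[n] <- pep; acc_v[n] <- acc
          mods_v[n] <- paste(mods, collapse = ";")
        }
      }
    }
    if (!length(pep_v)) return(NULL)
    n <- length(pep_v)
    ids <- spectrum_counter + seq_len(n)
    spectrum_counter <<- spectrum_counter + n
    data.frame(spectrum_id = sprintf("SP%07d", ids),
               sample_id = sample_id, peptide = pep_v, mods = mods_v,
               protein_accession = acc_v,
               psm_score = stats::rnorm(n, config$target_score_mean,
                                        config$target_score_sd),
               alc = NA_real_, is_decoy = FALSE, is_de_novo = FALSE,
               stringsAsFactors = FALSE)
  }

  finish_sample <- function(tab, sample_id) {
    if (is.null(tab)) return(NULL)
    n <- nrow(tab)
    # a slice of PSMs are de novo results carrying an ALC instead
    dn <- stats::runif(n) < config$de_novo_fraction
    tab$is_de_novo <- dn
    tab$alc[dn] <- stats::runif(sum(dn), 30, 98)
    tab$psm_score[dn] <- NA_real_
    # reversed-peptide decoys
    ndec <- max(2L, round(config$decoy_fraction * sum(!dn)))
    src <- sample(which(!dn), ndec, replace = TRUE)
    rev_pep <- vapply(strsplit(tab$peptide[src], ""),
                      function(x) paste(rev(x), collapse = ""), character(1))
    dec <- data.frame(
      spectrum_id = sprintf("SPD%06d_%s", seq_len(ndec), sample_id),
      sample_id = sample_id, peptide = rev_pep, mods = "",
      protein_accession = paste0("DECOY_", tab$protein_accession[src]),
      psm_score = stats::rnorm(ndec, config$decoy_score_mean,
                               config$decoy_score_sd),
      alc = NA_real_, is_decoy = TRUE, is_de_novo = FALSE,
      stringsAsFactors = FALSE)
    rbind(tab, dec)
  }

  for (si in seq_len(nrow(config$samples))) {
    sample_id <- config$samples$sample_id[si]
    age <- config$samples$age_class[si]
    p_endo <- config$endogenous_deamidation[[age]]
    seqs <- lapply(stats::setNames(endo_acc, endo_acc), function(acc) {
      gene <- pr[[acc]]$gene_symbol
      if (gene %in% phylo_genes) derived[[sample_id]][[gene]]
      else pr[[acc]]$sequence
    })
    endo_tab <- emit(sample_id, endo_acc, seqs, config$detect_prob, p_endo)
    cont_seqs <- lapply(stats::setNames(cont_acc, cont_acc),
                        function(acc) pr[[acc]]$sequence)
    cont_tab <- emit(sample_id, cont_acc, cont_seqs,
                     config$contaminant_detect_prob,
                     config$contaminant_deamidation)
    tab <- finish_sample(rbind(endo_tab, cont_tab), sample_id)
    all_psms[[sample_id]] <- tab
    truth_prot[[sample_id]] <- data.frame(
      sample_id = sample_id,
      accession = c(endo_acc, cont_acc),
      endogenous = rep(c(TRUE, FALSE), c(length(endo_acc), length(cont_acc))),
      true_deamidation = rep(c(p_endo, config$contaminant_deamidation),
                             c(length(endo_acc), length(cont_acc))),
      stringsAsFactors = FALSE)
  }
  # extraction blank: contaminants only, lighter load
  cont_seqs <- lapply(stats::setNames(cont_acc, cont_acc),
                      function(acc) pr[[acc]]$sequence)
  blank <- finish_sample(
    emit("BLANK", cont_acc, cont_seqs, config$contaminant_detect_prob,
         config$contaminant_deamidation), "BLANK")
  all_psms[["BLANK"]] <- blank
  list(psms = all_psms, truth = list(proteins = do.call(rbind, truth_prot)))
}

# ---- study presets ---------------------------------------------------------

RHINO12_TREE <- paste0(
  "((Equus_caballus:0.012,(Equus_asinus:0.006,Equus_hydruntinus:0.006)",
  ":0.008):0.022,(Tapirus_terrestris:0.025,((Ceratotherium_simum:0.006,",
  "Diceros_bicornis:0.006):0.008,((Rhinoceros_unicornis:0.005,",
  "Rhinoceros_sondaicus:0.005):0.006,(Dicerorhinus_sumatrensis:0.006,",
  "(Stephanorhinus_sp:0.004,Coelodonta_antiquitatis:0.004):0.004):0.005)",
  ":0.006):0.01):0.01,Bos_primigenius:0.06);")

# aligned-block widths per gene: the mature (telopeptide-free) chains of the
# two COL1 genes plus the informative covered blocks of the three
# non-collagenous genes; totals 2,089 alignment columns
RHINO12_GENE_LENGTHS <- c(COL1A1 = 1014L, COL1A2 = 1002L, COL3A1 = 30L,
                          PEDF = 25L, AHSG = 18L)
RHINO12_GENE_RATES <- c(COL1A1 = 0.7, COL1A2 = 0.9, COL3A1 = 1.2,
                        PEDF = 1.5, AHSG = 1.7)
# alignment-excluded ranges of each reference entry: collagen telopeptides,
# and the flanking regions of the NCPs outside their covered blocks (the
# flanks still contribute peptides, Q/N coverage and deamidation evidence)
RHINO12_EXCLUDED <- list(
  COL1A1 = data.frame(start = c(1L, 1031L), end = c(16L, 1055L)),
  COL1A2 = data.frame(start = c(1L, 1014L), end = c(11L, 1028L)),
  COL3A1 = data.frame(start = c(1L, 631L), end = c(600L, 1466L)),
  PEDF   = data.frame(start = c(1L, 226L), end = c(200L, 418L)),
  AHSG   = data.frame(start = c(1L, 169L), end = c(150L, 367L)))

# translated nuclear gene partitions of the extended analysis; totals 3,917
NUCLEAR_GENE_LENGTHS <- c(BRCA1 = 1023L, EDNRB = 442L, KIT = 339L,
                          MC1R = 317L, MITF = 297L, SNAI2 = 268L,
                          SOX10 = 466L, TBX15 = 402L, TYR = 363L)

TINY4_TREE <- "((TaxA:0.1,TaxB:0.1):0.05,TaxC:0.1,TaxD:0.15);"
TINY4_GENE_LENGTHS <- c(g1 = 250L, g2 = 150L)
TINY4_GENE_RATES <- c(g1 = 0.8, g2 = 1.2)

# non-phylogenetic endogenous bone proteins and the contaminant catalogue
RHINO12_EXTRA_ENDO <- c("COL2A1", "COL5A1", "COL5A2", "BGN", "OMD", "LUM",
                        "CHAD", "NCL", "ALB", "SPP1", "DCN", "FN1", "VIM")
RHINO12_CONTAMINANTS <- c("TRYP_PIG", "KRT1", "KRT2", "KRT5", "KRT9",
                          "KRT10", "KRT14", "CSN1S1", "CSN1S2", "CSN2",
                          "LYZ_CHICK", "ALB_BOVIN", "H2A", "H2B", "H3", "H4")

#' Assemble a preset synthetic study
#'
#' `"rhino12"` mirrors a 12-taxon Perissodactyl design (five extant
#' rhinoceroses, two extinct rhinoceros genera sampled as ancient specimens,
#' a tapir, three equids and a bovid outgroup) with five gene partitions
#' totalling 2,089 columns; `"tiny4"` is a 4-taxon smoke-test bundle.
#'
#' @param preset `"rhino12"` or `"tiny4"`.
#' @param seed Integer seed.
#' @return List: `config` ([study_config()]), `proteome`
#'   (`reference_proteome`), `derived` (per-sample true gene sequences),
#'   `gene_seqs` (per-gene taxon sequences for all taxa), `psms`, `truth`,
#'   `reference_taxon`.
#' @export
make_study <- function(preset = c("rhino12", "tiny4"), seed = 1) {
  preset <- match.arg(preset)
  model <- dayhoff_model()
  if (preset == "rhino12") {
    tree <- ape::read.tree(text = RHINO12_TREE)
    lengths <- RHINO12_GENE_LENGTHS
    rates <- RHINO12_GENE_RATES
    samples <- data.frame(sample_id = c("SCH3", "PMF40"),
                          taxon = c("Stephanorhinus_sp",
                                    "Coelodonta_antiquitatis"),
                          age_class = c("old", "young"),
                          stringsAsFactors = FALSE)
    outgroup <- "Bos_primigenius"
    ref_taxon <- "Ceratotherium_simum"
    excl <- RHINO12_EXCLUDED
    extra_endo <- RHINO12_EXTRA_ENDO
    contaminants <- RHINO12_CONTAMINANTS
  } else {
    tree <- ape::read.tree(text = TINY4_TREE)
    lengths <- TINY4_GENE_LENGTHS
    rates <- TINY4_GENE_RATES
    samples <- data.frame(sample_id = "S1", taxon = "TaxA",
                          age_class = "old", stringsAsFactors = FALSE)
    outgroup <- "TaxD"
    ref_taxon <- "TaxC"
    excl <- list()
    extra_endo <- c("BGN", "OMD")
    contaminants <- c("TRYP_PIG", "KRT1", "CSN2")
  }
  config <- study_config(tree, lengths, rates, samples, outgroup, seed = seed)
  gene_seqs <- simulate_alignment(tree, model, lengths, rates, seed = seed)
  set.seed(seed + 1L)
  # reference proteome: each phylogenetic gene is the reference taxon's
  # evolved block embedded in synthetic flanking sequence (collagen
  # telopeptides / NCP regions outside the covered block), shared across
  # taxa; plus the other bone proteins and the contaminant catalogue
  entries <- list()
  flanks <- list()
  for (g in names(lengths)) {
    core <- gene_seqs[[g]][[ref_taxon]]
    ex <- excl[[g]]
    if (!is.null(ex)) {
      fl1 <- .random_protein(ex$end[1L] - ex$start[1L] + 1L, model)
      fl2 <- .random_protein(ex$end[2L] - ex$start[2L] + 1L, model)
    } else fl1 <- fl2 <- ""
    flanks[[g]] <- c(fl1, fl2)
    entries[[paste0("REF_", g)]] <- list(sequence = paste0(fl1, core, fl2),
                                         gene_symbol = g,
                                         is_contaminant = FALSE,
                                         telopeptides = as_ranges(ex))
  }
  for (g in extra_endo)
    entries[[paste0("REF_", g)]] <- list(sequence = .random_protein(300L, model),
                                         gene_symbol = g,
                                         is_contaminant = FALSE,
                                         telopeptides = as_ranges(NULL))
  for (g in contaminants)
    entries[[paste0("CON_", g)]] <- list(sequence = .random_protein(220L, model),
                                         gene_symbol = g,
                                         is_contaminant = TRUE,
                                         telopeptides = as_ranges(NULL))
  proteome <- structure(list(entries = entries), class = "reference_proteome")
  # true full-length proteins per sample: the taxon's evolved block spliced
  # between the reference flanks
  derived <- lapply(stats::setNames(samples$sample_id, samples$sample_id),
                    function(sid) {
    taxon <- samples$taxon[samples$sample_id == sid]
    stats::setNames(lapply(names(gene_seqs), function(g)
      paste0(flanks[[g]][1L], gene_seqs[[g]][[taxon]], flanks[[g]][2L])),
      names(gene_seqs))
  })
  sim <- simulate_psm_study(config, proteome, derived)
  list(config = config, proteome = proteome, derived = derived,
       gene_seqs = gene_seqs, psms = sim$psms, truth = sim$truth,
       reference_taxon = ref_taxon, model = model)
}

#' Write a preset study bundle to disk
#'
#' Writes the exact formats the pipeline reads: reference proteome FASTA,
#' telopeptide side-table TSV, per-sample PSM TSVs (plus the extraction
#' blank), per-gene sequence FASTAs for all taxa, the generating tree, a
#' pipeline YAML configuration, and the truth record TSV. Regenerating with
#' the same preset and seed is byte-identical.
#'
#' @param preset `"rhino12"` or `"tiny4"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the study list from [make_study()].
#' @export
make_fixture_study <- function(preset = c("rhino12", "tiny4"), dir, seed = 1) {
  preset <- match.arg(preset)
  st <- make_study(preset, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome_fasta(st$proteome, file.path(dir, "proteome.fasta"))
  telo <- do.call(rbind, lapply(names(st$proteome$entries), function(acc) {
    r <- st$proteome$entries[[acc]]$telopeptides
    if (!nrow(r)) return(NULL)
    data.frame(accession = acc, start = r$start, end = r$end)
  }))
  if (is.null(telo)) telo <- data.frame(accession = character(),
                                        start = integer(), end = integer())
  utils::write.table(telo, file.path(dir, "telopeptides.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (sid in names(st$psms))
    write_psm_table(st$psms[[sid]], file.path(dir, paste0("psm_", sid, ".tsv")))
  gdir <- file.path(dir, "genes")
  dir.create(gdir, showWarnings = FALSE)
  for (g in names(st$gene_seqs)) {
    xss <- Biostrings::AAStringSet(st$gene_seqs[[g]])
    Biostrings::writeXStringSet(xss, file.path(gdir, paste0(g, ".fasta")),
                                width = 60L)
  }
  ape::write.tree(st$config$tree, file.path(dir, "tree.nwk"))
  utils::write.table(st$truth$proteins, file.path(dir, "truth_proteins.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- list(
    preset = preset, seed = seed,
    paths = list(proteome = "proteome.fasta",
                 telopeptides = "telopeptides.tsv",
                 psm_tables = stats::setNames(
                   as.list(paste0("psm_", st$config$samples$sample_id, ".tsv")),
                   st$config$samples$sample_id),
                 blank = "psm_BLANK.tsv", genes_dir = "genes",
                 tree = "tree.nwk"),
    thresholds = list(fdr = 0.01, alc = 50, min_unique = 2, min_score = 20,
                      min_qn_positions = 3, saav_min_spectra = 2,
                      coverage_warn = 0.40),
    phylo = list(model = "Dayhoff",
                 bootstrap = if (preset == "tiny4") 20L else 100L,
                 generations = if (preset == "tiny4") 20000L else 200000L,
                 sample_interval = 500, burn_in = 0.10,
                 outgroup = st$config$outgroup,
                 gene_order = names(st$config$gene_lengths)),
    samples = st$config$samples)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(st)
}
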