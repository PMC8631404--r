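#' @title Synthetic multi-study fixtures with known ground truth
#'
#' @description Emulates the structure of the integrated source data --
#' several studies quantifying overlapping proteomes with different
#' acquisition types, per-study batch scale factors, multiplicative
#' measurement noise, gene-label synonym corruption and dropout -- so that
#' every pipeline stage can be tested against a known truth without any
#' download. Abundances and noise are lognormal, the standard model for MS
#' proteomics intensities; protein lengths are lognormal with a median near
#' 400 residues and K/R make up ~11% of residues, so nearly every protein
#' yields at least one detectable tryptic peptide.
#'
#' @name synthetic_data
NULL

# Approximate residue frequencies (vertebrate proteome-like), K+R ~ 0.11.
AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.022, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.011, Y = 0.027)

#' Generate a synthetic proteome with ground truth
#'
#' Draws gene symbols, amino-acid sequences (lognormal lengths, median ~400
#' residues, clamped to 60--3000), true per-cell copy numbers (lognormal over
#' about four orders of magnitude), molecular weights and theoretical tryptic
#' peptide counts. A ~5% housekeeping subset is designated, and every gene
#' gets one registered synonym plus a UniProt-style accession, forming an
#' invertible synonym registry for corruption/recovery tests.
#'
#' @param n_genes number of genes, >= 10
#' @param seed integer seed; the same seed reproduces the proteome exactly
#' @param hk_fraction fraction of genes designated housekeeping, default 0.05
#' @return list of class `synthetic_proteome`: `genes`, `synonyms`,
#'   `accessions`, `sequences`, `mol_weight`, `theor_peptides`,
#'   `true_copies`, `housekeeping`, `synonym_table` (data.frame), `seed`
#' @export
generate_proteome <- function(n_genes, seed = 1L, hk_fraction = 0.05) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 10L) stop("n_genes must be >= 10")
  set.seed(seed)
  genes <- sprintf("GN%05d", seq_len(n_genes))
  synonyms <- sprintf("ALT%05dRIK", seq_len(n_genes))
  accessions <- sprintf("P%06d", seq_len(n_genes))

  len <- pmin(pmax(round(stats::rlnorm(n_genes, log(400), 0.4)), 60L), 3000L)
  sequences <- vapply(len, function(L)
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = ""), character(1))
  names(sequences) <- genes

  spec <- digest_spec("trypsin")
  theor_peptides <- vapply(sequences, count_theoretical_peptides,
                           integer(1) * 1, spec = spec)
  mol_weight <- vapply(sequences, molecular_weight, numeric(1))

  # median ~1e5 copies/cell, spread ~4 orders of magnitude (+- 2 sd)
  true_copies <- stats::rlnorm(n_genes, log(1e5), 2.3)
  names(true_copies) <- genes

  housekeeping <- sort(sample(genes, max(3L, round(hk_fraction * n_genes))))

  synonym_table <- data.frame(
    accession = accessions,
    gene_names = paste(genes, synonyms, sep = "|"),
    species = "mouse",
    stringsAsFactors = FALSE)

  structure(
    list(genes = genes, synonyms = stats::setNames(synonyms, genes),
         accessions = stats::setNames(accessions, genes),
         sequences = sequences, mol_weight = mol_weight,
         theor_peptides = theor_peptides, true_copies = true_copies,
         housekeeping = housekeeping, synonym_table = synonym_table,
         seed = seed),
    class = "synthetic_proteome")
}

#' Simulate one study's quantification table
#'
#' Per-gene signal is `true_copies x detectability x batch_factor x noise`,
#' where detectability is the theoretical tryptic peptide count for
#' LFQ/TMT/SILAC and 1 for iBAQ, and the noise is lognormal with mean 1 and
#' the requested coefficient of variation. A fraction of gene labels is
#' replaced by the gene's registered synonym (label corruption), and a
#' fraction of genes is dropped (missingness); dropout is guarded so that at
#' least one housekeeping gene always survives. For `data_type = "molar"` the
#' emitted value is a concentration in uM proportional to truth (batch and
#' noise applied), bypassing the detectability model.
#'
#' @param proteome a [generate_proteome()] result
#' @param study_id character study identifier
#' @param data_type one of `"LFQ"`, `"iBAQ"`, `"TMT"`, `"SILAC"`, `"molar"`
#' @param batch_factor positive per-study scale factor
#' @param noise_cv coefficient of variation of multiplicative noise, in [0,1]
#' @param synonym_corruption_rate fraction of surviving labels corrupted
#' @param dropout_rate fraction of genes dropped
#' @param seed integer seed
#' @return list of class `synthetic_study`: `table` (study table in the
#'   pipeline's input layout), `truth` (true copies of emitted genes,
#'   `batch_factor`, `noise_cv`, `corrupted` named map corrupt label -> true
#'   gene), `study_id`, `data_type`, `seed`
#' @export
simulate_study <- function(proteome, study_id, data_type = "LFQ",
                           batch_factor = 1, noise_cv = 0.2,
                           synonym_corruption_rate = 0, dropout_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  data_type <- match.arg(data_type, c("LFQ", "iBAQ", "TMT", "SILAC", "molar"))
  rates <- c(noise_cv, synonym_corruption_rate, dropout_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (batch_factor <= 0) stop("batch_factor must be positive")
  set.seed(seed)

  genes <- proteome$genes
  # dropout, guarded: never remove every housekeeping gene
  if (dropout_rate > 0) {
    drop <- sample(c(TRUE, FALSE), length(genes), replace = TRUE,
                   prob = c(dropout_rate, 1 - dropout_rate))
    kept <- genes[!drop]
    if (!any(proteome$housekeeping %in% kept))
      kept <- c(kept, sample(proteome$housekeeping, 1L))
    genes <- genes[genes %in% kept]
  }
  # detectability-zero proteins are unusable for peptide-scaled types
  if (data_type %in% c("LFQ", "TMT", "SILAC"))
    genes <- genes[proteome$theor_peptides[genes] > 0]

  det <- switch(data_type,
    LFQ = , TMT = , SILAC = proteome$theor_peptides[genes],
    iBAQ = , molar = rep(1, length(genes)))
  sigma <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  noise <- if (sigma > 0) {
    stats::rlnorm(length(genes), -sigma^2 / 2, sigma)  # mean exactly 1
  } else rep(1, length(genes))
  value <- proteome$true_copies[genes] * det * batch_factor * noise
  value_type <- if (data_type == "molar") "uM" else data_type
  if (data_type == "molar") value <- value * 1e-5  # arbitrary uM scale

  labels <- genes
  corrupted <- character()
  if (synonym_corruption_rate > 0) {
    hit <- stats::runif(length(genes)) < synonym_corruption_rate
    labels[hit] <- proteome$synonyms[genes[hit]]
    corrupted <- stats::setNames(genes[hit], labels[hit])
  }

  table <- data.frame(
    gene = unname(labels),
    accession = unname(proteome$accessions[genes]),
    value = unname(value),
    value_type = value_type,
    study_id = study_id,
    species = "mouse",
    brain_region = "cortex",
    cell_type = "mixed",
    location = "cell",
    condition = "healthy",
    age = "young",
    stringsAsFactors = FALSE)

  structure(
    list(table = table,
         truth = list(true_copies = proteome$true_copies[genes],
                      batch_factor = batch_factor, noise_cv = noise_cv,
                      corrupted = corrupted),
         study_id = study_id, data_type = data_type, seed = seed),
    class = "synthetic_study")
}

#' Simulate a metabolome with per-compartment truth and mixed units
#'
#' Draws true uM concentrations per compound and compartment (lognormal),
#' assigns molecular weights, and emits measurement records expressed
#' randomly in uM, ng per g wet tissue or nmol per mg dry weight using the
#' package's conversion constants, so converting them back to uM recovers the
#' truth. Compound names get a lower/upper-case variant mapped by a synthetic
#' CID table.
#'
#' @param n_compounds number of compounds, >= 5
#' @param compartments compartment vocabulary, subset of `tissue`, `neuron`,
#'   `astrocyte`, `blood`, `extracellular`
#' @param seed integer seed
#' @return list of class `synthetic_metabolome`: `records` (data.frame
#'   `name`, `cid`, `value`, `unit`, `mol_weight`, `compartment`, `species`,
#'   `method`), `truth_uM` (matrix compound x compartment), `cid_table`,
#'   `constants`, `seed`
#' @export
simulate_metabolome <- function(n_compounds,
                                compartments = c("tissue", "neuron",
                                                 "astrocyte", "blood",
                                                 "extracellular"),
                                seed = 1L) {
  n_compounds <- as.integer(n_compounds)
  if (n_compounds < 5L) stop("n_compounds must be >= 5")
  allowed <- c("tissue", "neuron", "astrocyte", "blood", "extracellular")
  bad <- setdiff(compartments, allowed)
  if (length(bad)) stop("unknown compartment '", bad[1L], "'")
  set.seed(seed)
  constants <- conversion_constants()

  names_ <- sprintf("metab%03d", seq_len(n_compounds))
  cids <- 10000L + seq_len(n_compounds)
  mw <- stats::runif(n_compounds, 75, 500)
  truth <- matrix(stats::rlnorm(n_compounds * length(compartments),
                                log(100), 1),
                  nrow = n_compounds,
                  dimnames = list(names_, compartments))

  units <- c("uM", "ng_per_g_wet", "nmol_per_mg_dry")
  rows <- list()
  for (i in seq_len(n_compounds)) {
    for (cp in compartments) {
      unit <- sample(units, 1L)
      value <- from_molar(truth[i, cp], unit, mol_weight = mw[i],
                          constants = constants)
      nm <- if (stats::runif(1) < 0.5) toupper(names_[i]) else names_[i]
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, cid = NA_integer_, value = value, unit = unit,
        mol_weight = mw[i], compartment = cp, species = "mouse",
        method = sample(c("MRS", "MS"), 1L), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  cid_table <- data.frame(name = names_, cid = cids, stringsAsFactors = FALSE)

  structure(
    list(records = records, truth_uM = truth, cid_table = cid_table,
         constants = constants, seed = seed),
    class = "synthetic_metabolome")
}

#' Write a synthetic study bundle to disk
#'
#' Emits the artifacts the pipeline consumes: per-study tables, a FASTA file
#' of protein sequences, the synonym table, the housekeeping list and a
#' ground-truth table.
#'
#' @param proteome a [generate_proteome()] result
#' @param studies list of [simulate_study()] results
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_synthetic_bundle <- function(proteome, studies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "studies"), showWarnings = FALSE)
  paths <- c()
  for (st in studies) {
    p <- file.path(dir, "studies", paste0(st$study_id, ".tsv"))
    utils::write.table(st$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  fa <- file.path(dir, "proteome.fasta")
  writeLines(paste0(">", proteome$genes, "\n", proteome$sequences), fa)
  syn <- file.path(dir, "synonyms.tsv")
  utils::write.table(proteome$synonym_table, syn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hk <- file.path(dir, "housekeeping.txt")
  writeLines(proteome$housekeeping, hk)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(gene = proteome$genes,
               true_copies = unname(proteome$true_copies),
               mol_weight = unname(proteome$mol_weight),
               theor_peptides = unname(proteome$theor_peptides)),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, fa, syn, hk, truth))
}
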