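# Shared fixture builders. Everything is generated in code; no data files.

# Independent brute-force digestion oracle: walks the sequence character by
# character, closing a fragment after every cleavage residue. Kept free of
# regular expressions and of the package's split implementation.
oracle_fragment_lengths <- function(residues, cleave = c("K", "R")) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  lens <- integer()
  cur <- 0L
  for (ch in chars) {
    cur <- cur + 1L
    if (ch %in% cleave) {
      lens <- c(lens, cur)
      cur <- 0L
    }
  }
  if (cur > 0L) lens <- c(lens, cur)
  lens
}

oracle_peptide_count <- function(residues, cleave = c("K", "R"),
                                 min_len = 6L, max_len = 29L) {
  lens <- oracle_fragment_lengths(residues, cleave)
  sum(lens >= min_len & lens <= max_len)
}

random_sequence <- function(len, kr_prob = 0.11) {
  other <- setdiff(names(amcpipe:::AA_FREQ), c("K", "R"))
  paste(sample(c("K", "R", other), len, replace = TRUE,
               prob = c(kr_prob / 2, kr_prob / 2,
                        rep((1 - kr_prob) / length(other), length(other)))),
        collapse = "")
}

# Small multi-study bundle on disk; returns paths and ground truth.
make_bundle <- function(dir, n_genes = 200, n_studies = 3, noise_cv = 0.1,
                        batch_factors = NULL, corruption = 0, dropout = 0,
                        seed = 42) {
  proteome <- generate_proteome(n_genes, seed = seed)
  if (is.null(batch_factors))
    batch_factors <- exp(seq(log(0.5), log(2), length.out = n_studies))
  types <- rep(c("LFQ", "iBAQ", "TMT", "SILAC"), length.out = n_studies)
  studies <- lapply(seq_len(n_studies), function(i)
    simulate_study(proteome, sprintf("st%02d", i), types[i],
                   batch_factor = batch_factors[i], noise_cv = noise_cv,
                   synonym_corruption_rate = corruption,
                   dropout_rate = dropout, seed = seed + i))
  write_synthetic_bundle(proteome, studies, dir)
  list(proteome = proteome, studies = studies,
       config = pipeline_config(
         file.path(dir, "studies"), file.path(dir, "proteome.fasta"),
         file.path(dir, "housekeeping.txt"), file.path(dir, "synonyms.tsv")))
}

# Map true gene symbols into the canonical namespace the pipeline reports in.
truth_in_canonical <- function(proteome) {
  g <- build_synonym_graph(
    as.list(proteome$genes),
    strsplit(proteome$synonym_table$gene_names, "|", fixed = TRUE))
  stats::setNames(proteome$true_copies,
                  canonical_labels(g, names(proteome$true_copies)))
}
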