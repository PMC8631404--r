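#' @title In-silico proteolytic digestion and protein mass
#'
#' @description Label-free MS intensities scale with the number of peptides a
#' protein can contribute. As a detectability correction, protein sequences
#' are cut in silico after every cleavage residue (K/R for trypsin, K for
#' lysC, no missed cleavages, no proline rule) and the fragments with a
#' detectable length of 6--29 residues are counted. Molecular weights use
#' average (not monoisotopic) residue masses, since the concentration
#' estimation works with bulk protein mass.
#'
#' @name protein_digest
NULL

# Average residue masses (g/mol), i.e. amino-acid mass minus one water.
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Digestion specification
#'
#' @param enzyme `"trypsin"` (cleaves after K and R) or `"lysC"` (after K)
#' @param min_len,max_len inclusive detectable fragment length bounds in
#'   residues; defaults 6 and 29
#' @return list of class `digest_spec`
#' @export
digest_spec <- function(enzyme = c("trypsin", "lysC"),
                        min_len = 6L, max_len = 29L) {
  enzyme <- match.arg(enzyme)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (min_len < 1L || min_len > max_len)
    stop("need 1 <= min_len <= max_len")
  structure(
    list(enzyme = enzyme,
         cleavage_residues = if (enzyme == "trypsin") c("K", "R") else "K",
         min_len = min_len, max_len = max_len),
    class = "digest_spec")
}

# Validate residues; X is tolerated (UniProt wildcard), B/J/O/U/Z are not.
check_residues <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(names(AA_RESIDUE_MASS), "X")))
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1L]],
                 bad[1L]))
  chars
}

#' Split a protein sequence into zero-missed-cleavage fragments
#'
#' Cuts immediately C-terminal to every cleavage residue. The concatenation
#' of the returned fragments equals the input sequence.
#'
#' @param residues amino-acid string
#' @param spec a [digest_spec()]
#' @return character vector of fragments, in order
#' @export
digest_fragments <- function(residues, spec = digest_spec()) {
  check_residues(residues)
  pat <- sprintf("(?<=[%s])", paste(spec$cleavage_residues, collapse = ""))
  strsplit(residues, pat, perl = TRUE)[[1L]]
}

#' Count theoretical peptides of detectable length
#'
#' @inheritParams digest_fragments
#' @return number of fragments with length in `[min_len, max_len]`
#' @examples
#' count_theoretical_peptides("AAAAAKGGGGGR") # 2
#' @export
count_theoretical_peptides <- function(residues, spec = digest_spec()) {
  frags <- digest_fragments(residues, spec)
  len <- nchar(frags)
  sum(len >= spec$min_len & len <= spec$max_len)
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (18.02 g/mol). An `X`
#' wildcard contributes the mean residue mass. If `provided` is given (a
#' molecular weight already reported by the source data), it is returned
#' unchanged and the sequence is not consulted.
#'
#' @param residues amino-acid string
#' @param provided optional molecular weight from the source data (g/mol)
#' @return molecular weight in g/mol
#' @export
molecular_weight <- function(residues, provided = NULL) {
  if (!is.null(provided) && length(provided) == 1L && is.finite(provided))
    return(as.numeric(provided))
  chars <- check_residues(residues)
  masses <- AA_RESIDUE_MASS[chars]
  masses[chars == "X"] <- mean(AA_RESIDUE_MASS)
  sum(masses) + WATER_MASS
}

#' Detectability factor for one protein and data type
#'
#' LFQ/TMT/SILAC intensities are divided by the theoretical peptide count;
#' iBAQ values already carry this normalization by definition, so the factor
#' is 1. A zero peptide count for a non-iBAQ entry cannot be used as a
#' divisor: `NA` is returned with a warning so the entry can be excluded
#' upstream.
#'
#' @param residues amino-acid string
#' @param data_type one of `"LFQ"`, `"TMT"`, `"SILAC"`, `"iBAQ"`
#' @param spec a [digest_spec()]
#' @return positive number, or `NA` (exclusion signal) when the peptide
#'   count is zero
#' @export
detectability_factor <- function(residues, data_type, spec = digest_spec()) {
  data_type <- match.arg(data_type, c("LFQ", "TMT", "SILAC", "iBAQ"))
  if (data_type == "iBAQ") return(1)
  n <- count_theoretical_peptides(residues, spec)
  if (n == 0L) {
    warning("zero theoretical peptides; entry should be excluded")
    return(NA_real_)
  }
  n
}

#' Read protein sequences from a FASTA file
#'
#' The identifier is the first whitespace-delimited header token; the UniProt
#' `sp|ACC|NAME` / `tr|ACC|NAME` dialect is recognized and the accession is
#' extracted.
#'
#' @param path FASTA file path
#' @return named character vector of amino-acid sequences (names are
#'   identifiers), with attribute `accession` where the UniProt dialect was
#'   detected
#' @export
read_fasta_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  acc <- ids
  uni <- grepl("^(sp|tr)\\|[^|]+\\|", ids)
  acc[uni] <- vapply(strsplit(ids[uni], "|", fixed = TRUE), `[`,
                     character(1), 2L)
  seqs <- as.character(aa)
  names(seqs) <- ids
  attr(seqs, "accession") <- acc
  seqs
}
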