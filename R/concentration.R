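#' @title Molar concentration estimation and housekeeping normalization
#'
#' @description The total-protein-mass ("proteomic ruler") approach converts
#' relative MS signals into absolute per-cell quantities by assuming a fixed
#' total cellular protein concentration (200 g/L) and protein amount per cell
#' (200 pg). Detectability-corrected signals are apportioned into copy
#' numbers in proportion to their share of the molecular-weight-weighted
#' signal sum; cell volume then follows from total protein mass, and molar
#' concentrations from copies per volume. Because only signal shares matter,
#' any per-study global scale cancels. Residual between-study scale is
#' removed by equalizing each study's median housekeeping-protein
#' concentration to a reference median computed from healthy young-to-middle
#' aged mouse data.
#'
#' @name concentration
NULL

#' Estimation constants
#'
#' @param total_cell_prot_conc_g_per_L total cellular protein concentration,
#'   default 200 g/L
#' @param prot_per_cell_pg protein amount per cell, default 200 pg
#' @param avogadro Avogadro constant, 1/mol
#' @return list of class `estimation_params`
#' @export
estimation_params <- function(total_cell_prot_conc_g_per_L = 200,
                              prot_per_cell_pg = 200,
                              avogadro = 6.02214076e23) {
  if (total_cell_prot_conc_g_per_L <= 0 || prot_per_cell_pg <= 0 ||
      avogadro <= 0)
    stop("estimation constants must be strictly positive")
  structure(
    list(total_cell_prot_conc_g_per_L = total_cell_prot_conc_g_per_L,
         prot_per_cell_pg = prot_per_cell_pg,
         avogadro = avogadro),
    class = "estimation_params")
}

#' Estimate copy numbers and molar concentrations for one study
#'
#' For one study (one cellular proteome; replicate columns are estimated
#' independently), with per-protein signal `s`, detectability factor `d` and
#' molecular weight `m`:
#' \deqn{W = \sum_i (s_i/d_i)\, m_i}
#' \deqn{N_i = (s_i/d_i)\, P\, N_A / W}
#' \deqn{V = \sum_i N_i m_i / N_A / C}
#' \deqn{c_i = N_i / (V N_A)}
#' where `P` is protein mass per cell (g), `C` total protein concentration
#' (g/L) and `N_A` Avogadro's number. `V` is identically `P/C` (1 pL at the
#' defaults) and the summed protein mass concentration equals `C` exactly.
#' Entries with zero or missing signal carry no quantification and are
#' dropped before the sums.
#'
#' @param inputs data.frame with columns `gene`, `signal` (a.u.),
#'   `detectability` (>= 1 theoretical peptide count, or 1 for iBAQ),
#'   `mol_weight` (g/mol); any further columns are carried through
#' @param params an [estimation_params()]
#' @return list with `table` (inputs plus `copy_number` molecules/cell and
#'   `concentration_uM`), `total_volume_L`, and `mw_weighted_signal_sum`
#' @export
estimate_study <- function(inputs, params = estimation_params()) {
  stopifnot(is.data.frame(inputs),
            all(c("gene", "signal", "detectability", "mol_weight") %in%
                  names(inputs)))
  keep <- !is.na(inputs$signal) & inputs$signal > 0 &
    !is.na(inputs$detectability) & inputs$detectability > 0
  inputs <- inputs[keep, , drop = FALSE]
  if (nrow(inputs) == 0L) stop("degenerate study: all signals zero or missing")
  if (any(inputs$mol_weight <= 0 | is.na(inputs$mol_weight)))
    stop("molecular weights must be positive")

  prot_per_cell_g <- params$prot_per_cell_pg * 1e-12
  corrected <- inputs$signal / inputs$detectability
  mw_sum <- sum(corrected * inputs$mol_weight)
  copy_number <- corrected * prot_per_cell_g * params$avogadro / mw_sum
  total_volume <- sum(copy_number * inputs$mol_weight / params$avogadro) /
    params$total_cell_prot_conc_g_per_L
  conc_M <- copy_number / (total_volume * params$avogadro)

  inputs$copy_number <- copy_number
  inputs$concentration_uM <- conc_M * 1e6
  list(table = inputs, total_volume_L = total_volume,
       mw_weighted_signal_sum = mw_sum)
}

#' Convert concentrations already reported in interpretable units to uM
#'
#' Some sources report molar concentrations directly, or mol per gram of
#' protein; the latter is bridged to mol/L through the total cellular protein
#' concentration (g/L).
#'
#' @param value numeric vector of reported values
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"mol_per_g_protein"`
#'   (one unit for the whole vector)
#' @param params an [estimation_params()]
#' @return concentrations in uM
#' @export
convert_reported_units <- function(value, unit, params = estimation_params()) {
  stopifnot(is.numeric(value))
  scale <- switch(unit,
    M = 1e6, mM = 1e3, uM = 1, "µM" = 1, nM = 1e-3,
    mol_per_g_protein = params$total_cell_prot_conc_g_per_L * 1e6,
    stop("unknown unit '", unit, "'"))
  value * scale
}

# Filter for reference-eligible entries. Mouse cell lines pass the species
# filter; organelle-only studies never contribute to the reference even
# though they are later normalized with it.
reference_filter <- function(entries,
                             species = c("mouse", "mouse cell line"),
                             condition = "healthy",
                             ages = c("young", "middle"),
                             organelle_only_studies = character()) {
  ok <- rep(TRUE, nrow(entries))
  if ("species" %in% names(entries))
    ok <- ok & tolower(entries$species) %in% tolower(species)
  if ("condition" %in% names(entries))
    ok <- ok & tolower(entries$condition) %in% tolower(condition)
  if ("age" %in% names(entries))
    ok <- ok & tolower(entries$age) %in% tolower(ages)
  if (length(organelle_only_studies) && "study_id" %in% names(entries))
    ok <- ok & !(entries$study_id %in% organelle_only_studies)
  entries[ok, , drop = FALSE]
}

#' Reference median concentration of housekeeping proteins
#'
#' Median concentration over housekeeping-gene entries from healthy,
#' young-to-middle-aged mouse data (mouse cell lines included). Studies that
#' quantified only an organelle fraction are excluded from the pool because
#' their concentration scale is not cellular.
#'
#' @param entries data.frame of concentration entries with columns
#'   `canonical_gene`, `concentration_uM` and provenance columns `species`,
#'   `condition`, `age`, `study_id`
#' @param housekeeping character vector of housekeeping gene symbols
#' @param species,condition,ages reference filters
#' @param organelle_only_studies study ids excluded from the pool
#' @return scalar reference median in uM
#' @export
compute_reference_median <- function(entries, housekeeping,
                                     species = c("mouse", "mouse cell line"),
                                     condition = "healthy",
                                     ages = c("young", "middle"),
                                     organelle_only_studies = character()) {
  pool <- reference_filter(entries, species, condition, ages,
                           organelle_only_studies)
  pool <- pool[pool$canonical_gene %in% norm_gene_name(housekeeping), ,
               drop = FALSE]
  if (nrow(pool) == 0L) stop("no reference entries")
  stats::median(pool$concentration_uM)
}

#' Normalize each study's concentrations to the housekeeping reference
#'
#' Multiplies every concentration in a study by
#' `reference_median / median(study's housekeeping concentrations)`, on the
#' linear uM scale. After normalization each study's housekeeping median
#' equals the reference median exactly, so applying the normalization twice
#' changes nothing.
#'
#' @param entries data.frame with `canonical_gene`, `concentration_uM`,
#'   `study_id`
#' @param housekeeping character vector of housekeeping gene symbols
#' @param reference_median scalar from [compute_reference_median()]
#' @return entries with scaled `concentration_uM` and `normalized = TRUE`
#' @export
normalize_to_reference <- function(entries, housekeeping, reference_median) {
  stopifnot(reference_median > 0)
  hk <- norm_gene_name(housekeeping)
  out <- split(entries, entries$study_id)
  out <- lapply(out, function(study) {
    hk_conc <- study$concentration_uM[study$canonical_gene %in% hk]
    hk_conc <- hk_conc[hk_conc > 0]
    if (length(hk_conc) == 0L)
      stop("no housekeeping genes with positive concentration in study '",
           study$study_id[1L], "'")
    hk_med <- stats::median(hk_conc)
    if (hk_med == 0) stop("zero housekeeping median in study '",
                          study$study_id[1L], "'")
    study$concentration_uM <- study$concentration_uM * reference_median /
      hk_med
    study
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$normalized <- TRUE
  out
}
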