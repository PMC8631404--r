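#' @title Metabolite unit standardization and tissue mixing
#'
#' @description Literature metabolite levels arrive in molar units, ng per
#' gram wet tissue, or nmol per mg dry weight. All are converted to uM using
#' a brain tissue density of 1.04 g/mL and a brain water content of 80%
#' (hence 0.20 mg dry per mg wet). Compound identities are aligned on PubChem
#' CIDs through an offline name table with a manual-override map. Tissue
#' concentrations are predicted from compartment concentrations by
#' volume-fraction mixing over the neuro-glia-vasculature ensemble.
#'
#' @name metabolite
NULL

#' Physical constants for metabolite unit conversion
#'
#' @param brain_density_g_per_mL brain tissue density, default 1.04 g/mL
#' @param water_fraction brain water content, default 0.80
#' @return list of class `conversion_constants`
#' @export
conversion_constants <- function(brain_density_g_per_mL = 1.04,
                                 water_fraction = 0.80) {
  if (brain_density_g_per_mL <= 0) stop("density must be positive")
  if (water_fraction <= 0 || water_fraction >= 1)
    stop("water fraction must be in (0, 1)")
  structure(list(brain_density_g_per_mL = brain_density_g_per_mL,
                 water_fraction = water_fraction),
            class = "conversion_constants")
}

#' Tissue composition model (volume fractions)
#'
#' Default fractions: extracellular space 0.19, vasculature 0.03, neuronal
#' somas 0.10, neurites (axons and dendrites) 0.60, glia 0.08. They must sum
#' to 1. When an astrocyte concentration is missing it is imputed from the
#' neuronal concentration.
#'
#' @param fractions named numeric vector over
#'   `extracellular, vasculature, neuron_soma, neurites, glia`
#' @return list of class `tissue_composition`
#' @export
tissue_composition <- function(fractions = c(extracellular = 0.19,
                                             vasculature = 0.03,
                                             neuron_soma = 0.10,
                                             neurites = 0.60,
                                             glia = 0.08)) {
  required <- c("extracellular", "vasculature", "neuron_soma", "neurites",
                "glia")
  if (!all(required %in% names(fractions)))
    stop("fractions must name ", paste(required, collapse = ", "))
  fractions <- fractions[required]
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop(sprintf("fractions sum to %.10f, not 1", sum(fractions)))
  structure(list(fractions = fractions,
                 imputation_rule = "astrocyte <- neuron when missing"),
            class = "tissue_composition")
}

#' Convert a metabolite measurement to uM
#'
#' Conversions:
#' \itemize{
#'   \item `ng_per_g_wet`: value x 1e-9 (g/g) x density (g/mL) x 1000 (mL/L)
#'     / mol_weight -> mol/L -> uM
#'   \item `nmol_per_mg_dry`: value x (1 - water_fraction) (mg dry per mg
#'     wet) x 1000 (mg/g) x density -> nmol/mL = uM
#'   \item `nmol_per_g_wet`: value x density -> nmol/mL = uM
#'   \item `umol_per_g_wet`: value x 1000 x density -> uM
#'   \item molar family (`M`, `mM`, `uM`, `nM`): metric rescale
#' }
#' All conversions are linear in `value`.
#'
#' @param value numeric vector of measurements
#' @param unit one unit string for the whole vector
#' @param mol_weight g/mol; required for mass-based units
#' @param constants a [conversion_constants()]
#' @return concentrations in uM
#' @export
to_molar <- function(value, unit, mol_weight = NA_real_,
                     constants = conversion_constants()) {
  stopifnot(is.numeric(value))
  dens <- constants$brain_density_g_per_mL
  dry_per_wet <- 1 - constants$water_fraction
  if (unit %in% c("ng_per_g_wet") && any(!is.finite(mol_weight)))
    stop("mol_weight required for unit '", unit, "'")
  switch(unit,
    M = value * 1e6,
    mM = value * 1e3,
    uM = value, "µM" = value,
    nM = value * 1e-3,
    ng_per_g_wet = value * 1e-9 * dens * 1000 / mol_weight * 1e6,
    nmol_per_mg_dry = value * dry_per_wet * 1000 * dens,
    nmol_per_g_wet = value * dens,
    umol_per_g_wet = value * 1000 * dens,
    stop("unknown unit '", unit, "'"))
}

#' Express a uM concentration back in a source unit
#'
#' Inverse of [to_molar()]; used for round-trip checks and to emit synthetic
#' tables in heterogeneous units.
#'
#' @inheritParams to_molar
#' @param conc_uM concentration in uM
#' @return value in `unit`
#' @export
from_molar <- function(conc_uM, unit, mol_weight = NA_real_,
                       constants = conversion_constants()) {
  conc_uM / to_molar(1, unit, mol_weight, constants)
}

#' Align compound records to PubChem CIDs
#'
#' Lookup is by lower-cased name in an offline CID table; a manual map (the
#' product of manual curation of ambiguous names) overrides the table.
#' Records already carrying a CID are unchanged; unresolvable records are
#' retained and reported.
#'
#' @param records data.frame with columns `name` and `cid` (NA when unknown)
#' @param cid_table data.frame with columns `name`, `cid`; a name mapped to
#'   two different CIDs is an error at load
#' @param manual_map named integer/numeric vector: lower-cased name -> CID
#' @return list with `records` (cid filled where possible) and `report`
#'   (`resolved`, `unresolved`, `unresolved_names`)
#' @export
align_cid <- function(records, cid_table, manual_map = NULL) {
  stopifnot(all(c("name", "cid") %in% names(records)),
            all(c("name", "cid") %in% names(cid_table)))
  key <- tolower(trimws(cid_table$name))
  dup <- tapply(cid_table$cid, key, function(x) length(unique(x)))
  if (any(dup > 1L))
    stop("conflicting CID in table for name(s): ",
         paste(names(dup)[dup > 1L], collapse = ", "))
  table_map <- stats::setNames(cid_table$cid[!duplicated(key)],
                               key[!duplicated(key)])
  resolved <- 0L
  unresolved_names <- character()
  for (i in seq_len(nrow(records))) {
    if (!is.na(records$cid[i])) { resolved <- resolved + 1L; next }
    nm <- tolower(trimws(records$name[i]))
    cid <- if (!is.null(manual_map) && nm %in% names(manual_map)) {
      manual_map[[nm]]
    } else if (nm %in% names(table_map)) {
      table_map[[nm]]
    } else NA
    if (is.na(cid)) {
      unresolved_names <- c(unresolved_names, records$name[i])
    } else {
      records$cid[i] <- cid
      resolved <- resolved + 1L
    }
  }
  list(records = records,
       report = list(resolved = resolved,
                     unresolved = length(unresolved_names),
                     unresolved_names = unique(unresolved_names)))
}

#' Predict tissue concentrations by volume-fraction mixing
#'
#' The predicted tissue concentration of a compound is the volume-fraction-
#' weighted sum of its compartment concentrations: the neuronal concentration
#' supplies both the neuron-soma and neurite fractions, the astrocytic
#' concentration supplies the glia fraction (imputed from the neuronal value
#' when absent), blood supplies vasculature, and the extracellular value its
#' own fraction. Compounds still missing a compartment after imputation are
#' excluded and reported (no imputation rule exists for blood or
#' extracellular values). Being a convex combination, the prediction lies
#' within the range of the compartment concentrations.
#'
#' @param per_compartment data.frame with columns `cid`, `compartment` (one
#'   of `neuron`, `astrocyte`, `blood`, `extracellular`) and `conc_uM`
#' @param model a [tissue_composition()]
#' @return list with `predicted` (named numeric vector, names are CIDs) and
#'   `excluded` (CIDs missing a compartment)
#' @export
mix_tissue <- function(per_compartment, model = tissue_composition()) {
  stopifnot(inherits(model, "tissue_composition"),
            all(c("cid", "compartment", "conc_uM") %in%
                  names(per_compartment)))
  fr <- model$fractions
  predicted <- c()
  excluded <- c()
  for (chunk in split(per_compartment, per_compartment$cid)) {
    comp <- stats::setNames(chunk$conc_uM, chunk$compartment)
    unknown <- setdiff(names(comp),
                       c("neuron", "astrocyte", "blood", "extracellular"))
    if (length(unknown))
      stop("unknown compartment '", unknown[1L], "'")
    if (!("astrocyte" %in% names(comp)) && "neuron" %in% names(comp))
      comp[["astrocyte"]] <- comp[["neuron"]]
    need <- c("neuron", "astrocyte", "blood", "extracellular")
    if (!all(need %in% names(comp))) {
      excluded <- c(excluded, chunk$cid[1L])
      next
    }
    pred <- fr[["extracellular"]] * comp[["extracellular"]] +
      fr[["vasculature"]] * comp[["blood"]] +
      (fr[["neuron_soma"]] + fr[["neurites"]]) * comp[["neuron"]] +
      fr[["glia"]] * comp[["astrocyte"]]
    predicted[as.character(chunk$cid[1L])] <- pred
  }
  list(predicted = predicted, excluded = excluded)
}

#' Compare predicted tissue concentrations with measured ones
#'
#' @param predicted,measured named numeric vectors (names are CIDs)
#' @return list with `n_common`, `spearman_rho`, `pearson_r`
#' @export
compare_predicted_to_measured <- function(predicted, measured) {
  common <- intersect(names(predicted), names(measured))
  if (length(common) < 3L) stop("insufficient overlap")
  list(n_common = length(common),
       spearman_rho = stats::cor(predicted[common], measured[common],
                                 method = "spearman"),
       pearson_r = stats::cor(predicted[common], measured[common],
                              method = "pearson"))
}
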