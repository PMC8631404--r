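#' @title RNA-to-protein conversion ratios
#'
#' @description Paired transcriptome/proteome measurements from the same
#' study give a per-gene conversion ratio between expression (RPKM or TPM)
#' and protein concentration (uM). Applying the ratios to expression from
#' another sample predicts protein levels under the assumption that
#' translation and turnover behave similarly across cell types; cell-specific
#' regulation degrades the prediction and is reported, not corrected.
#'
#' @name rtp
NULL

#' Fit RNA-to-protein conversion ratios
#'
#' `ratio_g = protein_g / expression_g` over the genes present in both
#' inputs. Replicate values for one gene should be averaged by the caller
#' beforehand (one value per gene). Genes with zero expression cannot yield a
#' ratio and are excluded and reported.
#'
#' @param ref_expression named numeric vector: gene -> expression
#' @param ref_protein named numeric vector: gene -> protein concentration, uM
#' @param unit expression unit, `"RPKM"` or `"TPM"`
#' @return list of class `rtp_model` with `ratios` (named numeric, uM per
#'   expression unit), `unit`, `excluded_zero_expression`
#' @export
fit_rtp <- function(ref_expression, ref_protein, unit = c("RPKM", "TPM")) {
  unit <- match.arg(unit)
  common <- intersect(names(ref_expression), names(ref_protein))
  if (length(common) == 0L) stop("no genes shared between expression and protein")
  expr <- ref_expression[common]
  zero <- !is.finite(expr) | expr <= 0
  usable <- common[!zero]
  if (length(usable) == 0L) stop("no genes with positive expression")
  structure(
    list(ratios = ref_protein[usable] / expr[!zero],
         unit = unit,
         excluded_zero_expression = common[zero]),
    class = "rtp_model")
}

#' Predict protein concentrations from expression
#'
#' `predicted_g = ratio_g x expression_g`, gene-wise linear. Genes without a
#' fitted ratio are omitted and counted. The expression unit must match the
#' unit the model was fitted with.
#'
#' @param expression named numeric vector: gene -> expression
#' @param model an [rtp_model][fit_rtp()]
#' @param unit expression unit of `expression`
#' @return list with `predicted_uM` (named numeric) and `n_without_ratio`
#' @export
predict_protein <- function(expression, model, unit = model$unit) {
  stopifnot(inherits(model, "rtp_model"))
  if (!identical(unit, model$unit))
    stop(sprintf("expression unit '%s' does not match model unit '%s'",
                 unit, model$unit))
  common <- intersect(names(expression), names(model$ratios))
  list(predicted_uM = model$ratios[common] * expression[common],
       n_without_ratio = length(setdiff(names(expression), common)))
}
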