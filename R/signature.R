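#' Comparative delta-delta-Ct fold change
#'
#' Standard relative quantification for qPCR: per condition the target gene
#' Ct is referenced to the housekeeping gene
#' (`dCt = Ct(target) - Ct(housekeeping)`), the treated dCt is referenced to
#' the control dCt (`ddCt = dCt(treated) - dCt(control)`), and the fold
#' change is `2^(-ddCt)`. Technical replicates are averaged on the Ct scale
#' first. The result is invariant to any constant shift applied to both
#' conditions' target (or housekeeping) Cts.
#'
#' @param target_treated,target_control Ct values of the target gene under
#'   treatment / control (vectors of technical replicates).
#' @param hk_treated,hk_control Ct values of the housekeeping gene.
#' @return Fold change (dimensionless).
#' @examples
#' ddct_fold_change(20, 24, 15, 15)  # ddCt = -4 -> FC = 16
#' @export
ddct_fold_change <- function(target_treated, target_control,
                             hk_treated, hk_control) {
  ms <- vapply(list(target_treated, target_control, hk_treated, hk_control),
               function(x) mean(x, na.rm = TRUE), numeric(1))
  if (any(!is.finite(ms))) {
    abort("All four Ct groups must contain finite values (is the housekeeping gene missing?).")
  }
  ddct <- (ms[1] - ms[3]) - (ms[2] - ms[4])
  2^(-ddct)
}

#' Per-gene fold changes from a long Ct table
#'
#' Applies [ddct_fold_change()] to every (sample, gene) pair of a long Ct
#' table against a designated control condition, normalising to the
#' housekeeping gene (HPRT1 by default).
#'
#' @param ct_data Long table with columns `sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param housekeeping Housekeeping gene name (default `"HPRT1"`).
#' @param control_condition Condition acting as the calibrator
#'   (default `"DMSO"`).
#' @return Tibble with columns `sample_id`, `gene`, `fold_change` for every
#'   non-control condition and non-housekeeping gene.
#' @export
signature_fold_changes <- function(ct_data, housekeeping = "HPRT1",
                                   control_condition = "DMSO") {
  if (!housekeeping %in% ct_data$gene) {
    abort(sprintf("Housekeeping gene '%s' absent from Ct table.", housekeeping))
  }
  if (!control_condition %in% ct_data$condition) {
    abort(sprintf("Control condition '%s' absent from Ct table.",
                  control_condition))
  }
  mean_ct <- function(cond, g) {
    x <- ct_data$ct[ct_data$condition == cond & ct_data$gene == g]
    if (length(x) == 0) return(NA_real_)
    mean(x, na.rm = TRUE)
  }
  targets <- setdiff(unique(ct_data$gene), housekeeping)
  conds <- setdiff(unique(ct_data$condition), control_condition)
  grid <- expand.grid(sample_id = conds, gene = targets,
                      stringsAsFactors = FALSE)
  grid$fold_change <- purrr::map2_dbl(grid$sample_id, grid$gene, function(s, g) {
    ddct_fold_change(
      target_treated = mean_ct(s, g),
      target_control = mean_ct(control_condition, g),
      hk_treated = mean_ct(s, housekeeping),
      hk_control = mean_ct(control_condition, housekeeping))
  })
  as_tibble(grid)
}

#' Classify a compound's expression signature
#'
#' Rule-based call on four marker genes: strong induction of the
#' repressor-target signature genes (HMOX1, ZNF469, HTRA3) indicates
#' functional BACH1 inhibition, while AKR1B10 induction alone indicates
#' NRF2 activation without BACH1 inhibition. A compound is called
#' `bach1_inhibitor` when at least `genes_required` of the three signature
#' genes exceed `bach1_min`; otherwise `nrf2_activator_only` when AKR1B10
#' exceeds `nrf2_min`; otherwise `inactive`. The numeric thresholds are
#' explicit configuration, not measured constants.
#'
#' @param fcs Named numeric vector or one-row data frame of fold changes
#'   for `HMOX1`, `ZNF469`, `HTRA3`, `AKR1B10` (all required).
#' @param bach1_min Fold-change threshold for the signature genes
#'   (default 2).
#' @param nrf2_min Fold-change threshold for AKR1B10 (default 2).
#' @param genes_required How many of the three signature genes must exceed
#'   `bach1_min` (default 2).
#' @return A tibble with the four fold changes and the `class` call.
#' @examples
#' classify_compound(c(HMOX1 = 20, ZNF469 = 5, HTRA3 = 4, AKR1B10 = 3))
#' @export
classify_compound <- function(fcs, bach1_min = 2, nrf2_min = 2,
                              genes_required = 2) {
  if (is.data.frame(fcs)) fcs <- unlist(fcs[1, , drop = TRUE])
  needed <- c("HMOX1", "ZNF469", "HTRA3", "AKR1B10")
  missing <- setdiff(needed, names(fcs))
  if (length(missing)) {
    abort(sprintf("Missing gene(s): %s", paste(missing, collapse = ", ")))
  }
  sig <- fcs[c("HMOX1", "ZNF469", "HTRA3")]
  cls <- if (sum(sig > bach1_min) >= genes_required) "bach1_inhibitor"
    else if (fcs[["AKR1B10"]] > nrf2_min) "nrf2_activator_only"
    else "inactive"
  tibble(fc_HMOX1 = fcs[["HMOX1"]], fc_ZNF469 = fcs[["ZNF469"]],
         fc_HTRA3 = fcs[["HTRA3"]], fc_AKR1B10 = fcs[["AKR1B10"]],
         class = cls)
}
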