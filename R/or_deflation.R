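# Odds-ratio deflation: how much of the true effect size survives when the
# association is re-fit on imputed genotypes.

#' Per-variant odds-ratio deflation records
#'
#' For each marker, the logistic fit on assayed genotypes defines the true
#' odds ratio and its risk allele; the fit is repeated on imputed integer
#' calls and on fractional dosages, both oriented to the risk allele of the
#' true fit, and the ratio imputed OR / true OR is reported on that
#' oriented scale. Variants without a converged fit in both conditions are
#' excluded and counted.
#'
#' @param true_results data.frame from [logistic_gwas()] on assayed
#'   genotypes
#' @param imputed_int_results [logistic_gwas()] on imputed integer calls
#' @param imputed_frac_results [logistic_gwas()] on imputed dosages
#' @param variant_ids markers to evaluate (e.g. the DAM panel)
#' @return data.frame: `variant_id`, `true_or`, `imputed_or_int`,
#'   `imputed_or_frac`, `ratio_int`, `ratio_frac`; attribute `n_excluded`
#'   counts non-converged markers
#' @export
or_deflation <- function(true_results, imputed_int_results,
                         imputed_frac_results, variant_ids) {
  pick <- function(res, ids) res[match(ids, res$variant_id), , drop = FALSE]
  tr <- pick(true_results, variant_ids)
  ii <- pick(imputed_int_results, variant_ids)
  fr <- pick(imputed_frac_results, variant_ids)
  ok <- !is.na(tr$b) & tr$flag == "" &
        !is.na(ii$b) & ii$flag == "" &
        !is.na(fr$b) & fr$flag == ""
  n_excluded <- sum(!ok)
  tr <- tr[ok, ]; ii <- ii[ok, ]; fr <- fr[ok, ]
  s <- sign(tr$b)               # orient to the true fit's risk allele
  s[s == 0] <- 1
  out <- data.frame(
    variant_id = tr$variant_id,
    true_or = exp(abs(tr$b)),
    imputed_or_int = exp(s * ii$b),
    imputed_or_frac = exp(s * fr$b),
    stringsAsFactors = FALSE
  )
  out$ratio_int <- out$imputed_or_int / out$true_or
  out$ratio_frac <- out$imputed_or_frac / out$true_or
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Summarise deflation ratios as mean with a 2-SE interval
#'
#' @param deflation data.frame from [or_deflation()]
#' @param which `"ratio_int"` or `"ratio_frac"`
#' @param label group label
#' @return one-row data.frame (see [group_summary()])
#' @export
or_deflation_summary <- function(deflation, which = "ratio_int",
                                 label = NA_character_) {
  group_summary(deflation[[which]], label)
}
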