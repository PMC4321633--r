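# Discordance and bias of imputation against assayed genotypes.
#
# All metrics are defined on minor-allele copy counts. Positive bias always
# means the major allele was over-predicted: for integer calls
# B_int = D_M - D_m, and for dosages B_frac = mean(G_0 - G_imp) on the
# minor-copy scale (equivalently mean(G_imp - G_0) when genotypes count
# major-allele copies). The bias can never exceed the discordance.

#' Integer-genotype discordance and bias at one variant
#'
#' `D_M` is the percentage of evaluable samples where the imputed call
#' carries fewer minor-allele copies than the truth (the major allele was
#' over-predicted by one or two copies); `D_m` is the minor-allele analogue;
#' `D_int = D_M + D_m` and `B_int = D_M - D_m`. Samples where either the
#' truth or the imputed call is missing are excluded from numerator and
#' denominator alike.
#'
#' @param truth integer vector of assayed genotypes, minor-copy coded
#' @param imputed integer vector of called imputed genotypes, minor-copy
#'   coded, aligned with `truth`
#' @return list: `D_M`, `D_m`, `D_int`, `B_int` (percent), `n_evaluated`
#' @export
integer_discordance_bias <- function(truth, imputed) {
  if (length(truth) != length(imputed))
    stop("truth and imputed must be aligned over the same samples")
  keep <- !is.na(truth) & !is.na(imputed)
  n <- sum(keep)
  if (n == 0L) stop("no evaluable samples (all calls missing)")
  t_ <- truth[keep]; i_ <- imputed[keep]
  D_M <- 100 * sum(i_ < t_) / n
  D_m <- 100 * sum(i_ > t_) / n
  list(D_M = D_M, D_m = D_m, D_int = D_M + D_m, B_int = D_M - D_m,
       n_evaluated = n)
}

#' Fractional (dosage) discordance and bias at one variant
#'
#' `D_frac = mean |G_imp - G_0|` and `B_frac = mean (G_0 - G_imp)` on the
#' minor-copy scale, so positive `B_frac` means the major allele was
#' over-predicted.
#'
#' @param truth integer vector of assayed genotypes, minor-copy coded
#' @param dosage numeric vector of imputed dosages, minor-copy coded
#' @return list: `D_frac`, `B_frac`, `n_evaluated`
#' @export
fractional_discordance_bias <- function(truth, dosage) {
  if (length(truth) != length(dosage))
    stop("truth and dosage must be aligned over the same samples")
  keep <- !is.na(truth) & !is.na(dosage)
  n <- sum(keep)
  if (n == 0L) stop("no evaluable samples (all values missing)")
  d <- truth[keep] - dosage[keep]
  list(D_frac = mean(abs(d)), B_frac = mean(d), n_evaluated = n)
}

#' Assemble a per-variant bias report row
#'
#' Convenience wrapper computing both metric families from alt-coded inputs
#' plus an allele orientation.
#'
#' @param truth_alt assayed genotypes, alt-copy coded
#' @param called_alt imputed integer calls, alt-copy coded
#' @param dosage_alt imputed dosages, alt-copy coded
#' @param orientation single-row orientation (see [determine_minor_allele()])
#' @param variant_id,panel,group labels copied into the row
#' @return one-row data.frame with columns `variant_id`, `panel`, `group`,
#'   `n_evaluated`, `D_M`, `D_m`, `D_int`, `B_int`, `D_frac`, `B_frac`
#' @export
bias_report_row <- function(truth_alt, called_alt, dosage_alt, orientation,
                            variant_id = orientation$variant_id,
                            panel = NA_character_, group = NA_character_) {
  t_minor <- to_minor_copies(truth_alt, orientation)
  c_minor <- to_minor_copies(called_alt, orientation)
  d_minor <- to_minor_copies(dosage_alt, orientation)
  int_m <- integer_discordance_bias(t_minor, c_minor)
  frac_m <- fractional_discordance_bias(t_minor, d_minor)
  data.frame(variant_id = variant_id, panel = panel, group = group,
             n_evaluated = int_m$n_evaluated,
             D_M = int_m$D_M, D_m = int_m$D_m,
             D_int = int_m$D_int, B_int = int_m$B_int,
             D_frac = frac_m$D_frac, B_frac = frac_m$B_frac,
             stringsAsFactors = FALSE)
}

#' Group summary as mean with a 2-standard-error interval
#'
#' @param values per-variant metric values
#' @param label group label
#' @return one-row data.frame: `group`, `mean`, `ci_lo`, `ci_hi` (mean
#'   +/- 2 x SE, reported as the 95\% CI), `n_variants`
#' @export
group_summary <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values to summarise")
  m <- mean(values)
  se <- if (n > 1L) sd(values) / sqrt(n) else NA_real_
  data.frame(group = label, mean = m,
             ci_lo = m - 2 * se, ci_hi = m + 2 * se,
             n_variants = n, stringsAsFactors = FALSE)
}
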