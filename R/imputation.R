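# Diploid haplotype-copying imputation of one masked variant at a time.
#
# The hidden state is an ordered pair of reference haplotypes; each copied
# haplotype switches template independently at rate rho per bp and emits the
# observed unphased genotype with per-allele error epsilon. Posteriors come
# from exact forward-backward over the pair state space (src/ls_hmm.cpp) —
# deterministic, with no MCMC convergence concerns — and the imputed dosage
# is the posterior mean alt-allele copy count.

#' Imputation engine parameters
#'
#' @param rho per-bp copying switch rate (default 2e-5; larger values make
#'   the posterior average over more reference templates, which stabilises
#'   dosages against panel sampling noise at the price of weaker
#'   haplotype-tracking)
#' @param epsilon per-allele copying error probability, in `[0, 0.5)`
#' @return list of class `hmm_params`
#' @export
hmm_params <- function(rho = 2e-5, epsilon = 0.004) {
  if (rho < 0) stop("'rho' must be non-negative")
  if (epsilon < 0 || epsilon >= 0.5) stop("'epsilon' must lie in [0, 0.5)")
  structure(list(rho = rho, epsilon = epsilon), class = "hmm_params")
}

#' Select the typed variants flanking a query within a centered window
#'
#' @param map variant map
#' @param query_variant variant id of the masked site
#' @param window_bp full window width in bp (default 1 Mb), centered on the
#'   query position
#' @return integer indices (into the map) of flanking variants, in position
#'   order, excluding the query itself
#' @export
select_window <- function(map, query_variant, window_bp = 1000000L) {
  if (window_bp <= 0) stop("'window_bp' must be positive")
  j <- match(query_variant, map$variant_id)
  if (is.na(j)) stop("unknown variant id: ", query_variant)
  half <- window_bp / 2
  idx <- which(abs(map$pos - map$pos[j]) <= half)
  idx <- setdiff(idx, j)
  if (!length(idx))
    stop("no typed variants within the window of ", query_variant,
         ": cannot impute")
  idx
}

#' Posterior genotype distribution at a masked site for one sample
#'
#' @param query_genotypes observed unphased genotypes (alt copies, NA =
#'   missing) over the window sites, the masked site included as NA
#' @param panel reference haplotype matrix restricted to the same sites
#' @param positions bp positions of the window sites
#' @param masked_index index (1-based, within the window) of the masked site
#' @param params an [hmm_params()]
#' @return numeric length-3 vector `P(g = 0, 1, 2)`
#' @export
impute_sample <- function(query_genotypes, panel, positions, masked_index,
                          params = hmm_params()) {
  panel <- as.matrix(panel)
  storage.mode(panel) <- "integer"
  if (nrow(panel) < 2L)
    stop("reference panel must contain at least 2 haplotypes")
  if (anyNA(panel)) stop("reference panels must be complete over the window")
  obs <- as.integer(query_genotypes)
  if (all(is.na(obs[-masked_index])))
    stop("all flanking genotypes missing: cannot impute")
  .ls_posterior_one(panel, obs, as.numeric(positions),
                    as.integer(masked_index) - 1L, params$rho, params$epsilon)
}

#' Convert a dosage to an integer genotype under a call tolerance
#'
#' A dosage `d` (minor- or alt-copy scale; the rule is coding-agnostic)
#' calls homozygous for the 0-allele when `d < T`, heterozygous when
#' `1 - T <= d < 1 + T`, homozygous for the 2-allele when `d >= 2 - T`, and
#' missing otherwise. At `T = 0.5` the three intervals tile `[0, 2]` and no
#' call is ever missing.
#'
#' @param dosage numeric vector in `[0, 2]` (NA allowed, propagates)
#' @param tol call tolerance `T` in (0, 0.5]
#' @return integer vector in \{0, 1, 2, NA\}
#' @export
call_integer_genotype <- function(dosage, tol = 0.5) {
  if (tol <= 0 || tol > 0.5) stop("'tol' must lie in (0, 0.5]")
  ok <- !is.na(dosage)
  if (any(dosage[ok] < 0 | dosage[ok] > 2))
    stop("dosages must lie in [0, 2]")
  out <- rep(NA_integer_, length(dosage))
  out[ok & dosage < tol] <- 0L
  out[ok & dosage >= 1 - tol & dosage < 1 + tol] <- 1L
  out[ok & dosage >= 2 - tol] <- 2L
  out
}

#' Impute one masked variant for every masked sample
#'
#' Applies the forward-backward engine to each sample whose genotype at
#' `variant_id` was masked, using the flanking typed variants within the
#' window and a phased reference panel covering those sites. A per-sample
#' failure (e.g. all flanking genotypes missing) yields missing values for
#' that sample rather than aborting the batch.
#'
#' @param cohort a `cohort` in which `variant_id` has been masked
#'   ([mask_variant()])
#' @param variant_id the masked variant
#' @param panel reference haplotype matrix over all cohort variants (columns
#'   aligned with the cohort map)
#' @param params an [hmm_params()]
#' @param window_bp window width in bp
#' @param tol call tolerance for the integer calls
#' @return list: `samples` (imputed sample indices), `dosage` (alt-copy
#'   scale), `called` (integer calls, alt-copy scale), `posterior` (n x 3),
#'   `quality` (max genotype posterior)
#' @export
impute_masked_panel <- function(cohort, variant_id, panel,
                                params = hmm_params(),
                                window_bp = 1000000L, tol = 0.5) {
  stopifnot(inherits(cohort, "cohort"))
  mrec <- cohort$masked[[variant_id]]
  if (is.null(mrec)) stop("variant ", variant_id, " has not been masked")
  panel <- as.matrix(panel)
  if (ncol(panel) != ncol(cohort$genotypes))
    stop("panel columns must align with the cohort variants")
  if (anyNA(panel)) stop("reference panels must be complete over the window")

  j <- match(variant_id, cohort$map$variant_id)
  win <- select_window(cohort$map, variant_id, window_bp)
  sites <- sort(c(win, j))
  masked_at <- match(j, sites)

  samples <- mrec$samples
  obs <- cohort$genotypes[samples, sites, drop = FALSE]
  obs[, masked_at] <- NA_integer_
  storage.mode(obs) <- "integer"
  sub_panel <- panel[, sites, drop = FALSE]
  storage.mode(sub_panel) <- "integer"

  post <- .ls_posterior_many(sub_panel, obs,
                             as.numeric(cohort$map$pos[sites]),
                             masked_at - 1L, params$rho, params$epsilon)
  dosage <- post[, 2] + 2 * post[, 3]
  list(samples = samples,
       dosage = dosage,
       called = call_integer_genotype(dosage, tol),
       posterior = post,
       quality = apply(post, 1L, function(p) if (anyNA(p)) NA_real_ else max(p)))
}
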