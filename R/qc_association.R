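# Study construction: per-variant QC, stratified splitting, logistic
# association scans, and selection of the disease-associated (DAM) and
# non-associated (NAM) marker panels.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test given the observed allele counts: every
#' heterozygote count of matching parity is enumerated, the probability of a
#' configuration (nAA, nAa, naa) being proportional to
#' `n! / (nAA! nAa! naa!) * 2^nAa`, and the p-value is the total probability
#' of configurations no more probable than the observed one (standard, not
#' mid-p, convention).
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts
#' @return exact p-value in `[0, 1]`
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(is.na(counts)) || any(counts < 0))
    stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("at least one genotyped sample required")
  n_a <- 2 * n_hom_minor + n_het  # minor allele count
  probs <- hwe_config_probs(n, n_a)
  obs <- probs[as.character(n_het)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# probabilities of all heterozygote counts given n samples and n_a copies of
# the rarer allele; named by heterozygote count
hwe_config_probs <- function(n, n_a) {
  n_a <- min(n_a, 2 * n - n_a)
  het <- seq.int(n_a %% 2, n_a, by = 2)
  hom_minor <- (n_a - het) / 2
  hom_major <- n - het - hom_minor
  lp <- lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(het + 1) -
        lgamma(hom_minor + 1) + het * log(2) -
        (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(2 * n - n_a + 1))
  setNames(exp(lp), het)
}

#' Per-variant quality control
#'
#' Retains variants with pooled MAF > 0.05, exact Hardy-Weinberg p-value in
#' controls > 1e-6 and genotype call rate > 0.95 (all strict inequalities).
#'
#' @param cohort a `cohort` with at least one control
#' @param maf_min,hwe_min,call_rate_min thresholds
#' @return list with `report` (per-variant data.frame: `variant_id`, `maf`,
#'   `hwe_p_controls`, `call_rate`, `pass`) and `cohort` (failing variants
#'   removed)
#' @export
qc_filter <- function(cohort, maf_min = 0.05, hwe_min = 1e-6,
                      call_rate_min = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  ctrl <- which(cohort$phenotype == 0L)
  if (!length(ctrl)) stop("no controls: HWE is computed in controls only")
  orientation <- determine_minor_allele(cohort)

  g_ctrl <- cohort$genotypes[ctrl, , drop = FALSE]
  gm_ctrl <- to_minor_copies(g_ctrl, orientation)
  hwe_p <- vapply(seq_len(ncol(gm_ctrl)), function(j) {
    x <- gm_ctrl[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, 1.0)
  call_rate <- colMeans(!is.na(cohort$genotypes))
  report <- data.frame(
    variant_id = cohort$map$variant_id,
    maf = orientation$maf,
    hwe_p_controls = hwe_p,
    call_rate = call_rate,
    stringsAsFactors = FALSE
  )
  report$pass <- report$maf > maf_min &
    !is.na(report$hwe_p_controls) & report$hwe_p_controls > hwe_min &
    report$call_rate > call_rate_min
  list(report = report,
       cohort = subset_cohort(cohort, variants = which(report$pass)))
}

#' Stratified random split of a cohort into two halves
#'
#' Strata are phenotype x sex x age-quartile (quartiles computed on the full
#' cohort); each stratum is randomly halved so split sizes differ by at most
#' one per stratum. Strata smaller than 2 are merged into the neighbouring
#' age stratum (with a warning), never dropped.
#'
#' @param cohort a `cohort` with at least 2 cases and 2 controls
#' @param seed RNG seed
#' @return list of two `cohort`s, `A` and `B`, plus the index vectors
#'   `idx_A`, `idx_B`
#' @export
stratified_split <- function(cohort, seed) {
  stopifnot(inherits(cohort, "cohort"))
  if (sum(cohort$phenotype == 1L) < 2L || sum(cohort$phenotype == 0L) < 2L)
    stop("need at least 2 cases and 2 controls to split")
  set.seed(seed)
  qs <- quantile(cohort$age, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  age_q <- findInterval(cohort$age, unique(qs)) + 1L

  n <- length(cohort$phenotype)
  strata <- split(seq_len(n),
                  interaction(cohort$phenotype, cohort$sex, age_q, drop = TRUE))
  # merge singleton strata into the neighbouring age quartile of the same
  # phenotype x sex cell
  small <- names(strata)[lengths(strata) < 2L]
  if (length(small)) {
    warning("merging ", length(small),
            " stratum/strata of size < 2 into neighbouring age strata")
    for (nm in small) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      q <- as.integer(parts[3])
      neighbours <- paste(parts[1], parts[2],
                          c(q - 1L, q + 1L, q - 2L, q + 2L), sep = ".")
      target <- neighbours[neighbours %in% names(strata) & neighbours != nm][1]
      if (is.na(target)) target <- setdiff(names(strata), nm)[1]
      strata[[target]] <- c(strata[[target]], strata[[nm]])
      strata[[nm]] <- NULL
    }
  }
  idx_A <- integer(0)
  # odd strata alternate which half receives the extra individual, per
  # phenotype class, so arm totals match within one individual
  carry <- c(`0` = 0L, `1` = 0L)
  for (s in strata) {
    s <- sample(s)
    take <- floor(length(s) / 2)
    if (length(s) %% 2L == 1L) {
      ph <- as.character(cohort$phenotype[s[1]])
      if (carry[[ph]] == 0L) {
        take <- take + 1L
        carry[[ph]] <- 1L
      } else carry[[ph]] <- 0L
    }
    idx_A <- c(idx_A, s[seq_len(take)])
  }
  idx_A <- sort(idx_A)
  idx_B <- setdiff(seq_len(n), idx_A)
  list(A = subset_cohort(cohort, idx_A),
       B = subset_cohort(cohort, idx_B),
       idx_A = idx_A, idx_B = idx_B)
}

# single-variant logistic fits; predictor on minor-copy scale
fit_one_variant <- function(y, x_minor) {
  keep <- !is.na(x_minor) & !is.na(y)
  y <- y[keep]; x <- x_minor[keep]
  out <- list(b = NA_real_, p_additive = NA_real_, p_genotypic = NA_real_,
              converged = FALSE, flag = "")
  if (length(unique(x)) < 2L) {
    out$flag <- "monomorphic"
    return(out)
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  b <- coef(fit)[["x"]]
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[["x"]])
  if (!fit$converged || !is.finite(b) || abs(b) > 15 || !is.finite(se) || se > 50) {
    out$flag <- "separation"
    return(out)
  }
  null_dev <- fit$null.deviance
  out$b <- b
  out$p_additive <- pchisq(null_dev - fit$deviance, df = 1, lower.tail = FALSE)
  # genotypic (2-df) model where three genotype classes are present
  if (length(unique(x)) == 3L) {
    xf <- factor(x, levels = c(0, 1, 2))
    fitg <- suppressWarnings(glm(y ~ xf, family = binomial()))
    bg <- coef(fitg)[-1]
    if (fitg$converged && all(is.finite(bg)) && all(abs(bg) < 15)) {
      out$b_het <- unname(bg[1])
      out$b_hom <- unname(bg[2])
      out$p_genotypic <- pchisq(null_dev - fitg$deviance, df = 2,
                                lower.tail = FALSE)
    }
  } else {
    out$p_genotypic <- out$p_additive
  }
  out$converged <- TRUE
  out
}

#' Per-variant logistic association scan
#'
#' Unadjusted logistic regression of case status on minor-allele copy count.
#' The additive slope `b` defines `or_minor = exp(b)` and the ranking
#' magnitude `or_magnitude = exp(|b|)`; a genotypic (2-df) fit is carried
#' alongside. Variants with a constant predictor or separated fits are
#' flagged and excluded from ranking.
#'
#' @param cohort a `cohort` with both phenotype classes
#' @param orientation optional orientation data.frame; computed from the
#'   cohort when missing
#' @param genotypes optional replacement predictor matrix (alt-copy coded;
#'   e.g. imputed dosages) aligned with the cohort's variants
#' @return data.frame: `variant_id`, `pos`, `maf`, `b`, `or_minor`,
#'   `or_magnitude`, `p_additive`, `p_genotypic`, `risk_allele`, `flag`
#' @export
logistic_gwas <- function(cohort, orientation = NULL, genotypes = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$phenotype
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("both phenotype classes must be present")
  if (is.null(orientation)) orientation <- determine_minor_allele(cohort)
  g <- if (is.null(genotypes)) cohort$genotypes else as.matrix(genotypes)
  if (ncol(g) != nrow(orientation))
    stop("genotype columns must match the orientation table")
  gm <- to_minor_copies(g, orientation)

  fits <- lapply(seq_len(ncol(gm)), function(j) fit_one_variant(y, gm[, j]))
  b <- vapply(fits, `[[`, 1.0, "b")
  res <- data.frame(
    variant_id = cohort$map$variant_id,
    pos = cohort$map$pos,
    maf = orientation$maf,
    b = b,
    or_minor = exp(b),
    or_magnitude = exp(abs(b)),
    p_additive = vapply(fits, `[[`, 1.0, "p_additive"),
    p_genotypic = vapply(fits, `[[`, 1.0, "p_genotypic"),
    risk_allele = ifelse(is.na(b), NA_character_,
                         ifelse(b > 0, "minor", "major")),
    flag = vapply(fits, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
  res
}

#' Select disease-associated and non-associated marker panels
#'
#' Ranks converged variants by `or_magnitude = exp(|b|)` (descending); the
#' top `panel_size` become the DAM panel (annotated with the fitted risk
#' allele) and the bottom `panel_size` the NAM panel. Ties are broken by
#' smaller additive p-value, then by variant id.
#'
#' @param results data.frame from [logistic_gwas()]
#' @param panel_size markers per panel (default 100)
#' @return list of class `marker_panel`: `dam` (data.frame with
#'   `variant_id`, `risk_allele`, `or_magnitude`), `nam`, and the attained
#'   `dam_or_threshold` / `nam_or_threshold`
#' @export
select_dam_nam <- function(results, panel_size = 100L) {
  usable <- results[!is.na(results$b) & results$flag == "", , drop = FALSE]
  if (nrow(usable) < 2L * panel_size)
    stop(sprintf("need at least %d ranked variants, have %d",
                 2L * panel_size, nrow(usable)))
  ord <- order(-usable$or_magnitude, usable$p_additive, usable$variant_id)
  usable <- usable[ord, , drop = FALSE]
  dam <- usable[seq_len(panel_size), , drop = FALSE]
  nam <- usable[seq.int(nrow(usable) - panel_size + 1L, nrow(usable)), ,
                drop = FALSE]
  structure(list(
    dam = dam[, c("variant_id", "risk_allele", "or_magnitude", "p_additive")],
    nam = nam[, c("variant_id", "risk_allele", "or_magnitude", "p_additive")],
    dam_or_threshold = min(dam$or_magnitude),
    nam_or_threshold = max(nam$or_magnitude),
    panel_size = as.integer(panel_size)
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d DAM (OR >= %.3f), %d NAM (OR <= %.3f)\n",
              nrow(x$dam), x$dam_or_threshold,
              nrow(x$nam), x$nam_or_threshold))
  invisible(x)
}
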