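# Shared data model: cohorts, allele orientation, masking.
#
# Genotype matrices are stored in alt-allele copy counts (the natural coding
# of the simulator and of VCF); every bias/discordance statistic is defined
# on minor-allele copies, obtained by applying an allele orientation
# ([determine_minor_allele()], [to_minor_copies()]). Fixing one internal
# convention keeps every sign unambiguous: a positive bias always means the
# major allele was over-predicted.

#' Construct a cohort
#'
#' @param genotypes samples x variants integer matrix of alt-allele copies
#'   (0/1/2, NA = missing)
#' @param phenotype integer 0/1 per sample (1 = case)
#' @param sex integer 0/1 per sample
#' @param age numeric per sample
#' @param map variant map data.frame (`variant_id`, `pos`, `ref`, `alt`)
#' @param truth_haplotypes optional phased 0/1 matrix with rows `2k-1`, `2k`
#'   belonging to sample `k` (simulation truth)
#' @param masked optional list of stored truth columns from [mask_variant()]
#' @return object of class `cohort`
#' @export
new_cohort <- function(genotypes, phenotype, sex, age, map,
                       truth_haplotypes = NULL, masked = list()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  if (length(phenotype) != n || length(sex) != n || length(age) != n)
    stop("covariate lengths must match the number of samples")
  if (ncol(genotypes) != nrow(map))
    stop("genotype columns must match the variant map")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype entries must lie in {0, 1, 2, NA}")
  if (anyDuplicated(map$variant_id)) stop("variant identifiers must be unique")
  if (is.unsorted(map$pos, strictly = TRUE))
    stop("variant positions must be strictly increasing")
  if (!is.null(truth_haplotypes)) {
    truth_haplotypes <- as.matrix(truth_haplotypes)
    storage.mode(truth_haplotypes) <- "integer"
    if (nrow(truth_haplotypes) != 2L * n)
      stop("truth haplotypes must have two rows per sample")
  }
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("s%04d", seq_len(n))
  colnames(genotypes) <- map$variant_id
  structure(list(genotypes = genotypes,
                 phenotype = as.integer(phenotype),
                 sex = as.integer(sex),
                 age = as.numeric(age),
                 map = map,
                 truth_haplotypes = truth_haplotypes,
                 masked = masked),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d cases / %d controls), %d variants\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (length(x$masked))
    cat("  masked variants:", paste(names(x$masked), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a cohort by samples and/or variants
#'
#' @param cohort a `cohort`
#' @param samples integer or logical sample selector (default all)
#' @param variants variant ids or indices (default all)
#' @return a `cohort`
#' @export
subset_cohort <- function(cohort, samples = NULL, variants = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$genotypes)
  if (is.null(samples)) samples <- seq_len(n)
  if (is.logical(samples)) samples <- which(samples)
  vidx <- if (is.null(variants)) seq_len(ncol(cohort$genotypes))
          else if (is.character(variants)) {
            i <- match(variants, cohort$map$variant_id)
            if (anyNA(i)) stop("unknown variant id(s): ",
                               paste(variants[is.na(i)], collapse = ", "))
            i
          } else variants
  truth <- cohort$truth_haplotypes
  if (!is.null(truth)) {
    rows <- as.vector(rbind(2L * samples - 1L, 2L * samples))
    truth <- truth[rows, vidx, drop = FALSE]
  }
  new_cohort(cohort$genotypes[samples, vidx, drop = FALSE],
             cohort$phenotype[samples], cohort$sex[samples],
             cohort$age[samples], cohort$map[vidx, , drop = FALSE],
             truth_haplotypes = truth,
             masked = cohort$masked)
}

#' Determine the minor allele per variant on the pooled cohort
#'
#' The minor allele is taken from pooled case + control allele frequencies.
#' A pooled alt frequency of exactly 0.5 declares the alt allele minor
#' (deterministic tie-break). Monomorphic variants are flagged with
#' `maf = 0` rather than raising an error, so QC can remove them.
#'
#' @param cohort a `cohort`
#' @return data.frame: `variant_id`, `minor_is_alt`, `maf`
#' @export
determine_minor_allele <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  g <- cohort$genotypes
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L))
    stop("variant(s) with no called genotypes: ",
         paste(cohort$map$variant_id[n_called == 0L], collapse = ", "))
  alt_freq <- colSums(g, na.rm = TRUE) / (2 * n_called)
  minor_is_alt <- alt_freq <= 0.5
  data.frame(variant_id = cohort$map$variant_id,
             minor_is_alt = minor_is_alt,
             maf = pmin(alt_freq, 1 - alt_freq),
             stringsAsFactors = FALSE)
}

#' Re-express alt-coded genotypes or dosages as minor-allele copies
#'
#' @param x numeric vector/matrix in alt-copy coding (genotypes in
#'   \{0,1,2\} or dosages in `[0,2]`); columns must align with `orientation`
#'   rows when `x` is a matrix
#' @param orientation data.frame from [determine_minor_allele()], or a
#'   single row of it when `x` is a vector for one variant
#' @return `x` re-coded as minor-allele copies (2 - x where the minor
#'   allele is the ref allele)
#' @export
to_minor_copies <- function(x, orientation) {
  flip <- !orientation$minor_is_alt
  if (is.matrix(x)) {
    if (ncol(x) != nrow(orientation))
      stop("orientation rows must match matrix columns")
    x[, flip] <- 2 - x[, flip, drop = FALSE]
    x
  } else {
    if (nrow(orientation) != 1L)
      stop("vector input needs a single-row orientation")
    if (flip) 2 - x else x
  }
}

#' Mask a variant for a subset of samples, retaining the truth column
#'
#' Sets the selected samples' genotypes at `variant_id` to missing and
#' stores the original column (alt-copy coded) under `cohort$masked`, keyed
#' by variant id, for later comparison against imputed values. Re-masking
#' the same variant is idempotent: the stored truth is the first pre-mask
#' column.
#'
#' @param cohort a `cohort`
#' @param variant_id variant to mask
#' @param samples sample selector (indices or logical); default all samples
#' @return the modified `cohort`
#' @export
mask_variant <- function(cohort, variant_id, samples = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  j <- match(variant_id, cohort$map$variant_id)
  if (is.na(j)) stop("unknown variant id: ", variant_id)
  n <- nrow(cohort$genotypes)
  if (is.null(samples)) samples <- seq_len(n)
  if (is.logical(samples)) samples <- which(samples)
  if (!variant_id %in% names(cohort$masked)) {
    cohort$masked[[variant_id]] <- list(
      truth = cohort$genotypes[, j],
      samples = sort(unique(samples))
    )
  } else {
    cohort$masked[[variant_id]]$samples <-
      sort(unique(c(cohort$masked[[variant_id]]$samples, samples)))
  }
  cohort$genotypes[samples, j] <- NA_integer_
  cohort
}

#' Recover the stored truth column of a masked variant
#'
#' @param cohort a `cohort` after [mask_variant()]
#' @param variant_id masked variant id
#' @return integer vector of pre-mask alt-copy genotypes
#' @export
masked_truth <- function(cohort, variant_id) {
  m <- cohort$masked[[variant_id]]
  if (is.null(m)) stop("variant ", variant_id, " has not been masked")
  m$truth
}

# genotypes implied by row-paired haplotypes
genotypes_from_haplotypes <- function(haplotypes) {
  n <- nrow(haplotypes) / 2
  if (n != floor(n)) stop("haplotype matrix must have an even row count")
  g <- haplotypes[2 * seq_len(n) - 1L, , drop = FALSE] +
       haplotypes[2 * seq_len(n), , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}
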