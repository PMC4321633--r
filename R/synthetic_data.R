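# Cohort and reference-panel simulator.
#
# A founder pool of binary haplotypes is expanded into a large population by
# mosaic copying (recombination as template switching, mutation as allele
# flips), which produces block-like linkage disequilibrium without an
# external coalescent simulator. Diploid individuals are formed by pairing
# population haplotypes; case/control status follows a logistic disease model
# over chosen causal variants, so every downstream stage sees data with a
# known risk architecture.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic study: the founder pool,
#' the mosaic expansion, the region geometry, the disease model sampling and
#' the reference-panel sizes. All randomness downstream flows from
#' `rng_seed` through named per-stage streams (see [stage_seeds()]).
#'
#' @param n_founders number of founder haplotypes seeding the mosaic pool
#' @param n_population_haplotypes size of the expanded haplotype pool from
#'   which individuals and the external panel are drawn
#' @param region_length_bp length of the simulated linear region in bp
#' @param n_variants number of biallelic SNPs placed on the region
#' @param maf_range length-2 numeric in (0, 0.5], range of founder
#'   alt-allele frequencies
#' @param switch_rate per-bp probability rate of switching copy template
#'   between adjacent variants (recombination analogue)
#' @param mutation_rate per-site allele flip probability after copying
#' @param n_cases,n_controls cohort arm sizes
#' @param panel_n_control,panel_n_case,panel_n_external reference panel
#'   sizes in individuals (2 haplotypes each)
#' @param rng_seed master seed; every stage derives its own stream from it
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_founders = 30L,
                       n_population_haplotypes = 6000L,
                       region_length_bp = 3000000L,
                       n_variants = 240L,
                       maf_range = c(0.1, 0.5),
                       switch_rate = 1e-5,
                       mutation_rate = 0.008,
                       n_cases = 600L,
                       n_controls = 600L,
                       panel_n_control = 60L,
                       panel_n_case = 60L,
                       panel_n_external = 40L,
                       rng_seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_population_haplotypes = as.integer(n_population_haplotypes),
    region_length_bp = as.integer(region_length_bp),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    switch_rate = as.numeric(switch_rate),
    mutation_rate = as.numeric(mutation_rate),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    panel_n_control = as.integer(panel_n_control),
    panel_n_case = as.integer(panel_n_case),
    panel_n_external = as.integer(panel_n_external),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("n_founders", "n_population_haplotypes", "region_length_bp",
              "n_variants", "n_cases", "n_controls")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop(sprintf("'%s' must be a non-negative integer", nm))
  }
  if (cfg$n_founders < 2L) stop("'n_founders' must be >= 2")
  if (cfg$n_variants < 1L) stop("'n_variants' must be >= 1")
  if (cfg$n_variants > cfg$region_length_bp)
    stop("cannot place ", cfg$n_variants, " distinct positions in ",
         cfg$region_length_bp, " bp")
  if (length(cfg$maf_range) != 2L || any(is.na(cfg$maf_range)) ||
      cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("'maf_range' must be an ordered pair in (0, 0.5]")
  for (nm in c("switch_rate", "mutation_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Derive named per-stage seeds from one master seed
#'
#' @param master integer master seed
#' @param stages character vector of stage names
#' @return named integer vector of seeds, all below 2^31
#' @export
stage_seeds <- function(master,
                        stages = c("founders", "mosaic", "phenotypes",
                                   "split", "panels", "qc", "extra")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  setNames(sample.int(.Machine$integer.max, length(stages)), stages)
}

#' Generate founder haplotypes and a variant map
#'
#' Places `n_variants` distinct positions uniformly on the region, draws a
#' per-site alt-allele frequency within `maf_range`, and samples founder
#' alleles independently at those frequencies. Founders carry no LD; LD is
#' induced by the mosaic expansion ([generate_mosaic_haplotypes()]).
#'
#' @param config a [sim_config()]
#' @param seed optional stage seed; defaults to the `founders` stream of the
#'   config master seed
#' @return list with `haplotypes` (founders x variants 0/1 matrix) and
#'   `map` (data.frame: `variant_id`, `pos`, `ref`, `alt`)
#' @export
generate_founder_haplotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- stage_seeds(config$rng_seed)[["founders"]]
  set.seed(seed)
  m <- config$n_variants
  pos <- sort(sample.int(config$region_length_bp, m, replace = FALSE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  map <- data.frame(
    variant_id = sprintf("var%04d", seq_len(m)),
    pos = pos, ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )
  f <- runif(m, config$maf_range[1], config$maf_range[2])
  hap <- matrix(rbinom(config$n_founders * m, 1L, rep(f, each = config$n_founders)),
                nrow = config$n_founders, ncol = m)
  list(haplotypes = hap, map = map)
}

#' Expand founders into a mosaic haplotype pool
#'
#' Each output haplotype copies a founder template; crossing an inter-variant
#' gap of `d` bp it switches to a uniformly chosen founder (possibly the
#' same) with probability `1 - exp(-switch_rate * d)`, and after copying each
#' allele flips with probability `mutation_rate`. With `switch_rate = 0` and
#' `mutation_rate = 0` every output is an exact founder copy.
#'
#' @param founders 0/1 haplotype matrix (rows = founders)
#' @param map variant map matching the founder columns
#' @param n_out number of haplotypes to generate
#' @param switch_rate per-bp template switch rate
#' @param mutation_rate per-site allele flip probability
#' @param seed RNG seed
#' @return `n_out` x variants 0/1 matrix
#' @export
generate_mosaic_haplotypes <- function(founders, map, n_out,
                                       switch_rate, mutation_rate, seed) {
  if (is.null(dim(founders)) || nrow(founders) == 0L)
    stop("founder haplotype set is empty")
  n_out <- as.integer(n_out)
  if (n_out <= 0L) stop("'n_out' must be positive")
  m <- ncol(founders)
  if (nrow(map) != m) stop("variant map does not match founder columns")
  set.seed(seed)
  nf <- nrow(founders)
  d <- diff(map$pos)
  p_switch <- 1 - exp(-switch_rate * d)

  out <- matrix(0L, nrow = n_out, ncol = m)
  # vectorised over output haplotypes: current template index per haplotype
  tpl <- sample.int(nf, n_out, replace = TRUE)
  out[, 1] <- founders[cbind(tpl, 1L)]
  for (t in seq_len(m - 1L)) {
    sw <- runif(n_out) < p_switch[t]
    if (any(sw)) tpl[sw] <- sample.int(nf, sum(sw), replace = TRUE)
    out[, t + 1L] <- founders[cbind(tpl, t + 1L)]
  }
  if (mutation_rate > 0) {
    flip <- matrix(runif(n_out * m) < mutation_rate, n_out, m)
    out[flip] <- 1L - out[flip]
  }
  storage.mode(out) <- "integer"
  out
}

#' Build a disease model with risk-minor and risk-major causal variants
#'
#' Chooses `n_risk_minor` causal variants whose risk allele is the alt
#' (minor, given founder frequencies below 0.5) allele, with per-copy
#' log-odds `+log(or)`, and `n_risk_major` variants whose risk allele is the
#' ref (major) allele, encoded as per-alt-copy effect `-log(or)`. Causal
#' variants are sampled away from each other where possible.
#'
#' @param map variant map
#' @param n_risk_minor,n_risk_major counts of causal variants per polarity
#' @param or per-copy odds ratio of the risk allele (> 1)
#' @param baseline_logit intercept of the logistic disease model
#' @param seed RNG seed for causal-variant selection
#' @return list of class `disease_model`: `variant_id`, `effect` (per
#'   alt-copy natural-log OR), `baseline_logit`
#' @export
make_disease_model <- function(map, n_risk_minor, n_risk_major,
                               or = 2, baseline_logit = -2.2, seed = 1L) {
  k <- n_risk_minor + n_risk_major
  if (k > nrow(map)) stop("more causal variants requested than variants in map")
  if (or <= 0) stop("'or' must be positive")
  set.seed(seed)
  idx <- sort(sample.int(nrow(map), k))
  pol <- sample(rep(c(1, -1), c(n_risk_minor, n_risk_major)))
  model <- list(
    variant_id = map$variant_id[idx],
    effect = pol * log(or),
    baseline_logit = baseline_logit
  )
  class(model) <- "disease_model"
  model
}

# linear predictor of the disease model for a genotype matrix (alt copies)
risk_score <- function(genotypes, map, model) {
  idx <- match(model$variant_id, map$variant_id)
  if (anyNA(idx)) stop("disease model names variants absent from the map")
  model$baseline_logit +
    as.numeric(genotypes[, idx, drop = FALSE] %*% model$effect)
}

#' Calibrate the model intercept to a target prevalence
#'
#' Solves for the intercept such that the mean case probability over a
#' reference haplotype pool (paired into individuals) equals `prevalence`.
#'
#' @param pool haplotype pool matrix (even rows paired into individuals)
#' @param map variant map
#' @param model disease model (its `baseline_logit` is ignored)
#' @param prevalence target mean case probability
#' @return the calibrated intercept (numeric scalar)
#' @export
calibrate_baseline <- function(pool, map, model, prevalence = 0.1) {
  n <- floor(nrow(pool) / 2)
  g <- pool[2 * seq_len(n) - 1L, , drop = FALSE] +
       pool[2 * seq_len(n), , drop = FALSE]
  m0 <- model
  m0$baseline_logit <- 0
  s <- risk_score(g, map, m0)
  f <- function(b0) mean(plogis(b0 + s)) - prevalence
  uniroot(f, lower = -50, upper = 50, tol = 1e-8)$root
}

#' Sample a case/control cohort from a haplotype pool
#'
#' Individuals are formed by pairing two haplotypes drawn uniformly (with
#' replacement across draws) from the pool; case status is Bernoulli with
#' probability `plogis(baseline_logit + sum(effect * alt copies))`.
#' Rejection sampling continues until both arms reach their target size.
#' Sex is Bernoulli(0.5) and age Normal(60, 10), both independent of
#' genotype; they exist to exercise stratified splitting.
#'
#' @param pool population haplotype matrix (0/1, rows = haplotypes)
#' @param map variant map
#' @param model a `disease_model`
#' @param n_cases,n_controls arm sizes
#' @param seed RNG seed
#' @param max_attempts cap on individual draws before giving up
#' @return a `cohort` (see [new_cohort()]) with truth haplotypes retained
#' @export
assign_phenotypes <- function(pool, map, model, n_cases, n_controls,
                              seed, max_attempts = 100 * (n_cases + n_controls) + 1000) {
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  if (n_cases < 0L || n_controls < 0L) stop("arm sizes must be non-negative")
  if (nrow(pool) < 2L) stop("haplotype pool too small to pair individuals")
  set.seed(seed)

  n_tot <- n_cases + n_controls
  geno <- matrix(0L, n_tot, ncol(pool))
  hapA <- matrix(0L, n_tot, ncol(pool))
  hapB <- matrix(0L, n_tot, ncol(pool))
  phe <- integer(n_tot)
  got_case <- 0L; got_ctrl <- 0L; kept <- 0L; attempts <- 0L

  batch <- max(256L, 2L * n_tot)
  while ((got_case < n_cases || got_ctrl < n_controls) &&
         attempts < max_attempts) {
    nb <- min(batch, max_attempts - attempts)
    attempts <- attempts + nb
    ia <- sample.int(nrow(pool), nb, replace = TRUE)
    ib <- sample.int(nrow(pool), nb, replace = TRUE)
    ga <- pool[ia, , drop = FALSE]
    gb <- pool[ib, , drop = FALSE]
    g <- ga + gb
    p <- plogis(risk_score(g, map, model))
    is_case <- rbinom(nb, 1L, p) == 1L
    for (i in seq_len(nb)) {
      if (is_case[i] && got_case < n_cases) {
        got_case <- got_case + 1L
      } else if (!is_case[i] && got_ctrl < n_controls) {
        got_ctrl <- got_ctrl + 1L
      } else next
      kept <- kept + 1L
      geno[kept, ] <- g[i, ]
      hapA[kept, ] <- ga[i, ]
      hapB[kept, ] <- gb[i, ]
      phe[kept] <- as.integer(is_case[i])
    }
  }
  if (got_case < n_cases || got_ctrl < n_controls)
    stop(sprintf(paste0("could not reach %d cases and %d controls within ",
                        "%d draws (got %d/%d); check baseline_logit"),
                 n_cases, n_controls, max_attempts, got_case, got_ctrl))

  ord <- order(-phe)  # cases first, stable
  truth <- matrix(0L, 2L * n_tot, ncol(pool))
  truth[2 * seq_len(n_tot) - 1L, ] <- hapA[ord, , drop = FALSE]
  truth[2 * seq_len(n_tot), ] <- hapB[ord, , drop = FALSE]

  new_cohort(
    genotypes = geno[ord, , drop = FALSE],
    phenotype = phe[ord],
    sex = rbinom(n_tot, 1L, 0.5),
    age = rnorm(n_tot, 60, 10),
    map = map,
    truth_haplotypes = truth
  )
}

#' Build the three phased reference panels
#'
#' Control and case panels are the truth haplotypes of randomly chosen
#' split-B controls and an equal number of split-B cases; the external panel
#' is drawn from an independent phenotype-agnostic population pool.
#'
#' @param cohortB a `cohort` with truth haplotypes (the held-out split)
#' @param external_pool haplotype matrix of the phenotype-agnostic pool
#' @param n_control,n_case,n_external panel sizes in individuals; the case
#'   panel always matches the control panel size
#' @param seed RNG seed
#' @return list of three haplotype matrices: `control_ref`, `case_ref`,
#'   `external_ref`
#' @export
build_reference_panels <- function(cohortB, external_pool,
                                   n_control, n_case = n_control,
                                   n_external, seed) {
  stopifnot(inherits(cohortB, "cohort"))
  if (is.null(cohortB$truth_haplotypes))
    stop("cohortB must carry truth haplotypes (panels are phased)")
  if (n_case != n_control)
    stop("case panel must have an equal number of individuals as the control panel")
  set.seed(seed)

  take_individuals <- function(idx, n, arm) {
    if (length(idx) < n)
      stop(sprintf("requested %d %s individuals but only %d available",
                   n, arm, length(idx)))
    chosen <- sort(sample(idx, n))
    rows <- as.vector(rbind(2L * chosen - 1L, 2L * chosen))
    cohortB$truth_haplotypes[rows, , drop = FALSE]
  }
  control_ref <- take_individuals(which(cohortB$phenotype == 0L), n_control, "control")
  case_ref <- take_individuals(which(cohortB$phenotype == 1L), n_case, "case")

  if (nrow(external_pool) < 2L * n_external)
    stop(sprintf("external pool has %d haplotypes, need %d",
                 nrow(external_pool), 2L * n_external))
  ext_rows <- sort(sample.int(nrow(external_pool), 2L * n_external))
  external_ref <- external_pool[ext_rows, , drop = FALSE]

  list(control_ref = control_ref, case_ref = case_ref,
       external_ref = external_ref)
}
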