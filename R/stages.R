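# File-based pipeline stages. Each stage reads the declared outputs of the
# stage before it from a run directory and writes its own, so stages can be
# re-run independently; all randomness comes from the same named streams
# derived from the master seed, so a stage-wise run reproduces
# run_experiment() exactly.

run_paths <- function(dir) {
  list(cohort = file.path(dir, "cohort", "cohort.vcf"),
       truth = file.path(dir, "cohort", "truth_phased.vcf"),
       samples = file.path(dir, "cohort", "samples.tsv"),
       external = file.path(dir, "panels", "external_pool.vcf"),
       qc = file.path(dir, "reports", "qc.tsv"),
       cohort_qc = file.path(dir, "cohort", "cohort_qc.vcf"),
       splitA = file.path(dir, "cohort", "splitA_samples.txt"),
       splitB = file.path(dir, "cohort", "splitB_samples.txt"),
       assoc = file.path(dir, "gwas", "association.tsv"),
       markers = file.path(dir, "gwas", "markers.tsv"),
       splitA_imp = file.path(dir, "imputed", "splitA_imputed.tsv"),
       ext_dosages = file.path(dir, "imputed", "external_dosages.vcf"),
       bias = file.path(dir, "reports", "bias.tsv"),
       summary = file.path(dir, "reports", "summary.tsv"),
       deflation = file.path(dir, "reports", "deflation.tsv"),
       config = file.path(dir, "config.yaml"))
}

need <- function(path, stage) {
  if (!file.exists(path))
    stop("missing ", path, ": run the '", stage, "' stage first",
         call. = FALSE)
  path
}

init_run_dir <- function(dir) {
  for (d in c("", "cohort", "panels", "gwas", "imputed", "reports"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  invisible(dir)
}

# reassemble a cohort (with truth haplotypes when available) from run files
load_cohort <- function(dir, qc_filtered = TRUE) {
  p <- run_paths(dir)
  path <- if (qc_filtered) need(p$cohort_qc, "qc") else need(p$cohort, "simulate")
  coh <- read_vcf(path)
  md <- read_sample_metadata(need(p$samples, "simulate"))
  stopifnot(identical(md$sample_id, rownames(coh$genotypes)))
  coh$phenotype <- as.integer(md$phenotype)
  coh$sex <- as.integer(md$sex)
  coh$age <- md$age
  if (file.exists(p$truth)) {
    tr <- read_vcf(p$truth)
    keep <- match(coh$map$variant_id, tr$map$variant_id)
    coh$truth_haplotypes <- tr$haplotypes[, keep, drop = FALSE]
  }
  coh
}

#' Run one pipeline stage against a run directory
#'
#' Stages: `simulate`, `qc`, `split`, `gwas`, `select`, `impute`, `assess`,
#' `deflate`, or `all` (equivalent to [run_experiment()]). Each stage
#' consumes the files the previous stage declared and fails with a message
#' naming the stage to run first when they are absent.
#'
#' @param stage stage name
#' @param dir run directory
#' @param cfg an [experiment_config()]; must match across stages of one run
#' @return invisibly, the stage's main result object
#' @export
run_stage <- function(stage, dir, cfg = experiment_config()) {
  stage <- match.arg(stage, c("simulate", "qc", "split", "gwas", "select",
                              "impute", "assess", "deflate", "all"))
  init_run_dir(dir)
  p <- run_paths(dir)
  seeds <- stage_seeds(cfg$sim$rng_seed,
                       c("founders", "mosaic", "external", "model",
                         "phenotypes", "split", "panels"))
  switch(stage,
    all = return(invisible(run_experiment(cfg, out_dir = dir,
                                          verbose = FALSE))),
    simulate = {
      sim <- simulate_study(cfg)
      write_cohort_vcf(sim$cohort, p$cohort, seed = cfg$sim$rng_seed)
      write_panel_vcf(sim$cohort$truth_haplotypes, sim$map, p$truth,
                      seed = cfg$sim$rng_seed)
      write_sample_metadata(sim$cohort, p$samples, seed = cfg$sim$rng_seed)
      write_panel_vcf(sim$external_pool, sim$map, p$external,
                      seed = cfg$sim$rng_seed)
      invisible(sim)
    },
    qc = {
      coh <- load_cohort(dir, qc_filtered = FALSE)
      out <- qc_filter(coh)
      write_report_tsv(out$report, p$qc, seed = cfg$sim$rng_seed)
      write_cohort_vcf(out$cohort, p$cohort_qc, seed = cfg$sim$rng_seed)
      invisible(out$report)
    },
    split = {
      coh <- load_cohort(dir)
      sp <- stratified_split(coh, seed = seeds[["split"]])
      writeLines(rownames(sp$A$genotypes), p$splitA)
      writeLines(rownames(sp$B$genotypes), p$splitB)
      invisible(sp)
    },
    gwas = {
      coh <- load_cohort(dir)
      ids_A <- readLines(need(p$splitA, "split"))
      orientation <- determine_minor_allele(coh)
      cohA <- subset_cohort(coh, match(ids_A, rownames(coh$genotypes)))
      res <- logistic_gwas(cohA, orientation = orientation)
      write_report_tsv(res, p$assoc, seed = cfg$sim$rng_seed)
      invisible(res)
    },
    select = {
      res <- read_report_tsv(need(p$assoc, "gwas"))
      res$flag[is.na(res$flag)] <- ""
      markers <- select_dam_nam(res, panel_size = cfg$marker_panel_size)
      write_report_tsv(rbind(cbind(markers$dam, set = "DAM"),
                             cbind(markers$nam, set = "NAM")), p$markers)
      invisible(markers)
    },
    impute = stage_impute(dir, cfg, seeds),
    assess = stage_assess(dir, cfg),
    deflate = stage_deflate(dir, cfg)
  )
}

stage_impute <- function(dir, cfg, seeds) {
  p <- run_paths(dir)
  coh <- load_cohort(dir)
  if (is.null(coh$truth_haplotypes))
    stop("phased truth haplotypes not found: run the 'simulate' stage first")
  ids_A <- readLines(need(p$splitA, "split"))
  ids_B <- readLines(need(p$splitB, "split"))
  mk <- read_report_tsv(need(p$markers, "select"))
  ext <- read_vcf(need(p$external, "simulate"))
  keep <- match(coh$map$variant_id, ext$map$variant_id)
  ext_pool <- ext$haplotypes[, keep, drop = FALSE]

  all_ids <- rownames(coh$genotypes)
  cohA <- subset_cohort(coh, match(ids_A, all_ids))
  cohB <- subset_cohort(coh, match(ids_B, all_ids))
  panels <- build_reference_panels(cohB, ext_pool,
                                   n_control = cfg$sim$panel_n_control,
                                   n_case = cfg$sim$panel_n_control,
                                   n_external = cfg$sim$panel_n_external,
                                   seed = seeds[["panels"]])
  case_rows_A <- which(cohA$phenotype == 1L)
  n_all <- nrow(coh$genotypes)
  long <- list()
  ids <- mk$variant_id
  ext_calls <- matrix(NA_integer_, n_all, length(ids),
                      dimnames = list(all_ids, ids))
  ext_dos <- matrix(NA_real_, n_all, length(ids),
                    dimnames = list(all_ids, ids))
  for (v in ids) {
    ra <- mask_impute_one(cohA, v, case_rows_A, panels$control_ref, cfg)
    rb <- mask_impute_one(cohA, v, case_rows_A, panels$case_ref, cfg)
    rc <- mask_impute_one(coh, v, seq_len(n_all), panels$external_ref, cfg)
    sid <- rownames(cohA$genotypes)[ra$samples]
    long[[length(long) + 1L]] <- data.frame(
      variant_id = v, panel = "control", sample_id = sid, truth = ra$truth,
      called = ra$called, dosage = ra$dosage, stringsAsFactors = FALSE)
    long[[length(long) + 1L]] <- data.frame(
      variant_id = v, panel = "case", sample_id = sid, truth = rb$truth,
      called = rb$called, dosage = rb$dosage, stringsAsFactors = FALSE)
    ext_calls[rc$samples, v] <- rc$called
    ext_dos[rc$samples, v] <- rc$dosage
  }
  write_report_tsv(do.call(rbind, long), p$splitA_imp,
                   seed = cfg$sim$rng_seed)
  midx <- sort(match(ids, coh$map$variant_id))
  ids_sorted <- coh$map$variant_id[midx]
  write_dosage_vcf(ext_dos[, ids_sorted, drop = FALSE],
                   coh$map[midx, , drop = FALSE], p$ext_dosages,
                   calls = ext_calls[, ids_sorted, drop = FALSE],
                   seed = cfg$sim$rng_seed)
  invisible(p$splitA_imp)
}

marker_groups <- function(mk) {
  grp <- ifelse(mk$set == "NAM", "NAM",
                ifelse(mk$risk_allele == "major", "DAM_major", "DAM_minor"))
  setNames(grp, mk$variant_id)
}

stage_assess <- function(dir, cfg) {
  p <- run_paths(dir)
  coh <- load_cohort(dir)
  orientation <- determine_minor_allele(coh)
  mk <- read_report_tsv(need(p$markers, "select"))
  long <- read_report_tsv(need(p$splitA_imp, "impute"))
  ext <- read_dosage_vcf(need(p$ext_dosages, "impute"))
  group_of <- marker_groups(mk)

  rows <- list()
  for (v in mk$variant_id) {
    ov <- orientation[orientation$variant_id == v, , drop = FALSE]
    for (pan in c("control", "case")) {
      d <- long[long$variant_id == v & long$panel == pan, ]
      rows[[length(rows) + 1L]] <- bias_report_row(
        d$truth, d$called, d$dosage, ov, v, pan, group_of[[v]])
    }
    j <- match(v, ext$map$variant_id)
    truth <- coh$genotypes[, match(v, coh$map$variant_id)]
    rows[[length(rows) + 1L]] <- bias_report_row(
      truth, ext$calls[, j], ext$dosages[, j], ov, v, "external",
      group_of[[v]])
  }
  bias <- do.call(rbind, rows)
  write_report_tsv(bias, p$bias, seed = cfg$sim$rng_seed)
  write_report_tsv(bias_group_summaries(bias), p$summary,
                   seed = cfg$sim$rng_seed)
  invisible(bias)
}

stage_deflate <- function(dir, cfg) {
  p <- run_paths(dir)
  coh <- load_cohort(dir)
  orientation <- determine_minor_allele(coh)
  mk <- read_report_tsv(need(p$markers, "select"))
  ext <- read_dosage_vcf(need(p$ext_dosages, "impute"))
  midx <- match(ext$map$variant_id, coh$map$variant_id)
  sub <- subset_cohort(coh, variants = midx)
  orient_sub <- orientation[midx, , drop = FALSE]
  true_fit <- logistic_gwas(sub, orientation = orient_sub)
  int_fit <- logistic_gwas(sub, orientation = orient_sub,
                           genotypes = ext$calls)
  frac_fit <- logistic_gwas(sub, orientation = orient_sub,
                            genotypes = ext$dosages)
  dam_ids <- mk$variant_id[mk$set == "DAM"]
  deflation <- or_deflation(true_fit, int_fit, frac_fit, dam_ids)
  write_report_tsv(deflation, p$deflation, seed = cfg$sim$rng_seed)
  invisible(deflation)
}
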